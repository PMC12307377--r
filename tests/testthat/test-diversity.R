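test_that("descriptive statistics use the n-1 sample SD and percent CV", {
  st <- descriptive_stats(c(2, 4, 6, 8))
  expect_equal(st$mean, 5)
  expect_equal(st$sd, 2.581989, tolerance = 1e-6)
  expect_equal(st$cv_percent, 51.63978, tolerance = 1e-5)
  expect_equal(st$range, 6)

  st0 <- descriptive_stats(c(5, 5, 5))
  expect_equal(st0$sd, 0)
  expect_equal(st0$cv_percent, 0)
  expect_equal(st0$range, 0)

  # published main-stem-length extremes reproduce the published range
  expect_equal(184.13 - 67.50, 116.63)

  expect_error(descriptive_stats(c(1)), class = "insufficient_data")
  expect_error(descriptive_stats(c(-1, 1)), class = "zero_mean")
})

test_that("ten-class stratification follows the half-open mean/SD scheme", {
  x <- c(1, 2, 2, 3, 3, 3, 4, 4, 5)
  pr <- stratify_ten_classes(x)
  expect_equal(pr$counts, c(0, 1, 0, 2, 0, 3, 2, 0, 1, 0))
  expect_equal(pr$shannon, 1.522955, tolerance = 1e-4)
  expect_equal(sum(pr$counts), length(x))
  expect_equal(sum(pr$rel_freq), 1, tolerance = 1e-9)

  # value exactly at the mean lands in class 6; extremes close classes 1/10.
  # for c(-2, 0 x7, 2): mean 0 and sd exactly 1, so +-2 sit on the class-1/10
  # boundaries and 0 sits on the class-6 lower edge
  y <- c(-2, rep(0, 7), 2)
  pry <- stratify_ten_classes(y)
  expect_equal(sd(y), 1)
  expect_equal(pry$counts[1], 1L)   # -2 = mean - 2S -> class 1 (closed)
  expect_equal(pry$counts[6], 7L)   #  0 = mean     -> class 6
  expect_equal(pry$counts[10], 1L)  # +2 = mean + 2S -> class 10 (closed)

  expect_warning(pr3 <- stratify_ten_classes(rep(4, 10)),
                 class = "degenerate_stratification")
  expect_equal(pr3$shannon, 0)
  expect_equal(sum(pr3$counts > 0), 1)
})

test_that("stratification agrees with a linear-scan oracle on random vectors", {
  set.seed(202)
  for (i in 1:1000) {
    x <- switch(1 + i %% 3,
                rnorm(30, 50, 10),
                rexp(25, 0.1),
                runif(40, -5, 5))
    pr <- stratify_ten_classes(x)
    expect_equal(pr$counts, tabulate(oracle_ten_classes(x), 10))
  }
})

test_that("H' of a million standard-normal draws matches the normal-CDF oracle", {
  set.seed(7)
  pr <- stratify_ten_classes(rnorm(1e6))
  p_exact <- diff(c(0, pnorm(seq(-2, 2, 0.5)), 1))
  h_exact <- -sum(p_exact * log(p_exact))
  expect_equal(h_exact, 2.0878, tolerance = 1e-4)
  expect_lt(abs(pr$shannon - h_exact), 0.01)
})

test_that("qualitative profiles reproduce published per-trait indices from counts", {
  reg <- millet_traits()
  # printed H' values recomputed from the printed category counts (2 dp)
  printed_h <- c(SZ = 0.66, SS = 0.89, SE = 1.04, SL = 0.79, BC = 0.79,
                 AC = 1.08, SLS = 0.69, FLS = 0.62, TL = 0.81, LR = 1.40)
  counts <- table4_counts()
  for (tr in names(printed_h)) {
    codes <- rep(seq_along(counts[[tr]]), counts[[tr]])
    pr <- qualitative_profile(codes, reg[[tr]])
    expect_equal(round(pr$shannon, 2), printed_h[[tr]],
                 label = sprintf("H' for %s", tr))
    expect_equal(sum(pr$counts), length(codes))
    expect_lte(pr$shannon, log(sum(pr$counts > 0)) + 1e-12)
  }

  # the two leaf-color rows are transposed in the published table; the
  # formulas give the transposed values, asserted here as recomputed
  lsc <- rep(1:3, counts$LSC)
  slc <- rep(1:2, counts$SLC)
  expect_equal(round(qualitative_profile(lsc, reg[["LSC"]])$shannon, 2), 0.87)
  expect_equal(round(qualitative_cv(lsc), 2), 51.86)
  expect_equal(round(qualitative_profile(slc, reg[["SLC"]])$shannon, 2), 0.44)
  expect_equal(round(qualitative_cv(slc), 2), 31.71)

  # hull color: published 0.44 is not reproducible from its printed counts;
  # the formula over the 7 renumbered classes gives 0.48
  hc <- rep(1:7, counts$HC)
  expect_equal(round(qualitative_profile(hc, reg[["HC"]])$shannon, 2), 0.48)

  # degenerate and uniform entropy
  d <- reg[["SLC"]]
  expect_equal(qualitative_profile(rep(1, 50), d)$shannon, 0)
  expect_equal(qualitative_profile(rep(1:2, each = 25), d)$shannon, log(2))
  expect_error(qualitative_profile(integer(0), d), class = "insufficient_data")
})

test_that("qualitative CV treats codes as numbers with the n-1 denominator", {
  expect_equal(round(qualitative_cv(rep(1:4, c(1066, 235, 22, 235))), 2), 66.20)
  expect_equal(round(qualitative_cv(rep(1:3, c(989, 1, 568))), 2), 55.66)
  expect_equal(qualitative_cv(rep(2, 10)), 0)
  expect_equal(qualitative_cv(c(1, 2)), 100 * sd(c(1, 2)) / 1.5)
})

test_that("CV is scale invariant while SD and range scale linearly", {
  set.seed(31)
  x <- rlnorm(200)
  for (c in c(0.5, 3, 100)) {
    expect_equal(descriptive_stats(c * x)$cv_percent,
                 descriptive_stats(x)$cv_percent, tolerance = 1e-9)
    expect_equal(descriptive_stats(c * x)$sd, c * descriptive_stats(x)$sd,
                 tolerance = 1e-9)
    expect_equal(descriptive_stats(c * x)$range, c * descriptive_stats(x)$range,
                 tolerance = 1e-9)
  }
})

test_that("the cohort-level diversity report mirrors the published layout", {
  tab <- generate_cohort(cohort_spec(n_accessions = 1558, seed = 13))
  rep_ <- diversity_report(tab)
  expect_equal(nrow(rep_$quantitative), 11)
  expect_equal(nrow(rep_$qualitative), 14)

  # simulated CVs land within 2 percentage points of the published CVs
  t3 <- table3_targets()
  cv_target <- 100 * t3$sd / t3$mean
  got <- rep_$quantitative$cv_percent[match(t3$trait, rep_$quantitative$trait)]
  expect_true(all(abs(got - cv_target) < 2))

  # "count (pct%)" cells: published example 1035 of 1558 -> 66.43%
  expect_equal(sprintf("%.2f%%", 100 * 1035 / 1558), "66.43%")

  # report profiles satisfy the partition invariants
  for (pr in rep_$profiles) {
    expect_equal(sum(pr$counts), pr$n)
    expect_equal(sum(pr$rel_freq), 1, tolerance = 1e-9)
    expect_gte(pr$shannon, 0)
    expect_lte(pr$shannon, log(sum(pr$counts > 0)) + 1e-12)
  }

  # writes parse back
  dir <- withr::local_tempdir()
  paths <- write_diversity_report(rep_, dir)
  expect_true(all(file.exists(paths)))
  t3back <- read.csv(file.path(dir, "table3.csv"))
  expect_equal(t3back$cv_percent, rep_$quantitative$cv_percent, tolerance = 1e-6)

  empty <- tab[0, ]
  attr(empty, "registry") <- attr(tab, "registry")
  class(empty) <- class(tab)
  expect_error(diversity_report(empty), class = "insufficient_data")
})
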