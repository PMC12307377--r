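test_that("contribution-rate weights normalize by their sum", {
  rates <- c(13.25, 9.08, 7.99, 7.17, 5.66, 4.62, 4.42, 4.27, 4.03, 3.82)
  w <- composite_weights(rates)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  w3 <- composite_weights(rates, digits = 3)
  expect_equal(w3[1], 0.206)
  expect_equal(w3[5], 0.088)
  # the published 3-dp weights sum to 0.999, a rounding artifact
  expect_equal(sum(w3), 0.999, tolerance = 1e-12)

  expect_equal(composite_weights(42), 1)
  expect_error(composite_weights(numeric(0)), class = "configuration_error")
  expect_error(composite_weights(c(1, -1)), class = "configuration_error")
})

test_that("composite F is the weighted sum of component scores", {
  w <- c(0.206, 0.141, 0.124, 0.111, 0.088, 0.072, 0.069, 0.066, 0.063, 0.059)
  z10 <- matrix(0, 2, 10)
  expect_equal(composite_f(z10, w), c(0, 0))
  e1 <- matrix(c(1, rep(0, 9)), 1)
  expect_equal(composite_f(e1, w), 0.206)
  s <- matrix(runif(30), 3, 10)
  expect_equal(composite_f(s, rep(0.1, 10)), rowSums(s) / 10, tolerance = 1e-12)
  expect_error(composite_f(s, w[1:5]), class = "alignment_error")
})

test_that("ranking is dense, descending, and deterministic under ties", {
  out <- rank_accessions(c(0.933, 0.850, 0.814), c("A148", "A116", "A136"), top_k = 2)
  expect_equal(out$accession_id, c("A148", "A116"))
  expect_equal(out$rank, 1:2)

  tie <- rank_accessions(rep(0.5, 3), c("c", "a", "b"))
  expect_equal(tie$rank, rep(1L, 3))
  expect_equal(tie$accession_id, c("a", "b", "c"))  # id order within ties

  # permutation invariance of the full ranking
  set.seed(15)
  f <- rnorm(40); ids <- sprintf("id%02d", 1:40)
  perm <- sample(40)
  expect_equal(rank_accessions(f, ids), rank_accessions(f[perm], ids[perm]))
  expect_true(setequal(rank_accessions(f, ids)$rank, seq_along(unique(f))))

  expect_warning(clamped <- rank_accessions(f, ids, top_k = 99),
                 class = "clamped_top_k")
  expect_equal(nrow(clamped), 40)
  expect_error(rank_accessions(1:3, c("a", "b")), class = "alignment_error")
})

test_that("the scoring pipeline is deterministic and row-order invariant", {
  tab <- generate_cohort(cohort_spec(n_accessions = 400, seed = 12))
  a <- score_accessions(tab)
  b <- score_accessions(tab)
  expect_identical(a$F, b$F)
  expect_equal(sum(a$weights), 1, tolerance = 1e-12)
  expect_equal(ncol(a$scores), a$pca$retained)

  # permuting accession rows permutes F but not its values or the ranking
  perm <- sample(nrow(tab))
  tabp <- tab[perm, ]
  attr(tabp, "registry") <- attr(tab, "registry")
  class(tabp) <- class(tab)
  c_ <- score_accessions(tabp)
  expect_equal(c_$F[names(a$F)], a$F, tolerance = 1e-9)
  expect_equal(c_$ranking$accession_id, a$ranking$accession_id)

  # adding a constant to a raw trait leaves z-score-based F unchanged
  shifted <- as.data.frame(tab)
  shifted$MPL <- shifted$MPL + 100
  d <- score_accessions(phenotype_table(shifted))
  expect_equal(d$F, a$F, tolerance = 1e-9)
})

test_that("an accession dominating yield traits ranks first when PC1 is yield-driven", {
  yield <- c("MPL", "ST", "SSW", "SGW", "TGW")
  cm <- diag(5) * 0.3 + 0.7
  dimnames(cm) <- list(yield, yield)
  tab <- as.data.frame(generate_cohort(cohort_spec(n_accessions = 500, seed = 33,
                                                   correlation = cm)))
  t3 <- table3_targets()
  for (tr in yield) {
    row <- t3[t3$trait == tr, ]
    tab[[tr]][1] <- min(row$mean + 5 * row$sd, row$max)
  }
  sc <- score_accessions(phenotype_table(tab))
  # with five strongly correlated yield traits, PC1 is yield-dominated
  pc1 <- sc$pca$loadings[, 1]
  expect_true(mean(abs(pc1[yield])) > mean(abs(pc1[setdiff(names(pc1), yield)])))
  expect_equal(sc$ranking$accession_id[1], tab$accession_id[1])
})

test_that("membership and z-score normalizations rank accessions concordantly", {
  tab <- generate_cohort(cohort_spec(n_accessions = 600, seed = 44))
  a <- score_accessions(tab, normalization = "zscore")
  b <- score_accessions(tab, normalization = "membership")
  rho <- cor(a$F, b$F[names(a$F)], method = "spearman")
  expect_gt(rho, 0.9)
})

test_that("accessions with missing traits are excluded from scoring with a record", {
  tab <- as.data.frame(generate_cohort(cohort_spec(n_accessions = 150, seed = 2)))
  tab$SSW[3] <- NA
  expect_message(sc <- score_accessions(phenotype_table(tab)), "excluding 1")
  expect_equal(sc$excluded, tab$accession_id[3])
  expect_equal(length(sc$F), 149)
})
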