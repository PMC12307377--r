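test_that("standardization yields zero-mean unit-SD columns and is idempotent", {
  expect_equal(drop(standardize_traits(matrix(1:3, ncol = 1))), c(-1, 0, 1),
               ignore_attr = TRUE)
  set.seed(4)
  m <- matrix(rnorm(60, 10, 3), 20, 3, dimnames = list(NULL, c("x", "y", "w")))
  z <- standardize_traits(m)
  expect_equal(unname(colMeans(z)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 3), tolerance = 1e-12)
  z2 <- standardize_traits(z)
  expect_equal(z2, z, tolerance = 1e-12, ignore_attr = TRUE)

  m[, 2] <- 7
  err <- expect_error(standardize_traits(m), class = "degenerate_trait")
  expect_match(conditionMessage(err), "y")
})

test_that("correlation matrix carries r, t-transform p-values and pair counts", {
  x <- c(1, 2, 3); y <- c(3, 2, 1)
  cr <- trait_correlation(cbind(a = x, b = y, c = x * 2))
  expect_equal(diag(cr$r), c(a = 1, b = 1, c = 1))
  expect_equal(cr$r["a", "b"], -1)
  expect_equal(cr$r["a", "c"], 1)
  expect_true(isSymmetric(cr$r))
  expect_true(all(abs(cr$r) <= 1 + 1e-12))

  # p-values match cor.test on a non-trivial panel
  set.seed(9)
  m <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, letters[1:4]))
  cr2 <- trait_correlation(m)
  ct <- cor.test(m[, 1], m[, 2])
  expect_equal(cr2$p["a", "b"], ct$p.value, tolerance = 1e-10)
  expect_equal(cr2$n_pairs["a", "b"], 50, ignore_attr = TRUE)

  # pairwise-complete handling of missing cells
  m[1:3, 2] <- NA
  cr3 <- trait_correlation(m)
  expect_equal(cr3$n_pairs["a", "b"], 47, ignore_attr = TRUE)
  expect_equal(cr3$r["a", "b"], cor(m[, 1], m[, 2], use = "complete.obs"))

  # BH adjustment is optional and off by default
  cr4 <- trait_correlation(m, p_adjust = "BH")
  expect_true(all(cr4$p >= cr3$p - 1e-12, na.rm = TRUE))
})

test_that("a strongly injected correlation is recovered from a generated cohort", {
  cm <- diag(2); cm[1, 2] <- cm[2, 1] <- 0.95
  dimnames(cm) <- list(c("SSW", "SGW"), c("SSW", "SGW"))
  tab <- generate_cohort(cohort_spec(n_accessions = 1e4, seed = 21, correlation = cm))
  r <- trait_correlation(standardize_traits(tab))$r["SSW", "SGW"]
  expect_gte(r, 0.94); expect_lte(r, 0.96)
})

test_that("the two-trait correlation PCA matches the closed-form eigensystem", {
  # construct a panel whose sample correlation is exactly 0.5:
  # eigenvalues (1.5, 0.5), PC1 unit eigenvector (1, 1)/sqrt(2)
  set.seed(11)
  n <- 300
  x <- drop(scale(rnorm(n)))
  e <- drop(scale(residuals(lm(rnorm(n) ~ x))))  # orthogonal to x by construction
  zz <- cbind(A = x, B = 0.5 * x + sqrt(0.75) * e)
  expect_equal(cor(zz)[1, 2], 0.5, tolerance = 1e-12)
  p <- trait_pca(zz, retain_eigenvalue = 0)
  expect_equal(p$eigenvalues, c(1.5, 0.5), tolerance = 1e-8)
  expect_equal(p$contribution, c(75, 25), tolerance = 1e-8)
  expect_equal(unname(p$score_coefficients[, 1]), c(1, 1) / sqrt(2), tolerance = 1e-8)
  expect_equal(unname(p$loadings[, 1]), rep(sqrt(1.5) / sqrt(2), 2), tolerance = 1e-8)
  expect_equal(unname(p$loadings[, 1]), rep(0.8660, 2), tolerance = 1e-4)

  # component score of the z-row (1, 1): dot product with (0.7071, 0.7071)
  s <- component_scores(rbind(c(A = 1, B = 1)), p)
  expect_equal(unname(s[1, "F1"]), sqrt(2), tolerance = 1e-8)
})

test_that("eigendecomposition agrees with an SVD oracle across random panels", {
  set.seed(77)
  for (i in 1:100) {
    n <- 40 + i %% 20
    m <- matrix(rnorm(n * 25), n, 25,
                dimnames = list(NULL, paste0("T", 1:25)))
    z <- standardize_traits(m)
    p <- trait_pca(z, retain_eigenvalue = 0, retain_max = 25)
    sv <- svd(z / sqrt(n - 1))
    expect_equal(p$eigenvalues, sv$d^2, tolerance = 1e-8)
    # subspace agreement up to sign, checked on the leading component
    v1 <- sv$v[, 1] * sign(sv$v[which.max(abs(sv$v[, 1])), 1])
    c1 <- p$score_coefficients[, 1] *
      sign(p$score_coefficients[which.max(abs(p$score_coefficients[, 1])), 1])
    expect_equal(unname(c1), v1, tolerance = 1e-6)
  }
})

test_that("PCA invariants hold on a generated cohort", {
  tab <- generate_cohort(cohort_spec(n_accessions = 800, seed = 3))
  z <- standardize_traits(tab)
  p <- trait_pca(z, retain_eigenvalue = 0, retain_max = 25)

  expect_equal(sum(p$eigenvalues), 25, tolerance = 1e-8)
  expect_equal(sum(p$contribution), 100, tolerance = 1e-8)
  expect_equal(p$cumulative, cumsum(p$contribution))
  expect_true(all(diff(p$eigenvalues) <= 1e-12))

  # all components kept: loadings reconstruct the correlation matrix
  expect_equal(p$loadings %*% t(p$loadings), cor(z), tolerance = 1e-6,
               ignore_attr = TRUE)

  # coefficient * sqrt(lambda) = loading; coefficient columns orthonormal
  expect_equal(sweep(p$score_coefficients, 2, sqrt(p$eigenvalues), "*"),
               p$loadings, tolerance = 1e-9)
  expect_equal(crossprod(p$score_coefficients), diag(25), tolerance = 1e-9,
               ignore_attr = TRUE)

  # sign convention: largest-|loading| trait positive in every component
  for (j in 1:25)
    expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)

  # retention rule: eigenvalue > 0.95 capped at 10
  pr <- trait_pca(z)
  expect_equal(pr$retained, sum(p$eigenvalues > 0.95 & seq_len(25) <= 10))

  # score columns: variance equals the eigenvalue; zero row scores zero
  s <- component_scores(z, pr)
  expect_equal(unname(apply(s, 2, var)), p$eigenvalues[seq_len(pr$retained)],
               tolerance = 1e-8)
  s0 <- component_scores(matrix(0, 1, 25, dimnames = list(NULL, colnames(z))), pr)
  expect_equal(unname(s0[1, ]), rep(0, pr$retained))

  # a z-row equal to a unit eigenvector scores 1 on its own component, 0 elsewhere
  v2 <- matrix(p$score_coefficients[, 2], 1, dimnames = list(NULL, colnames(z)))
  s2 <- component_scores(v2, pr)
  expect_equal(unname(s2[1, ]), as.numeric(seq_len(pr$retained) == 2),
               tolerance = 1e-9)

  # trait-order mismatch is an alignment error
  zz <- z[, rev(colnames(z))]
  expect_error(component_scores(zz, pr), class = "alignment_error")
})

test_that("published loading/coefficient conventions are internally consistent", {
  ref <- millet_reference_pca()
  # score coefficient = loading / sqrt(eigenvalue): published PC1 example
  expect_equal(ref$loadings["STC", "PC1"] / sqrt(ref$eigenvalues[1]), 0.298,
               tolerance = 0.005)
  # contribution rate = 100 * eigenvalue / 25 reproduces the published rate
  expect_lt(abs(100 * ref$eigenvalues[1] / 25 - ref$contribution[1]), 0.05)
  # published cumulative rate is the running sum of printed rates (to rounding)
  expect_equal(ref$cumulative, cumsum(ref$contribution), tolerance = 0.015)
})
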