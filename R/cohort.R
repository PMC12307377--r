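# Truncated-normal moments on [lo, hi] for underlying N(mu, sigma)
truncnorm_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  Z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  m <- mu + sigma * (da - db) / Z
  v <- sigma^2 * (1 + (a * da - b * db) / Z - ((da - db) / Z)^2)
  list(mean = m, sd = sqrt(v))
}

# Solve for the underlying normal so the [lo, hi]-truncated distribution
# attains the target mean/sd (fixed-point iteration; the truncation is
# mild for published trait ranges so this converges in a few steps).
match_truncnorm <- function(mean, sd, lo, hi, tol = 1e-10, maxit = 200L) {
  mu <- mean; sigma <- sd
  for (i in seq_len(maxit)) {
    mo <- truncnorm_moments(mu, sigma, lo, hi)
    if (abs(mo$mean - mean) < tol && abs(mo$sd - sd) < tol) break
    sigma <- sigma * sd / mo$sd
    mu <- mu + (mean - mo$mean)
  }
  list(mu = mu, sigma = sigma)
}

# deterministic per-trait substream seed below 2^31
substream_seed <- function(seed, k) {
  (as.numeric(seed) %% 1e6) * 2039 + 7919 * k %% 1e6
}

#' Specification for a synthetic accession cohort
#'
#' Bundles and validates the generator targets: sample size, per-trait
#' quantitative targets (mean, SD, min, max), qualitative category
#' probabilities, an optional correlation matrix over quantitative
#' traits, and the master seed. Defaults reproduce the published
#' marginal distributions of the 1,558-accession millet panel
#' ([table3_targets()], [table4_targets()]).
#'
#' @param n_accessions Number of accessions to simulate.
#' @param quantitative Data frame as returned by [table3_targets()].
#' @param qualitative Named list of category probability vectors.
#' @param correlation Optional symmetric positive semi-definite matrix
#'   with unit diagonal, rows/columns named by quantitative traits.
#' @param seed Master integer seed; every trait draws from a substream
#'   derived deterministically from it.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_accessions = 1558, quantitative = table3_targets(),
                        qualitative = table4_targets(), correlation = NULL,
                        seed = 1L) {
  stopifnot(n_accessions >= 1)
  if (any(quantitative$sd <= 0))
    pd_stop("quantitative target sd must be > 0", "configuration_error")
  if (any(quantitative$min >= quantitative$max))
    pd_stop("quantitative target min must be < max", "configuration_error")
  bad <- vapply(qualitative, function(p) abs(sum(p) - 1) > 1e-9 || any(p < 0), logical(1))
  if (any(bad))
    pd_stop(sprintf("qualitative probabilities must be nonnegative and sum to 1 (%s)",
                    paste(names(qualitative)[bad], collapse = ", ")),
            "configuration_error")
  if (!is.null(correlation)) {
    if (!isSymmetric(unname(correlation), tol = 1e-8) ||
        any(abs(diag(correlation) - 1) > 1e-8))
      pd_stop("correlation must be symmetric with unit diagonal", "configuration_error")
    ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      pd_stop("correlation matrix is not positive semi-definite", "configuration_error")
    if (is.null(rownames(correlation)) ||
        !all(rownames(correlation) %in% quantitative$trait))
      pd_stop("correlation rows/columns must be named by quantitative traits",
              "configuration_error")
  }
  structure(list(n_accessions = as.integer(n_accessions), quantitative = quantitative,
                 qualitative = qualitative, correlation = correlation,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic accession cohort
#'
#' Draws a seedable synthetic panel whose marginal distributions emulate
#' the published trait summaries. Quantitative traits are sampled from
#' moment-matched truncated normals: the underlying normal parameters are
#' solved so that, after truncation to the published \eqn{[min, max]}
#' range, the distribution attains the target mean and SD. An optional
#' correlation matrix induces dependence between quantitative traits via
#' a Gaussian-copula-style Cholesky mix of the per-trait standard normal
#' streams. Out-of-range draws are resampled from the marginal (up to
#' `max_resample` rounds, then clipped to the range). Qualitative traits
#' are sampled categorically per target probabilities, independently of
#' the quantitative block. Identical spec and seed give identical tables.
#'
#' @param spec A [cohort_spec()]; alternatively pass `n`/`seed`/... which
#'   are forwarded to `cohort_spec()`.
#' @param registry A `trait_registry` matching the target trait names.
#' @param max_resample Cap on marginal resampling rounds for out-of-range
#'   draws before clipping.
#' @param ... Arguments forwarded to [cohort_spec()] when `spec` is NULL.
#' @return A `phenotype_table` with `spec$n_accessions` rows.
#' @examples
#' tab <- generate_cohort(n_accessions = 200, seed = 7)
#' nrow(tab)
#' @export
generate_cohort <- function(spec = NULL, registry = millet_traits(),
                            max_resample = 1000L, ...) {
  spec <- spec %||% cohort_spec(...)
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_accessions
  qt <- spec$quantitative
  quant <- qt$trait
  qual <- names(spec$qualitative)

  # per-trait standard-normal substreams
  E <- matrix(NA_real_, n, length(quant), dimnames = list(NULL, quant))
  for (j in seq_along(quant)) {
    set.seed(substream_seed(spec$seed, j))
    E[, j] <- stats::rnorm(n)
  }
  if (!is.null(spec$correlation)) {
    tr <- rownames(spec$correlation)
    U <- chol(spec$correlation + diag(1e-10, nrow(spec$correlation)))
    E[, tr] <- E[, tr, drop = FALSE] %*% U
  }

  X <- E
  for (j in seq_along(quant)) {
    p <- qt[j, ]
    mm <- match_truncnorm(p$mean, p$sd, p$min, p$max)
    x <- mm$mu + mm$sigma * E[, j]
    set.seed(substream_seed(spec$seed, j) + 1)
    for (round in seq_len(max_resample)) {
      out <- which(x < p$min | x > p$max)
      if (!length(out)) break
      x[out] <- mm$mu + mm$sigma * stats::rnorm(length(out))
    }
    X[, j] <- pmin(pmax(x, p$min), p$max)
  }

  Q <- matrix(NA_real_, n, length(qual), dimnames = list(NULL, qual))
  for (j in seq_along(qual)) {
    prob <- spec$qualitative[[j]]
    set.seed(substream_seed(spec$seed, length(quant) + j))
    Q[, j] <- sample(seq_along(prob), n, replace = TRUE, prob = prob)
  }

  set.seed(substream_seed(spec$seed, length(quant) + length(qual) + 1))
  mc <- material_class_counts()
  material <- sample(names(mc), n, replace = TRUE, prob = mc / sum(mc))

  out <- data.frame(accession_id = sprintf("ACC%05d", seq_len(n)),
                    accession_name = sprintf("SIM-%05d", seq_len(n)),
                    material_class = material, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(X), as.data.frame(Q))
  # order columns per registry
  phenotype_table(out, registry)
}
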