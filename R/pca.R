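#' Standardize trait columns to z-scores
#'
#' Centers each trait on its mean and scales by its sample standard
#' deviation (n-1), so every column has mean 0 and sample SD 1.
#' Qualitative traits are standardized on their integer codes.
#'
#' @param x A `phenotype_table` or numeric matrix (accessions x traits).
#' @param traits Optional subset of traits to keep.
#' @return A numeric z-score matrix with attributes `"center"` and
#'   `"scale"` holding the per-trait means and SDs.
#' @export
standardize_traits <- function(x, traits = NULL) {
  m <- if (inherits(x, "phenotype_table")) trait_matrix(x, traits) else {
    m0 <- as.matrix(x)
    if (!is.null(traits)) m0 <- m0[, traits, drop = FALSE]
    m0
  }
  ctr <- colMeans(m, na.rm = TRUE)
  scl <- apply(m, 2, stats::sd, na.rm = TRUE)
  degenerate <- which(!is.na(scl) & scl == 0)
  if (length(degenerate))
    pd_stop(sprintf("zero-variance trait(s): %s",
                    paste(colnames(m)[degenerate], collapse = ", ")),
            "degenerate_trait")
  z <- sweep(sweep(m, 2, ctr), 2, scl, "/")
  attr(z, "center") <- ctr
  attr(z, "scale") <- scl
  z
}

#' Pearson correlation matrix with significance
#'
#' Pairwise-complete Pearson correlations between trait columns, with
#' two-sided p-values from the t transform
#' \eqn{t = r \sqrt{(n-2)/(1-r^2)}}. Cells with fewer than 3 complete
#' pairs are flagged undefined (`NA`).
#'
#' @param z Numeric matrix (accessions x traits); typically z-scores,
#'   though Pearson r is invariant to per-column affine scaling.
#' @param p_adjust Optional p-value adjustment method passed to
#'   [stats::p.adjust()] (e.g. `"BH"`); `"none"` (default) reports raw
#'   two-sided p-values.
#' @return A list of class `trait_correlation` with matrices `r`, `p`,
#'   and `n_pairs`.
#' @export
trait_correlation <- function(z, p_adjust = "none") {
  z <- as.matrix(z)
  if (nrow(z) < 3L) pd_stop("need at least 3 rows for correlations", "insufficient_data")
  r <- stats::cor(z, use = "pairwise.complete.obs")
  npairs <- crossprod(!is.na(z))
  r[npairs < 3L] <- NA_real_
  tstat <- r * sqrt((npairs - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = npairs - 2, lower.tail = FALSE)
  diag(p) <- NA_real_
  if (p_adjust != "none") {
    lower <- lower.tri(p)
    p[lower] <- stats::p.adjust(p[lower], method = p_adjust)
    p[upper.tri(p)] <- t(p)[upper.tri(p)]
  }
  structure(list(r = r, p = p, n_pairs = npairs, p_adjust = p_adjust),
            class = "trait_correlation")
}

#' @export
print.trait_correlation <- function(x, ...) {
  cat(sprintf("<trait_correlation> %d traits, p-values %s\n",
              ncol(x$r), if (x$p_adjust == "none") "raw two-sided" else
                sprintf("adjusted (%s)", x$p_adjust)))
  cat("strongest off-diagonal pairs:\n")
  r <- x$r; diag(r) <- NA
  ord <- order(-abs(r))[seq_len(min(10, sum(!is.na(r))))]
  idx <- arrayInd(ord, dim(r))
  keep <- idx[, 1] < idx[, 2]
  idx <- idx[keep, , drop = FALSE]
  for (i in seq_len(min(5, nrow(idx))))
    cat(sprintf("  %s ~ %s  r = %+.3f\n", colnames(r)[idx[i, 1]],
                colnames(r)[idx[i, 2]], r[idx[i, 1], idx[i, 2]]))
  invisible(x)
}

#' Principal component analysis of the trait correlation matrix
#'
#' Eigendecomposition of the Pearson correlation matrix of all traits
#' (qualitative traits entering through their integer codes). Components
#' are retained while the eigenvalue exceeds `retain_eigenvalue` and the
#' component index does not exceed `retain_max`. Loadings are eigenvector
#' times \eqn{\sqrt\lambda}; score coefficients are the unit eigenvector
#' elements (loading / \eqn{\sqrt\lambda}); the contribution rate of a
#' component is \eqn{100\,\lambda/p} percent, \eqn{p} the number of
#' traits. Eigenvector signs are fixed so the largest-|loading| trait of
#' each component is positive; eigenvalue ties are broken by input trait
#' order.
#'
#' @param z Z-score matrix from [standardize_traits()] (a
#'   `phenotype_table` is standardized on the fly).
#' @param retain_eigenvalue Eigenvalue retention threshold.
#' @param retain_max Maximum number of retained components.
#' @return An object of class `trait_pca`: `eigenvalues`, `loadings`,
#'   `score_coefficients` (all components), `contribution`, `cumulative`
#'   (percent), `retained`, plus the standardization `center`/`scale`.
#' @export
trait_pca <- function(z, retain_eigenvalue = 0.95, retain_max = 10L) {
  if (inherits(z, "phenotype_table")) z <- standardize_traits(z)
  if (!all(is.finite(z))) pd_stop("non-finite values in standardized matrix", "numeric_error")
  R <- stats::cor(z)
  e <- eigen(R, symmetric = TRUE)
  p <- ncol(z)
  vec <- e$vectors
  lam <- e$values
  loadings <- sweep(vec, 2, sqrt(pmax(lam, 0)), "*")
  # sign convention: largest-|loading| trait positive per component
  for (j in seq_len(p)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      vec[, j] <- -vec[, j]
    }
  }
  dimnames(loadings) <- dimnames(vec) <- list(colnames(z), paste0("PC", seq_len(p)))
  contribution <- 100 * lam / p
  retained <- sum(lam > retain_eigenvalue & seq_len(p) <= retain_max)
  structure(list(eigenvalues = lam, loadings = loadings,
                 score_coefficients = vec,
                 contribution = contribution, cumulative = cumsum(contribution),
                 retained = retained, retain_eigenvalue = retain_eigenvalue,
                 retain_max = retain_max,
                 center = attr(z, "center"), scale = attr(z, "scale")),
            class = "trait_pca")
}

#' @export
print.trait_pca <- function(x, digits = 2, ...) {
  k <- x$retained
  cat(sprintf("<trait_pca> %d traits, %d retained components (eigenvalue > %.2f, max %d)\n",
              nrow(x$loadings), k, x$retain_eigenvalue, x$retain_max))
  tab <- rbind(eigenvalue = x$eigenvalues[1:k],
               `contribution (%)` = x$contribution[1:k],
               `cumulative (%)` = x$cumulative[1:k])
  colnames(tab) <- paste0("PC", 1:k)
  print(round(tab, digits))
  invisible(x)
}

#' Component scores for accessions
#'
#' Projects normalized trait values onto the retained components:
#' \eqn{F_i = \sum_j c_{ji} z_j} with the unit-eigenvector score
#' coefficients, so each score column has sample variance equal to its
#' eigenvalue on the fitting data.
#'
#' @param z Normalized matrix whose columns match the PCA trait order.
#' @param pca A `trait_pca`.
#' @return Accession x component score matrix (`F1..Fk`, k = retained).
#' @export
component_scores <- function(z, pca) {
  stopifnot(inherits(pca, "trait_pca"))
  z <- as.matrix(z)
  if (!identical(colnames(z), rownames(pca$loadings)))
    pd_stop("trait columns do not align with the PCA trait order", "alignment_error")
  k <- pca$retained
  if (k < 1L) pd_stop("no retained components", "configuration_error")
  s <- z %*% pca$score_coefficients[, seq_len(k), drop = FALSE]
  colnames(s) <- paste0("F", seq_len(k))
  s
}
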