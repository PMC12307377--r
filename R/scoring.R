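#' Contribution-rate weights for the composite score
#'
#' Normalizes the retained components' contribution rates to weights
#' summing to 1: \eqn{w_i = rate_i / \sum rate}. With the published
#' 3-decimal rounding the printed weights sum to 0.999; rounding is
#' optional and off by default.
#'
#' @param contribution_rates Percent contribution rates of the retained
#'   components (all > 0).
#' @param digits Optional decimal places for rounding each weight.
#' @return Numeric weight vector.
#' @examples
#' w <- composite_weights(c(13.25, 9.08, 7.99, 7.17, 5.66,
#'                          4.62, 4.42, 4.27, 4.03, 3.82), digits = 3)
#' w[1]  # 0.206
#' w[5]  # 0.088
#' @export
composite_weights <- function(contribution_rates, digits = NULL) {
  if (!length(contribution_rates))
    pd_stop("no contribution rates supplied", "configuration_error")
  if (any(contribution_rates <= 0))
    pd_stop("contribution rates must be positive", "configuration_error")
  w <- contribution_rates / sum(contribution_rates)
  if (!is.null(digits)) w <- round(w, digits)
  w
}

#' Composite F-value
#'
#' Per-accession weighted sum of component scores:
#' \eqn{F = \sum_i w_i F_i}.
#'
#' @param scores Accession x component score matrix.
#' @param weights Weight vector, one per score column.
#' @return Numeric vector of composite F-values.
#' @export
composite_f <- function(scores, weights) {
  scores <- as.matrix(scores)
  if (ncol(scores) != length(weights))
    pd_stop(sprintf("%d score columns vs %d weights", ncol(scores), length(weights)),
            "alignment_error")
  drop(scores %*% weights)
}

#' Rank accessions by composite score
#'
#' Orders accessions by descending F. Ranks are dense with ties sharing
#' the smaller rank; within ties the order is ascending `accession_id`.
#'
#' @param f Composite F-values.
#' @param ids Accession ids (same length as `f`).
#' @param top_k Number of report rows to return (clamped to `length(f)`
#'   with a warning if larger).
#' @param table Optional `phenotype_table` supplying accession names and
#'   the quantitative trait columns for the report.
#' @return A data frame of the top `top_k` accessions: `rank`,
#'   `accession_id`, (optionally `accession_name` and quantitative
#'   traits), `F`.
#' @export
rank_accessions <- function(f, ids, top_k = length(f), table = NULL) {
  if (length(f) != length(ids))
    pd_stop("f and ids differ in length", "alignment_error")
  if (top_k > length(f)) {
    pd_warn(sprintf("top_k = %d exceeds n = %d; clamped", top_k, length(f)),
            "clamped_top_k")
    top_k <- length(f)
  }
  ord <- order(-f, ids)
  f_sorted <- f[ord]
  # dense ranking: ties share the smallest rank
  rk <- match(f_sorted, unique(f_sorted))
  out <- data.frame(rank = rk, accession_id = ids[ord], F = f_sorted,
                    stringsAsFactors = FALSE)
  if (!is.null(table)) {
    reg <- attr(table, "registry")
    extra <- as.data.frame(table)[match(out$accession_id, table$accession_id),
                                  c("accession_name", quantitative_traits(reg)),
                                  drop = FALSE]
    out <- cbind(out[c("rank", "accession_id")], extra["accession_name"],
                 F = out$F, extra[quantitative_traits(reg)])
  }
  rownames(out) <- NULL
  utils::head(out, top_k)
}

#' Normalize raw traits for scoring
#'
#' `"zscore"` centers and scales each trait ([standardize_traits()]);
#' `"membership"` applies the membership function
#' \eqn{u = (x - x_{min})/(x_{max} - x_{min})} mapping each trait onto
#' `[0, 1]`.
#'
#' @param table A `phenotype_table` or numeric matrix.
#' @param normalization `"zscore"` or `"membership"`.
#' @return Normalized matrix.
#' @export
normalize_traits <- function(table, normalization = c("zscore", "membership")) {
  normalization <- match.arg(normalization)
  if (normalization == "zscore") return(standardize_traits(table))
  m <- if (inherits(table, "phenotype_table")) trait_matrix(table) else as.matrix(table)
  lo <- apply(m, 2, min, na.rm = TRUE)
  hi <- apply(m, 2, max, na.rm = TRUE)
  if (any(hi - lo == 0))
    pd_stop(sprintf("zero-range trait(s): %s",
                    paste(colnames(m)[hi - lo == 0], collapse = ", ")),
            "degenerate_trait")
  u <- sweep(sweep(m, 2, lo), 2, hi - lo, "/")
  attr(u, "center") <- lo
  attr(u, "scale") <- hi - lo
  u
}

#' End-to-end composite scoring pipeline
#'
#' Normalization, correlation-matrix PCA, component scores, contribution
#' -rate weights, composite F and ranking in one call. PCA is always fit
#' on the correlation matrix (which is invariant to the per-trait affine
#' normalization); the chosen normalization determines the matrix the
#' score coefficients are applied to.
#'
#' @param table A validated `phenotype_table`.
#' @param normalization `"zscore"` (default) or `"membership"`.
#' @param retain_eigenvalue,retain_max Component retention knobs, see
#'   [trait_pca()].
#' @param weight_digits Optional rounding of weights (e.g. 3 to
#'   reproduce published 3-decimal weights); `NULL` for unrounded.
#' @param top_k Rows in the top-accession report.
#' @return A list of class `composite_scores`: `scores` (F1..Fk matrix),
#'   `weights`, `F` (named by accession), `ranking` (full table),
#'   `top` (top_k report with quantitative traits), and the underlying
#'   `pca`. Accessions with missing trait values are excluded from
#'   scoring; their ids are recorded in `excluded`.
#' @export
score_accessions <- function(table, normalization = c("zscore", "membership"),
                             retain_eigenvalue = 0.95, retain_max = 10L,
                             weight_digits = NULL, top_k = 10L) {
  stopifnot(inherits(table, "phenotype_table"))
  normalization <- match.arg(normalization)
  m <- trait_matrix(table)
  complete <- stats::complete.cases(m)
  excluded <- table$accession_id[!complete]
  if (length(excluded))
    message(sprintf("excluding %d accession(s) with missing traits from scoring",
                    length(excluded)))
  tab <- table[complete, , drop = FALSE]
  attr(tab, "registry") <- attr(table, "registry")
  class(tab) <- class(table)

  u <- normalize_traits(tab, normalization)
  z <- if (normalization == "zscore") u else standardize_traits(tab)
  pca <- trait_pca(z, retain_eigenvalue = retain_eigenvalue, retain_max = retain_max)
  scores <- component_scores(u, pca)
  weights <- composite_weights(pca$contribution[seq_len(pca$retained)],
                               digits = weight_digits)
  f <- composite_f(scores, weights)
  names(f) <- tab$accession_id
  ranking <- rank_accessions(f, tab$accession_id, top_k = length(f), table = tab)
  top <- utils::head(ranking, min(top_k, nrow(ranking)))
  structure(list(scores = scores, weights = weights, F = f, ranking = ranking,
                 top = top, pca = pca, normalization = normalization,
                 norm_center = attr(u, "center"), norm_scale = attr(u, "scale"),
                 excluded = excluded),
            class = "composite_scores")
}

#' @export
print.composite_scores <- function(x, ...) {
  cat(sprintf("<composite_scores> %d accessions, %d components, %s normalization\n",
              length(x$F), ncol(x$scores), x$normalization))
  cat("weights:", paste(sprintf("%.3f", x$weights), collapse = " "), "\n")
  cat("top accessions:\n")
  print(utils::head(x$top[, c("rank", "accession_id", "F")], 5), row.names = FALSE)
  invisible(x)
}
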