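#' Fit a full phenotypic-diversity evaluation
#'
#' The one-call interface: given a validated accession-by-trait table,
#' computes (i) the per-trait diversity report (descriptive statistics,
#' CV, 10-class and categorical Shannon-Wiener indices), (ii) the trait
#' correlation matrix with significance, (iii) the correlation-matrix
#' PCA with loadings, contribution rates and score coefficients, (iv)
#' contribution-rate-weighted composite F-values with accession ranking,
#' and (v) Ward hierarchical clustering with per-cluster trait profiles.
#'
#' @param table A `phenotype_table` (see [read_phenotype_table()] or
#'   [generate_cohort()]).
#' @param k Number of phenotype clusters.
#' @param linkage Clustering linkage, see [cluster_accessions()].
#' @param retain_eigenvalue,retain_max PCA retention knobs.
#' @param normalization Scoring normalization, `"zscore"` or
#'   `"membership"`.
#' @param weight_digits Optional rounding of composite weights.
#' @param top_k Rows in the top-accession report.
#' @param exclude_traits Trait(s) to drop from clustering only.
#' @return An object of class `phenodiv` with components `diversity`,
#'   `correlation`, `pca`, `scoring`, `clusters`, `profiles`, the input
#'   `table` and the matched `call`.
#' @examples
#' tab <- generate_cohort(n_accessions = 300, seed = 11)
#' fit <- phenodiv(tab, top_k = 5)
#' print(fit)
#' head(coef(fit))
#' @seealso [summary.phenodiv()], [predict.phenodiv()], [phenodiv_run()]
#' @export
phenodiv <- function(table, k = 5L, linkage = "ward",
                     retain_eigenvalue = 0.95, retain_max = 10L,
                     normalization = "zscore", weight_digits = NULL,
                     top_k = 10L, exclude_traits = NULL) {
  stopifnot(inherits(table, "phenotype_table"))
  diversity <- diversity_report(table)
  z <- standardize_traits(table)
  correlation <- trait_correlation(z)
  scoring <- score_accessions(table, normalization = normalization,
                              retain_eigenvalue = retain_eigenvalue,
                              retain_max = retain_max,
                              weight_digits = weight_digits, top_k = top_k)
  clusters <- cluster_accessions(table, k = k, linkage = linkage,
                                 exclude = exclude_traits)
  profiles <- cluster_profiles(table, clusters)
  structure(list(diversity = diversity, correlation = correlation,
                 pca = scoring$pca, scoring = scoring, clusters = clusters,
                 profiles = profiles, table = table, call = match.call()),
            class = "phenodiv")
}

#' @export
print.phenodiv <- function(x, ...) {
  reg <- attr(x$table, "registry")
  kinds <- registry_kinds(reg)
  cat(sprintf("Phenotypic diversity evaluation: %d accessions, %d traits (%d quantitative, %d qualitative)\n",
              nrow(x$table), length(reg), sum(kinds == "quantitative"),
              sum(kinds == "qualitative")))
  q <- x$diversity$quantitative
  cat(sprintf("Quantitative CV %.2f-%.2f%%, H' %.2f-%.2f; qualitative CV %.2f-%.2f%%, H' %.2f-%.2f\n",
              min(q$cv_percent), max(q$cv_percent), min(q$shannon), max(q$shannon),
              min(x$diversity$qualitative$cv_percent), max(x$diversity$qualitative$cv_percent),
              min(x$diversity$qualitative$shannon), max(x$diversity$qualitative$shannon)))
  k <- x$pca$retained
  cat(sprintf("PCA: %d retained components, cumulative contribution %.2f%%\n",
              k, x$pca$cumulative[k]))
  cat(sprintf("Clustering: %d groups of sizes %s (%s linkage)\n",
              x$clusters$k, paste(x$clusters$sizes, collapse = ", "),
              x$clusters$linkage))
  cat("Top accessions by composite F:\n")
  print(utils::head(x$scoring$top[, c("rank", "accession_id", "F")], 5),
        row.names = FALSE)
  invisible(x)
}

#' Summarize a phenotypic-diversity fit
#'
#' @param object A `phenodiv` fit.
#' @param ... Unused.
#' @return An object of class `summary.phenodiv` collecting the
#'   quantitative and qualitative diversity tables, the PCA eigenvalue /
#'   contribution table, composite weights, the top-accession report and
#'   cluster sizes.
#' @export
summary.phenodiv <- function(object, ...) {
  k <- object$pca$retained
  structure(list(
    n = nrow(object$table),
    quantitative = object$diversity$quantitative,
    qualitative = object$diversity$qualitative[, c("trait", "n", "cv_percent", "shannon")],
    pca_table = data.frame(component = paste0("PC", 1:k),
                           eigenvalue = object$pca$eigenvalues[1:k],
                           contribution = object$pca$contribution[1:k],
                           cumulative = object$pca$cumulative[1:k]),
    weights = object$scoring$weights,
    top = object$scoring$top,
    cluster_sizes = object$clusters$sizes),
    class = "summary.phenodiv")
}

#' @export
print.summary.phenodiv <- function(x, digits = 3, ...) {
  cat(sprintf("Phenotypic diversity evaluation of %d accessions\n\n", x$n))
  cat("Quantitative traits:\n")
  q <- x$quantitative; q[-1] <- lapply(q[-1], round, digits)
  print(q, row.names = FALSE)
  cat("\nQualitative traits:\n")
  ql <- x$qualitative; ql[-1] <- lapply(ql[-1], round, digits)
  print(ql, row.names = FALSE)
  cat("\nPrincipal components:\n")
  p <- x$pca_table; p[-1] <- lapply(p[-1], round, digits)
  print(p, row.names = FALSE)
  cat("\nComposite weights:", paste(round(x$weights, 3), collapse = " "), "\n")
  cat("\nTop accessions:\n")
  t <- x$top; t$F <- round(t$F, digits)
  print(t, row.names = FALSE)
  cat("\nCluster sizes:", paste(x$cluster_sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Extract PCA score coefficients from a fit
#'
#' @param object A `phenodiv` fit.
#' @param ... Unused.
#' @return The trait x retained-component score-coefficient matrix (the
#'   multipliers applied to normalized traits to obtain component
#'   scores).
#' @export
coef.phenodiv <- function(object, ...) {
  object$pca$score_coefficients[, seq_len(object$pca$retained), drop = FALSE]
}

#' Score new accessions against a fitted evaluation
#'
#' Applies the fitted normalization (centers/scales learned from the
#' fitting panel), score coefficients and composite weights to new
#' accessions.
#'
#' @param object A `phenodiv` fit.
#' @param newdata A `phenotype_table` (or data frame with the same trait
#'   columns); defaults to the fitting table.
#' @param ... Unused.
#' @return A data frame with `accession_id`, component scores `F1..Fk`
#'   and the composite `F`.
#' @export
predict.phenodiv <- function(object, newdata = NULL, ...) {
  newdata <- newdata %||% object$table
  reg <- attr(object$table, "registry")
  m <- if (inherits(newdata, "phenotype_table")) trait_matrix(newdata)
       else as.matrix(newdata[, names(reg), drop = FALSE])
  sc <- object$scoring
  # apply the normalization parameters learned on the fitting panel
  u <- sweep(sweep(m, 2, sc$norm_center), 2, sc$norm_scale, "/")
  f <- component_scores(u, object$pca)
  data.frame(accession_id = if (!is.null(newdata$accession_id)) as.character(newdata$accession_id)
             else rownames(m) %||% as.character(seq_len(nrow(m))),
             f, F = composite_f(f, sc$weights),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Diagnostic plots for a fit
#'
#' `which = "scree"` draws the eigenvalue scree with the retention
#' threshold; `"dendrogram"` the clustering tree; `"scores"` the
#' accessions on the first two component scores colored by cluster.
#'
#' @param x A `phenodiv` fit.
#' @param which One of `"scree"`, `"dendrogram"`, `"scores"`.
#' @param ... Passed to the underlying plotting function.
#' @export
plot.phenodiv <- function(x, which = c("scree", "dendrogram", "scores"), ...) {
  which <- match.arg(which)
  if (which == "scree") {
    graphics::plot(x$pca$eigenvalues, type = "b", xlab = "Component",
                   ylab = "Eigenvalue", main = "Eigenvalue scree", ...)
    graphics::abline(h = x$pca$retain_eigenvalue, lty = 2)
  } else if (which == "dendrogram") {
    graphics::plot(x$clusters$hclust, labels = FALSE, hang = -1,
                   main = sprintf("Accession dendrogram (%s linkage)", x$clusters$linkage),
                   xlab = "", sub = "", ...)
    stats::rect.hclust(x$clusters$hclust, k = x$clusters$k)
  } else {
    s <- x$scoring$scores
    lab <- x$clusters$assignments[rownames(s)]
    graphics::plot(s[, 1], s[, 2], col = lab, pch = 16,
                   xlab = "F1", ylab = "F2", main = "Component scores", ...)
    graphics::legend("topright", legend = paste("cluster", sort(unique(lab))),
                     col = sort(unique(lab)), pch = 16, cex = 0.8)
  }
  invisible(x)
}
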