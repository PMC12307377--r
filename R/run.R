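#' Run the full evaluation and write a report bundle
#'
#' Reproducible end-to-end run: reads an existing phenotype table or
#' simulates a cohort, fits [phenodiv()], and writes the complete output
#' bundle as delimited text — `table3.csv` / `table4.csv` (diversity),
#' `table5.csv` (loadings with eigenvalue / contribution / cumulative
#' footer rows), `table6.csv` (score coefficients), `table7.csv` (top
#' accessions), `correlations.csv` (long-format r and p),
#' `scores.csv` (per-accession component scores, F and rank),
#' `clusters.csv`, `cluster_profiles.csv`, `dendrogram.newick`, and a
#' `manifest.dcf` echoing the configuration, seed, package version and
#' row counts. Identical configuration and seed give identical bundles.
#'
#' @param out_dir Output directory (created; must be writable).
#' @param input Optional path to an existing phenotype table; when
#'   `NULL` a cohort is simulated.
#' @param n,seed Simulation size and master seed (ignored when `input`
#'   is given ... except that `seed` is still recorded).
#' @param registry Trait registry.
#' @param ... Further arguments passed to [phenodiv()].
#' @return Invisibly, a list with the `phenodiv` fit and the manifest.
#' @export
phenodiv_run <- function(out_dir, input = NULL, n = 1558L, seed = 42L,
                         registry = millet_traits(), ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0)
    pd_stop(sprintf("output directory not writable: %s", out_dir), "io_error")

  table <- if (is.null(input)) {
    generate_cohort(cohort_spec(n_accessions = n, seed = seed), registry = registry)
  } else {
    read_phenotype_table(input, registry = registry)
  }
  fit <- phenodiv(table, ...)

  write_phenotype_table(table, file.path(out_dir, "cohort.csv"))
  write_diversity_report(fit$diversity, out_dir)

  k <- fit$pca$retained
  cols <- paste0("PC", seq_len(k))
  t5 <- as.data.frame(fit$pca$loadings[, seq_len(k), drop = FALSE])
  t5 <- rbind(t5,
              Eigenvalue = fit$pca$eigenvalues[seq_len(k)],
              `Contribution rate (%)` = fit$pca$contribution[seq_len(k)],
              `Cumulative (%)` = fit$pca$cumulative[seq_len(k)])
  utils::write.csv(cbind(trait = rownames(t5), round(t5, 4)),
                   file.path(out_dir, "table5.csv"), row.names = FALSE)
  t6 <- fit$pca$score_coefficients[, seq_len(k), drop = FALSE]
  utils::write.csv(cbind(trait = rownames(t6), as.data.frame(round(t6, 4))),
                   file.path(out_dir, "table6.csv"), row.names = FALSE)

  r <- fit$correlation$r
  lower <- which(lower.tri(r), arr.ind = TRUE)
  utils::write.csv(data.frame(trait1 = colnames(r)[lower[, 2]],
                              trait2 = colnames(r)[lower[, 1]],
                              r = r[lower], p = fit$correlation$p[lower]),
                   file.path(out_dir, "correlations.csv"), row.names = FALSE)

  sc <- fit$scoring
  utils::write.csv(cbind(data.frame(accession_id = names(sc$F)),
                         as.data.frame(sc$scores), F = sc$F,
                         rank = sc$ranking$rank[match(names(sc$F), sc$ranking$accession_id)]),
                   file.path(out_dir, "scores.csv"), row.names = FALSE)
  utils::write.csv(sc$top, file.path(out_dir, "table7.csv"), row.names = FALSE)

  utils::write.csv(data.frame(accession_id = names(fit$clusters$assignments),
                              cluster = fit$clusters$assignments),
                   file.path(out_dir, "clusters.csv"), row.names = FALSE)
  utils::write.csv(fit$profiles, file.path(out_dir, "cluster_profiles.csv"),
                   row.names = FALSE)
  as_newick(fit$clusters, file.path(out_dir, "dendrogram.newick"))

  manifest <- c(
    package = "phenodiv",
    version = as.character(utils::packageVersion("phenodiv")),
    input = input %||% "simulated",
    seed = as.character(seed),
    accessions = as.character(nrow(table)),
    traits = as.character(length(registry)),
    retained_components = as.character(k),
    clusters = as.character(fit$clusters$k),
    linkage = fit$clusters$linkage,
    normalization = sc$normalization,
    files = paste(c("cohort.csv", "table3.csv", "table4.csv", "table5.csv",
                    "table6.csv", "table7.csv", "correlations.csv", "scores.csv",
                    "clusters.csv", "cluster_profiles.csv", "dendrogram.newick"),
                  collapse = ", "))
  write.dcf(t(as.matrix(manifest)), file.path(out_dir, "manifest.dcf"))
  invisible(list(fit = fit, manifest = as.list(manifest)))
}
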