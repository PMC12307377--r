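#' Hierarchical clustering of accessions
#'
#' Agglomerative clustering on Euclidean distances over standardized
#' traits, cut into `k` groups. Ward linkage (the `ward.D2` criterion:
#' merge the pair with minimal within-cluster variance increase, heights
#' on the distance scale) is the default; average and complete linkage
#' are available for sensitivity runs. Cluster labels are ordered by
#' descending cluster size, ties by the first member's accession id.
#'
#' @param x A `phenotype_table` or z-score matrix.
#' @param k Number of clusters to cut.
#' @param linkage `"ward"`, `"average"` or `"complete"`.
#' @param exclude Optional trait abbreviation(s) to drop before
#'   clustering (e.g. to run on 24 of the 25 traits).
#' @return An object of class `pheno_clusters`: `assignments` (named
#'   integer vector of labels 1..k), `sizes`, `k`, `linkage`,
#'   `merge_history` (data frame of merges with heights), and the
#'   underlying [stats::hclust()] object `hclust`.
#' @export
cluster_accessions <- function(x, k = 5L, linkage = c("ward", "average", "complete"),
                               exclude = NULL) {
  linkage <- match.arg(linkage)
  z <- if (inherits(x, "phenotype_table")) {
    traits <- setdiff(names(attr(x, "registry")), exclude)
    standardize_traits(x, traits)
  } else {
    m <- as.matrix(x)
    if (!is.null(exclude)) m <- m[, setdiff(colnames(m), exclude), drop = FALSE]
    m
  }
  n <- nrow(z)
  if (k < 1L || k > n)
    pd_stop(sprintf("k = %d outside 1..%d", k, n), "configuration_error")
  method <- c(ward = "ward.D2", average = "average", complete = "complete")[[linkage]]
  hc <- stats::hclust(stats::dist(z), method = method)
  raw <- stats::cutree(hc, k = k)
  ids <- rownames(z) %||% as.character(seq_len(n))
  names(raw) <- ids
  # relabel by descending size, ties by first-member id
  sizes <- table(raw)
  first_id <- vapply(names(sizes), function(lab) min(ids[raw == as.integer(lab)]),
                     character(1))
  ord <- order(-as.integer(sizes), first_id)
  relabel <- integer(length(sizes))
  relabel[as.integer(names(sizes))[ord]] <- seq_along(sizes)
  assignments <- relabel[raw]
  names(assignments) <- ids
  structure(list(assignments = assignments,
                 sizes = as.integer(table(assignments)), k = as.integer(k),
                 linkage = linkage,
                 merge_history = data.frame(left = hc$merge[, 1],
                                            right = hc$merge[, 2],
                                            height = hc$height),
                 hclust = hc),
            class = "pheno_clusters")
}

#' @export
print.pheno_clusters <- function(x, ...) {
  cat(sprintf("<pheno_clusters> %d accessions in %d groups (%s linkage)\n",
              length(x$assignments), x$k, x$linkage))
  cat("sizes:", paste(sprintf("%s=%d", seq_len(x$k), x$sizes), collapse = ", "), "\n")
  invisible(x)
}

#' Per-cluster trait profiles
#'
#' Summarizes each trait within each cluster (mean, SD, min, quartiles,
#' median, max, n), the tabular backing of per-cluster violin profiles.
#'
#' @param table A `phenotype_table`.
#' @param clusters A `pheno_clusters` whose assignments cover the table.
#' @param traits Optional subset of traits to profile (default: all).
#' @return A long data frame: `cluster`, `trait`, `n`, `mean`, `sd`,
#'   `min`, `q25`, `median`, `q75`, `max`.
#' @export
cluster_profiles <- function(table, clusters, traits = NULL) {
  stopifnot(inherits(table, "phenotype_table"), inherits(clusters, "pheno_clusters"))
  unknown <- setdiff(names(clusters$assignments), table$accession_id)
  if (length(unknown))
    pd_stop(sprintf("assignments name accession(s) absent from the table: %s",
                    paste(utils::head(unknown, 3), collapse = ", ")),
            "alignment_error")
  reg <- attr(table, "registry")
  traits <- traits %||% names(reg)
  lab <- clusters$assignments[table$accession_id]
  out <- do.call(rbind, lapply(sort(unique(lab)), function(cl) {
    rows <- which(lab == cl)
    do.call(rbind, lapply(traits, function(tr) {
      v <- table[[tr]][rows]
      v <- v[!is.na(v)]
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      data.frame(cluster = cl, trait = tr, n = length(v), mean = mean(v),
                 sd = if (length(v) > 1) stats::sd(v) else 0,
                 min = min(v), q25 = q[1], median = q[2], q75 = q[3],
                 max = max(v), stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Export a dendrogram in Newick format
#'
#' Serializes the merge history as a Newick tree: leaf labels are
#' accession ids and branch lengths derive from merge heights (each
#' branch spans the height difference between a node and its parent
#' merge).
#'
#' @param clusters A `pheno_clusters` (or an `hclust` object).
#' @param path Optional file to write to.
#' @return The Newick string, invisibly if written to `path`.
#' @export
as_newick <- function(clusters, path = NULL) {
  hc <- if (inherits(clusters, "pheno_clusters")) clusters$hclust else clusters
  stopifnot(inherits(hc, "hclust"))
  lab <- hc$labels %||% as.character(seq_len(nrow(hc$merge) + 1L))
  node <- function(i, parent_h) {
    if (i < 0) return(sprintf("%s:%.6g", lab[-i], parent_h))
    h <- hc$height[i]
    sprintf("(%s,%s):%.6g", node(hc$merge[i, 1], h), node(hc$merge[i, 2], h),
            parent_h - h)
  }
  root <- nrow(hc$merge)
  s <- sprintf("(%s,%s);", node(hc$merge[root, 1], hc$height[root]),
               node(hc$merge[root, 2], hc$height[root]))
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}
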