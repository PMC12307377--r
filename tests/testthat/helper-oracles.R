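# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# assign each value to its 10-class bin by linear scan over the 9 boundaries
oracle_ten_classes <- function(x) {
  m <- mean(x); s <- sd(x)
  b <- m + seq(-2, 2, by = 0.5) * s
  vapply(x, function(v) {
    if (v <= b[1]) return(1L)
    if (v >= b[9]) return(10L)
    j <- 1L
    while (j < 9L && !(v >= b[j] && v < b[j + 1])) j <- j + 1L
    j + 1L
  }, integer(1))
}

oracle_shannon <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

# exhaustive greedy Ward agglomeration: merge the pair with minimal
# within-cluster sum-of-squares increase; heights on the ward.D2 scale
# sqrt(2 * delta_SS)
oracle_ward <- function(x) {
  clusters <- lapply(seq_len(nrow(x)), function(i) i)
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      a <- clusters[[i]]; b <- clusters[[j]]
      ma <- colMeans(x[a, , drop = FALSE]); mb <- colMeans(x[b, , drop = FALSE])
      d <- (length(a) * length(b)) / (length(a) + length(b)) * sum((ma - mb)^2)
      if (d < best_d) { best_d <- d; best <- c(j, i) }
    }
    heights <- c(heights, sqrt(2 * best_d))
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
    lab <- integer(nrow(x))
    for (ci in seq_along(clusters)) lab[clusters[[ci]]] <- ci
    partitions[[as.character(length(clusters))]] <- lab  # keyed by cluster count
  }
  list(heights = heights, partitions = partitions)
}

# partition agreement invariant to label permutation
same_partition <- function(a, b) {
  identical(unname(as.integer(factor(a, levels = unique(a)))),
            unname(as.integer(factor(b, levels = unique(b)))))
}

# small helper: cohort restricted to a handful of accessions for I/O tests
tiny_table <- function(n = 3, seed = 99) {
  generate_cohort(cohort_spec(n_accessions = n, seed = seed))
}

# five-group fixture with centroids planted in every trait: quantitative
# means offset by +-2 published SDs (within-group SD 0.4x), qualitative
# distributions concentrated (0.85) on a group-specific category
planted_cohort <- function(seed_base = 100) {
  sizes <- c(322, 260, 283, 213, 480)
  shift <- matrix(c( 2,  2, -2,  0,  2,  2,  2, -2,  0,  0,  0,
                    -2,  0,  2,  2, -2,  0,  0,  2,  2, -2,  2,
                     0, -2,  0, -2,  0, -2,  2,  0, -2,  2, -2,
                     2, -2,  2, -2, -2,  2, -2,  2,  2,  2,  0,
                    -2,  2, -2,  2,  2, -2,  2, -2, -2, -2,  2),
                  5, 11, byrow = TRUE)
  t3 <- table3_targets()
  parts <- lapply(1:5, function(g) {
    qt <- t3
    qt$mean <- qt$mean + shift[g, ] * qt$sd
    qt$sd <- qt$sd * 0.4
    qt$min <- pmax(qt$mean - 10 * qt$sd, 0)
    qt$max <- qt$mean + 10 * qt$sd
    qual <- lapply(table4_targets(), function(p) {
      K <- length(p)
      q <- rep(0.15 / (K - 1), K)
      q[(g - 1) %% K + 1] <- 0.85
      q
    })
    p <- as.data.frame(generate_cohort(cohort_spec(
      n_accessions = sizes[g], quantitative = qt, qualitative = qual,
      seed = seed_base + g)))
    p$accession_id <- sprintf("G%d-%04d", g, seq_len(nrow(p)))
    p
  })
  tab <- phenotype_table(do.call(rbind, parts))
  list(table = tab,
       truth = stats::setNames(rep(1:5, sizes), tab$accession_id),
       sizes = sizes, shift = shift, targets = t3)
}
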