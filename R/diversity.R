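#' Descriptive variability statistics for one quantitative trait
#'
#' Mean, sample standard deviation (n-1 denominator), extremes, range
#' and coefficient of variation (CV = 100 * SD / mean).
#'
#' @param x Numeric vector of trait values; `NA`s are dropped.
#' @param trait Optional trait abbreviation carried into the result.
#' @return A one-row data frame with columns `trait`, `n`, `mean`, `sd`,
#'   `max`, `min`, `range`, `cv_percent`.
#' @examples
#' descriptive_stats(c(2, 4, 6, 8))  # mean 5, sd 2.582, cv 51.64
#' @export
descriptive_stats <- function(x, trait = NA_character_) {
  x <- x[!is.na(x)]
  if (length(x) < 2L)
    pd_stop("need at least 2 observations", "insufficient_data")
  data.frame(trait = trait, n = length(x), mean = mean(x), sd = stats::sd(x),
             max = max(x), min = min(x), range = max(x) - min(x),
             cv_percent = cv_percent(x), stringsAsFactors = FALSE)
}

#' Ten-class stratification and Shannon-Wiener index of a continuous trait
#'
#' Stratifies values into 10 classes anchored on the trait mean
#' \eqn{\bar X} and sample standard deviation \eqn{S}: class 1 is
#' \eqn{x \le \bar X - 2S}, class 10 is \eqn{x \ge \bar X + 2S}, and the
#' interior classes advance in 0.5 S steps, each half-open
#' \eqn{[lower, upper)} so that values exactly at the mean fall in
#' class 6. The Shannon-Wiener index \eqn{H' = -\sum P_i \ln P_i} is
#' computed over the occupied classes (with \eqn{0 \ln 0 := 0}).
#'
#' When the trait is constant (S = 0) the stratification is degenerate:
#' all mass is assigned to class 6, \eqn{H' = 0}, and a warning is
#' emitted.
#'
#' @param x Numeric vector; `NA`s dropped.
#' @param trait Optional trait abbreviation.
#' @return An object of class `class_profile`: a list with `trait`,
#'   `class_labels` (1..10), `counts`, `rel_freq`, `shannon`,
#'   `boundaries` (the 9 cut points), and `n`.
#' @export
stratify_ten_classes <- function(x, trait = NA_character_) {
  x <- x[!is.na(x)]
  if (length(x) < 2L)
    pd_stop("need at least 2 observations to stratify", "insufficient_data")
  m <- mean(x); s <- stats::sd(x)
  if (s == 0) {
    pd_warn(sprintf("constant trait%s: degenerate stratification, H' = 0",
                    if (is.na(trait)) "" else paste0(" ", trait)),
            "degenerate_stratification")
    counts <- integer(10); counts[6] <- length(x)
    return(structure(list(trait = trait, class_labels = 1:10, counts = counts,
                          rel_freq = counts / length(x), shannon = 0,
                          boundaries = rep(m, 9), n = length(x)),
                     class = "class_profile"))
  }
  b <- m + seq(-2, 2, by = 0.5) * s
  cls <- findInterval(x, b) + 1L
  cls[x <= b[1]] <- 1L
  cls[x >= b[9]] <- 10L
  counts <- tabulate(cls, nbins = 10L)
  structure(list(trait = trait, class_labels = 1:10, counts = counts,
                 rel_freq = counts / length(x), shannon = shannon_index(counts),
                 boundaries = b, n = length(x)),
            class = "class_profile")
}

#' @export
print.class_profile <- function(x, ...) {
  cat(sprintf("<class_profile>%s n=%d, H' = %.4f\n",
              if (is.na(x$trait)) "" else paste0(" ", x$trait), x$n, x$shannon))
  df <- data.frame(class = x$class_labels, count = x$counts,
                   freq = sprintf("%.2f%%", 100 * x$rel_freq))
  print(df[df$count > 0, ], row.names = FALSE)
  invisible(x)
}

#' Category profile and Shannon-Wiener index of a qualitative trait
#'
#' Tabulates category counts over the descriptor's full code set and
#' computes \eqn{H' = -\sum P_i \ln P_i} over the observed categories.
#'
#' @param codes Integer category codes; `NA`s dropped.
#' @param descriptor The trait's `trait_descriptor`.
#' @return An object of class `class_profile` whose `class_labels` are
#'   the descriptor's category codes.
#' @examples
#' d <- millet_traits()[["SZ"]]
#' p <- qualitative_profile(rep(1:3, c(989, 1, 568)), d)
#' round(p$shannon, 2)  # 0.66
#' @export
qualitative_profile <- function(codes, descriptor) {
  stopifnot(inherits(descriptor, "trait_descriptor"),
            descriptor$kind == "qualitative")
  codes <- codes[!is.na(codes)]
  if (!length(codes)) pd_stop("no observations", "insufficient_data")
  if (!all(codes %in% descriptor$codes))
    pd_stop(sprintf("codes outside descriptor set for %s", descriptor$abbreviation),
            "validation_error")
  counts <- tabulate(codes, nbins = max(descriptor$codes))
  structure(list(trait = descriptor$abbreviation, class_labels = descriptor$codes,
                 counts = counts, rel_freq = counts / length(codes),
                 shannon = shannon_index(counts), boundaries = NULL,
                 n = length(codes)),
            class = "class_profile")
}

#' Coefficient of variation of qualitative category codes
#'
#' The CV (percent, n-1 sample SD) of the integer codes themselves,
#' the convention used for reporting qualitative-trait variability
#' alongside quantitative CVs.
#'
#' @param codes Integer category codes.
#' @return CV in percent.
#' @examples
#' qualitative_cv(rep(1:4, c(1066, 235, 22, 235)))  # 66.20
#' @export
qualitative_cv <- function(codes) {
  cv_percent(codes)
}

#' Full diversity report for a phenotype table
#'
#' Computes, per trait, the descriptive statistics, 10-class (for
#' quantitative) or per-category (for qualitative) frequency profile,
#' coefficient of variation and Shannon-Wiener index, mirroring the
#' standard quantitative/qualitative diversity tables.
#'
#' @param table A `phenotype_table`.
#' @return A list of class `diversity_report` with elements
#'   `quantitative` (data frame: trait, mean, sd, max, min, range, CV,
#'   H'), `qualitative` (data frame: trait, CV, H', and `count (pct%)`
#'   cells per category), and `profiles` (named list of `class_profile`).
#' @export
diversity_report <- function(table) {
  stopifnot(inherits(table, "phenotype_table"))
  if (nrow(table) < 2L)
    pd_stop("need at least 2 accessions for a diversity report", "insufficient_data")
  reg <- attr(table, "registry")
  profiles <- list()

  qn <- quantitative_traits(reg)
  quant <- do.call(rbind, lapply(qn, function(tr) {
    x <- table[[tr]]
    st <- descriptive_stats(x, tr)
    pr <- stratify_ten_classes(x, tr)
    profiles[[tr]] <<- pr
    cbind(st, shannon = pr$shannon)
  }))

  ql <- qualitative_traits(reg)
  maxk <- max(vapply(reg[ql], function(d) length(d$codes), integer(1)))
  qual <- do.call(rbind, lapply(ql, function(tr) {
    codes <- table[[tr]]
    pr <- qualitative_profile(codes, reg[[tr]])
    profiles[[tr]] <<- pr
    cells <- sprintf("%d (%.2f%%)", pr$counts, 100 * pr$rel_freq)
    cells[pr$counts == 0] <- ""
    cells <- c(cells, rep("", maxk - length(cells)))
    out <- data.frame(trait = tr, n = pr$n,
                      cv_percent = qualitative_cv(codes),
                      shannon = pr$shannon, stringsAsFactors = FALSE)
    freq <- as.data.frame(as.list(cells), stringsAsFactors = FALSE)
    names(freq) <- paste0("class", seq_len(maxk))
    cbind(out, freq)
  }))

  structure(list(quantitative = quant, qualitative = qual, profiles = profiles),
            class = "diversity_report")
}

#' @export
print.diversity_report <- function(x, digits = 2, ...) {
  cat("Quantitative traits:\n")
  q <- x$quantitative
  q[-1] <- lapply(q[-1], round, digits)
  print(q, row.names = FALSE)
  cat("\nQualitative traits:\n")
  print(data.frame(trait = x$qualitative$trait,
                   cv_percent = round(x$qualitative$cv_percent, digits),
                   shannon = round(x$qualitative$shannon, digits)),
        row.names = FALSE)
  invisible(x)
}

#' Write a diversity report as delimited text
#'
#' Emits `table3.csv` (quantitative traits) and `table4.csv`
#' (qualitative traits with per-class "count (pct%)" cells) into a
#' directory.
#'
#' @param report A `diversity_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_diversity_report <- function(report, dir) {
  stopifnot(inherits(report, "diversity_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p3 <- file.path(dir, "table3.csv")
  p4 <- file.path(dir, "table4.csv")
  utils::write.csv(report$quantitative, p3, row.names = FALSE)
  utils::write.csv(report$qualitative, p4, row.names = FALSE)
  invisible(c(p3, p4))
}
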