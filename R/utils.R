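# internal helpers shared across modules

pd_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "phenodiv_error")))
}

pd_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "phenodiv_warning")))
}

# sample coefficient of variation, percent (n-1 denominator)
cv_percent <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L)
    pd_stop("need at least 2 observations for a CV", "insufficient_data")
  m <- mean(x)
  if (m == 0)
    pd_stop("CV undefined for zero mean", "zero_mean")
  100 * stats::sd(x) / m
}

# Shannon-Wiener index from class counts; 0*log(0) := 0
shannon_index <- function(counts) {
  if (any(counts < 0)) pd_stop("negative class count", "invalid_counts")
  n <- sum(counts)
  if (n == 0) pd_stop("no observations", "insufficient_data")
  p <- counts[counts > 0] / n
  -sum(p * log(p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
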