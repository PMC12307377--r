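#' Published marginal trait distributions for the 1,558-accession millet panel
#'
#' Summary statistics reported for a national panel of 1,558 foxtail
#' millet accessions, used as the default targets of the synthetic-cohort
#' generator. `table3_targets()` returns the per-trait mean, standard
#' deviation, minimum and maximum of the 11 quantitative traits;
#' `table4_counts()` the per-category accession counts of the 14
#' qualitative traits; `table4_targets()` the same counts normalized to
#' category probability vectors.
#'
#' @return `table3_targets()`: a data frame with columns `trait`, `mean`,
#'   `sd`, `min`, `max` (11 rows). `table4_counts()`: a named list of
#'   integer count vectors, one per qualitative trait, padded with zeros
#'   to the registry code set. `table4_targets()`: a named list of
#'   probability vectors (each sums to 1).
#' @examples
#' table3_targets()[table3_targets()$trait == "TGW", ]  # mean 3.11, sd 0.39
#' sum(table4_targets()$AC)                             # 1
#' @export
table3_targets <- function() {
  data.frame(
    trait = c("STC", "GP", "MPL", "MTL", "ST", "SSW", "SGW", "TGW", "L", "a", "b"),
    mean  = c(73.56, 111.99, 29.06, 129.51, 6.26, 98.90, 80.88, 3.11, 62.53, 6.77, 28.03),
    sd    = c(6.63, 4.63, 5.32, 20.04, 1.25, 27.21, 22.96, 0.39, 2.44, 1.13, 3.38),
    max   = c(99.00, 126.00, 51.63, 184.13, 10.69, 187.12, 161.76, 5.43, 71.30, 10.18, 35.77),
    min   = c(58.00, 102.00, 12.60, 67.50, 2.24, 10.36, 7.43, 2.05, 46.96, 0.97, 8.13),
    stringsAsFactors = FALSE)
}

#' @rdname table3_targets
#' @export
table4_counts <- function() {
  counts <- list(
    LSC = c(1035, 232, 291),
    SLC = c(1306, 252),
    SZ  = c(989, 1, 568),
    SS  = c(1066, 235, 22, 235),
    SE  = c(513, 308, 737),
    SNC = c(1547, 10, 0, 0),
    SL  = c(1105, 135, 314, 4),
    BC  = c(94, 1051, 413),
    AC  = c(569, 382, 607),
    HC  = c(7, 29, 20, 9, 77, 1398, 18),
    SLS = c(99, 1217, 227, 15),
    FLS = c(30, 352, 1176),
    TL  = c(272, 191, 1095),
    LR  = c(199, 216, 146, 758, 239))
  lapply(counts, as.integer)
}

#' @rdname table3_targets
#' @export
table4_targets <- function() {
  lapply(table4_counts(), function(cnt) cnt / sum(cnt))
}

#' Published PCA summary for the 1,558-accession millet panel
#'
#' The reported principal-component decomposition of the 25-trait
#' correlation matrix for the same panel: eigenvalues, contribution
#' rates (percent of total variance), cumulative rates, the trait-by
#' -component loading matrix, and the component score coefficient matrix
#' (unit eigenvector elements, i.e. loading divided by the square root of
#' the eigenvalue). Useful as reference input for weight derivation and
#' for consistency checks of the PCA conventions used here.
#'
#' @return A list with elements `eigenvalues`, `contribution`,
#'   `cumulative` (numeric vectors of length 10), and `loadings`,
#'   `coefficients` (25 x 10 matrices with trait rownames).
#' @export
millet_reference_pca <- function() {
  read_mat <- function(f) {
    p <- system.file("extdata", f, package = "phenodiv", mustWork = TRUE)
    as.matrix(utils::read.csv(p, row.names = 1, check.names = FALSE))
  }
  list(
    eigenvalues  = c(3.31, 2.27, 2.00, 1.79, 1.41, 1.16, 1.11, 1.07, 1.01, 0.95),
    contribution = c(13.25, 9.08, 7.99, 7.17, 5.66, 4.62, 4.42, 4.27, 4.03, 3.82),
    cumulative   = c(13.25, 22.33, 30.32, 37.49, 43.14, 47.77, 52.19, 56.46, 60.48, 64.30),
    loadings     = read_mat("millet_panel_pca_loadings.csv"),
    coefficients = read_mat("millet_panel_score_coefficients.csv"))
}

#' @rdname table3_targets
#' @export
material_class_counts <- function() {
  c(landrace = 847L, breeding_line = 432L, selected_cultivar = 256L,
    genetic_stock = 4L, other = 19L)
}
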