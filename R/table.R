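ID_COLUMNS <- c("accession_id", "accession_name", "material_class")

MATERIAL_CLASSES <- c("landrace", "breeding_line", "selected_cultivar",
                      "genetic_stock", "other")

#' Construct and validate a phenotype table
#'
#' A phenotype table is a data frame with one row per accession: three
#' identity columns (`accession_id`, `accession_name`, `material_class`)
#' followed by one numeric column per registered trait. Qualitative traits
#' are stored as their integer category codes. Validation checks column
#' completeness, uniqueness of accession ids, numeric values, and
#' membership of qualitative codes in each descriptor's code set; `NA`
#' marks an explicitly missing value.
#'
#' @param data A data frame carrying the identity and trait columns.
#' @param registry A `trait_registry`; defaults to [millet_traits()].
#' @return A data frame of class `phenotype_table` with the registry
#'   attached as attribute `"registry"`.
#' @export
phenotype_table <- function(data, registry = millet_traits()) {
  stopifnot(is.data.frame(data), inherits(registry, "trait_registry"))
  data <- as.data.frame(data, stringsAsFactors = FALSE)

  missing_cols <- setdiff(c(ID_COLUMNS, names(registry)), names(data))
  if (length(missing_cols))
    pd_stop(sprintf("missing required column(s): %s", paste(missing_cols, collapse = ", ")),
            "schema_error")
  data <- data[, c(ID_COLUMNS, names(registry))]

  data$accession_id <- as.character(data$accession_id)
  if (anyDuplicated(data$accession_id))
    pd_stop(sprintf("duplicate accession_id: %s",
                    paste(unique(data$accession_id[duplicated(data$accession_id)]), collapse = ", ")),
            "validation_error")
  bad_class <- !is.na(data$material_class) & !(data$material_class %in% MATERIAL_CLASSES)
  if (any(bad_class))
    pd_stop(sprintf("unknown material_class '%s' (row %d)",
                    data$material_class[which(bad_class)[1]], which(bad_class)[1]),
            "validation_error")

  for (tr in names(registry)) {
    v <- data[[tr]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(as.character(v)))
      bad <- which(is.na(vn) & !is.na(v) & trimws(as.character(v)) != "")
      if (length(bad))
        pd_stop(sprintf("non-numeric value '%s' in column %s, row %d (accession %s)",
                        as.character(v[bad[1]]), tr, bad[1], data$accession_id[bad[1]]),
                "parse_error")
      v <- vn
      data[[tr]] <- v
    }
    bad <- which(!is.na(v) & !is.finite(v))
    if (length(bad))
      pd_stop(sprintf("non-finite value in column %s, row %d", tr, bad[1]), "validation_error")
    d <- registry[[tr]]
    if (d$kind == "qualitative") {
      bad <- which(!is.na(v) & !(v %in% d$codes))
      if (length(bad))
        pd_stop(sprintf(
          "qualitative code %s outside allowed set {%s} in column %s, row %d (accession %s)",
          format(v[bad[1]]), paste(d$codes, collapse = ","), tr, bad[1],
          data$accession_id[bad[1]]), "validation_error")
    } else {
      bad <- which(!is.na(v) & v < 0)
      if (length(bad))
        pd_stop(sprintf("negative value in quantitative column %s, row %d", tr, bad[1]),
                "validation_error")
    }
  }
  structure(data, registry = registry,
            class = c("phenotype_table", "data.frame"))
}

#' @export
print.phenotype_table <- function(x, ...) {
  reg <- attr(x, "registry")
  kinds <- registry_kinds(reg)
  cat(sprintf("<phenotype_table> %d accessions x %d traits (%d quantitative, %d qualitative)\n",
              nrow(x), length(reg), sum(kinds == "quantitative"), sum(kinds == "qualitative")))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6))
  invisible(x)
}

#' Read / write a delimited phenotype table
#'
#' Reads a delimited text file (comma by default, any single-character
#' delimiter accepted) whose header carries the identity columns and the
#' registry abbreviations (matched case-insensitively), validates it
#' against the registry, and returns a [phenotype_table()]. Rows violating
#' a qualitative code set are rejected with the offending cell named.
#'
#' @param path File path.
#' @param registry A `trait_registry`.
#' @param sep Field delimiter.
#' @return `read_phenotype_table()` returns a `phenotype_table`;
#'   `write_phenotype_table()` returns `path` invisibly.
#' @export
read_phenotype_table <- function(path, registry = millet_traits(), sep = ",") {
  if (!file.exists(path)) pd_stop(sprintf("file not found: %s", path), "io_error")
  raw <- utils::read.table(path, header = TRUE, sep = sep, colClasses = "character",
                           check.names = FALSE, fileEncoding = "UTF-8",
                           stringsAsFactors = FALSE)
  # case-insensitive header resolution
  want <- c(ID_COLUMNS, names(registry))
  idx <- match(tolower(want), tolower(names(raw)))
  if (anyNA(idx))
    pd_stop(sprintf("missing required column(s): %s",
                    paste(want[is.na(idx)], collapse = ", ")), "schema_error")
  raw <- raw[, idx]
  names(raw) <- want
  phenotype_table(raw, registry)
}

#' @rdname read_phenotype_table
#' @param x A `phenotype_table`.
#' @export
write_phenotype_table <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "phenotype_table"))
  utils::write.table(as.data.frame(x), path, sep = sep, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Average yearly observations into a single phenotype table
#'
#' Trait values are consolidated across observation years: quantitative
#' traits take the arithmetic mean of the available years; qualitative
#' traits take the modal code, with ties broken in favour of the code
#' recorded in the earliest tied year.
#'
#' @param observations A data frame with columns `accession_id`, `year`,
#'   optionally `accession_name` and `material_class`, and one column per
#'   registered trait; one row per accession-year.
#' @param registry A `trait_registry`.
#' @return A `phenotype_table` with one row per accession.
#' @export
average_years <- function(observations, registry = millet_traits()) {
  need <- c("accession_id", "year", names(registry))
  missing_cols <- setdiff(need, names(observations))
  if (length(missing_cols))
    pd_stop(sprintf("yearly observations missing column(s): %s",
                    paste(missing_cols, collapse = ", ")), "schema_error")
  observations <- observations[order(observations$year), , drop = FALSE]
  ids <- unique(observations$accession_id)
  kinds <- registry_kinds(registry)

  one <- function(id) {
    rows <- observations[observations$accession_id == id, , drop = FALSE]
    vals <- lapply(names(registry), function(tr) {
      v <- rows[[tr]]
      keep <- !is.na(v)
      if (!any(keep)) return(NA_real_)
      v <- v[keep]
      if (kinds[[tr]] == "quantitative") return(mean(v))
      tab <- table(v)
      top <- names(tab)[tab == max(tab)]
      # earliest-year tie-break: rows are year-sorted, take first occurrence
      as.numeric(v[v %in% as.numeric(top)][1])
    })
    names(vals) <- names(registry)
    c(list(accession_id = id,
           accession_name = if ("accession_name" %in% names(rows)) rows$accession_name[1] else id,
           material_class = if ("material_class" %in% names(rows)) rows$material_class[1] else "other"),
      vals)
  }
  out <- do.call(rbind, lapply(ids, function(id) as.data.frame(one(id), stringsAsFactors = FALSE)))
  phenotype_table(out, registry)
}

# numeric trait matrix (accessions x traits), rownames = accession ids
trait_matrix <- function(table, traits = NULL) {
  stopifnot(inherits(table, "phenotype_table"))
  reg <- attr(table, "registry")
  traits <- traits %||% names(reg)
  m <- as.matrix(as.data.frame(table)[, traits, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- table$accession_id
  m
}
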