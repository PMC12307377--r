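#' Trait descriptor
#'
#' A descriptor fixes the identity of one phenotypic trait: its full name,
#' the abbreviation used as a column header, whether it is measured on a
#' continuous scale or scored against an ordered list of integer category
#' codes, and its units.
#'
#' @param name Full trait name.
#' @param abbreviation Short unique code used as the column header
#'   (e.g. `"MPL"` for main spike length).
#' @param kind `"quantitative"` or `"qualitative"`.
#' @param units Measurement units for quantitative traits (`"d"`, `"cm"`,
#'   `"mm"`, `"g"`, or `""` for dimensionless scores).
#' @param labels Character vector of category labels for qualitative
#'   traits; the integer codes are `seq_along(labels)` (codes always start
#'   at 1 and are consecutive). Must be `NULL` for quantitative traits.
#' @return An object of class `trait_descriptor`.
#' @export
trait_descriptor <- function(name, abbreviation, kind = c("quantitative", "qualitative"),
                             units = "", labels = NULL) {
  kind <- match.arg(kind)
  if (kind == "quantitative" && !is.null(labels))
    pd_stop(sprintf("quantitative trait '%s' must not carry category labels", abbreviation),
            "invalid_descriptor")
  if (kind == "qualitative" && (is.null(labels) || length(labels) < 2L))
    pd_stop(sprintf("qualitative trait '%s' needs at least two category labels", abbreviation),
            "invalid_descriptor")
  structure(
    list(name = name, abbreviation = abbreviation, kind = kind, units = units,
         codes = if (kind == "qualitative") seq_along(labels) else integer(0),
         labels = labels %||% character(0)),
    class = "trait_descriptor")
}

#' @export
print.trait_descriptor <- function(x, ...) {
  cat(sprintf("<trait> %s (%s), %s", x$abbreviation, x$name, x$kind))
  if (x$kind == "quantitative") {
    if (nzchar(x$units)) cat(sprintf(" [%s]", x$units))
  } else {
    cat(": ", paste(sprintf("%d=%s", x$codes, x$labels), collapse = "; "), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Build a trait registry
#'
#' A registry is a named, validated collection of [trait_descriptor()]s;
#' abbreviations must be unique and become the names of the list.
#'
#' @param ... Trait descriptors.
#' @return An object of class `trait_registry`.
#' @export
trait_registry <- function(...) {
  traits <- list(...)
  if (length(traits) == 1L && is.list(traits[[1]]) && !inherits(traits[[1]], "trait_descriptor"))
    traits <- traits[[1]]
  ok <- vapply(traits, inherits, logical(1), "trait_descriptor")
  if (!all(ok)) pd_stop("all registry entries must be trait descriptors", "invalid_registry")
  abbr <- vapply(traits, `[[`, character(1), "abbreviation")
  if (anyDuplicated(abbr))
    pd_stop(sprintf("duplicate abbreviation(s): %s",
                    paste(unique(abbr[duplicated(abbr)]), collapse = ", ")),
            "invalid_registry")
  names(traits) <- abbr
  structure(traits, class = "trait_registry")
}

#' @export
print.trait_registry <- function(x, ...) {
  kinds <- vapply(x, `[[`, character(1), "kind")
  cat(sprintf("<trait_registry> %d traits (%d quantitative, %d qualitative)\n",
              length(x), sum(kinds == "quantitative"), sum(kinds == "qualitative")))
  for (d in x) print(d)
  invisible(x)
}

#' The 25-trait foxtail millet registry
#'
#' The default descriptor set used for foxtail millet germplasm panels:
#' 11 quantitative traits (phenology, plant architecture, yield components
#' and CIELAB grain color) and 14 qualitative traits scored as small
#' integer codes against standard descriptor lists. Hull color is coded
#' 1-7 (White, Orange, Brown, Black, Red, Yellow, Cyan).
#'
#' @return A `trait_registry` with 25 descriptors.
#' @examples
#' reg <- millet_traits()
#' length(reg)                # 25
#' reg[["STC"]]$units         # "d"
#' length(reg[["HC"]]$codes)  # 7
#' @export
millet_traits <- function() {
  trait_registry(
    trait_descriptor("Seedling-to-spike period", "STC", "quantitative", "d"),
    trait_descriptor("Growth period",            "GP",  "quantitative", "d"),
    trait_descriptor("Main spike length",        "MPL", "quantitative", "cm"),
    trait_descriptor("Main stem length",         "MTL", "quantitative", "cm"),
    trait_descriptor("Stem thickness",           "ST",  "quantitative", "mm"),
    trait_descriptor("Single-spike weight",      "SSW", "quantitative", "g"),
    trait_descriptor("Single-spike grain weight","SGW", "quantitative", "g"),
    trait_descriptor("1000-grain weight",        "TGW", "quantitative", "g"),
    trait_descriptor("Grain L*",                 "L",   "quantitative", ""),
    trait_descriptor("Grain a*",                 "a",   "quantitative", ""),
    trait_descriptor("Grain b*",                 "b",   "quantitative", ""),
    trait_descriptor("Leaf sheath color",  "LSC", "qualitative",
                     labels = c("Green", "Red", "Violet")),
    trait_descriptor("Seedling leaf color","SLC", "qualitative",
                     labels = c("Green", "Yellow-Green")),
    trait_descriptor("Stargazer color",    "SZ",  "qualitative",
                     labels = c("Yellow", "Green", "Violet")),
    trait_descriptor("Spike shape",        "SS",  "qualitative",
                     labels = c("Fusiform", "Spikelet style", "Cat's paw style", "Cylindrical style")),
    trait_descriptor("Spike elasticity",   "SE",  "qualitative",
                     labels = c("Compact", "Intermediate", "Relaxed")),
    trait_descriptor("Spike neck shape",   "SNC", "qualitative",
                     labels = c("Erect", "Medium bend", "Hooked bend", "Curved")),
    trait_descriptor("Seta length",        "SL",  "qualitative",
                     labels = c("Short", "Very short", "Long", "Very long")),
    trait_descriptor("Bristle color",      "BC",  "qualitative",
                     labels = c("Yellow", "Green", "Violet")),
    trait_descriptor("Anther color",       "AC",  "qualitative",
                     labels = c("White", "Orange", "Yellow")),
    trait_descriptor("Hull color",         "HC",  "qualitative",
                     labels = c("White", "Orange", "Brown", "Black", "Red", "Yellow", "Cyan")),
    trait_descriptor("Seedling leaf shape","SLS", "qualitative",
                     labels = c("Semi-erect", "Erect", "Horizontal", "Downslope")),
    trait_descriptor("Flowering leaf shape","FLS","qualitative",
                     labels = c("Erect", "Horizontal", "Downslope")),
    trait_descriptor("Tillering character","TL",  "qualitative",
                     labels = c("Strong", "Moderate", "Weak")),
    trait_descriptor("Lodging resistance", "LR",  "qualitative",
                     labels = c("Weak", "Very weak", "Moderate", "Strong", "Very strong"))
  )
}

#' Export or import a trait registry as a plain-text config
#'
#' Registries round-trip through Debian-control-style records (one block
#' per trait, blank-line separated), a human-editable key-value format.
#'
#' @param registry A `trait_registry`.
#' @param path File to write to / read from.
#' @return `read_registry()` returns a `trait_registry`;
#'   `write_registry()` returns `path` invisibly.
#' @export
write_registry <- function(registry, path) {
  stopifnot(inherits(registry, "trait_registry"))
  recs <- do.call(rbind, lapply(registry, function(d) {
    c(name = d$name, abbreviation = d$abbreviation, kind = d$kind,
      units = d$units, labels = paste(d$labels, collapse = "; "))
  }))
  write.dcf(recs, file = path)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  recs <- read.dcf(path, fields = c("name", "abbreviation", "kind", "units", "labels"))
  traits <- lapply(seq_len(nrow(recs)), function(i) {
    rec <- unname(recs[i, ])
    names(rec) <- colnames(recs)
    labs <- rec[["labels"]]
    labs <- if (is.na(labs) || !nzchar(labs)) NULL else trimws(strsplit(labs, ";")[[1]])
    trait_descriptor(unname(rec[["name"]]), unname(rec[["abbreviation"]]),
                     unname(rec[["kind"]]),
                     if (is.na(rec[["units"]])) "" else unname(rec[["units"]]), labs)
  })
  trait_registry(traits)
}

registry_kinds <- function(registry) vapply(registry, `[[`, character(1), "kind")

quantitative_traits <- function(registry) names(registry)[registry_kinds(registry) == "quantitative"]
qualitative_traits  <- function(registry) names(registry)[registry_kinds(registry) == "qualitative"]
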