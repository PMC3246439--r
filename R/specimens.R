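#' Specimen metadata tables
#'
#' A specimen record carries the classical measurements and labels used by
#' the reduction statistics: `specimen_id`, `assemblage`, `collection_class`
#' (`"excavated"` or `"surface"`), `retouched` (Bordes types 6 and above),
#' an optional integer Bordes `type_code`, and the `length`, `tip_length`
#' and `tang_length` measurements in the outline's planar units.
#'
#' `as_specimens()` validates the vocabulary and the measurement
#' invariants: tip and tang lengths must be nonnegative, and when all three
#' lengths are present `length` must equal `tip_length + tang_length`
#' within `tol` (relative), otherwise a warning names the specimens.
#'
#' @param x A data frame of specimen records.
#' @param tol Relative tolerance for the length decomposition check.
#' @return A validated specimen tibble.
#' @export
as_specimens <- function(x, tol = 0.05) {
  required <- c("specimen_id", "assemblage", "collection_class", "retouched")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0(
      "specimen table is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ), class = "tangmorph_format_error")
  }
  out <- tibble::as_tibble(x)
  out$specimen_id <- as.character(out$specimen_id)
  bad_class <- setdiff(unique(out$collection_class), c("excavated", "surface"))
  if (length(bad_class) > 0) {
    rlang::abort(paste0(
      "collection_class must be 'excavated' or 'surface'; found: ",
      paste(bad_class, collapse = ", ")
    ), class = "tangmorph_format_error")
  }
  out$retouched <- as.logical(out$retouched)
  for (col in c("length", "tip_length", "tang_length")) {
    if (!col %in% names(out)) out[[col]] <- NA_real_
  }
  neg <- out$specimen_id[
    (!is.na(out$tip_length) & out$tip_length < 0) |
      (!is.na(out$tang_length) & out$tang_length < 0)
  ]
  if (length(neg) > 0) {
    rlang::abort(paste0(
      "negative tip or tang length for specimen(s): ",
      paste(neg, collapse = ", ")
    ), class = "tangmorph_format_error")
  }
  full <- !is.na(out$length) & !is.na(out$tip_length) & !is.na(out$tang_length)
  off <- full & abs(out$length - (out$tip_length + out$tang_length)) >
    tol * pmax(out$length, .Machine$double.eps)
  if (any(off)) {
    rlang::warn(paste0(
      "length != tip_length + tang_length beyond tolerance for: ",
      paste(out$specimen_id[off], collapse = ", ")
    ))
  }
  out
}

#' @rdname as_specimens
#' @param path Path to a comma-delimited specimen table with a header row.
#' @export
read_specimens <- function(path, tol = 0.05) {
  as_specimens(readr::read_csv(path, show_col_types = FALSE), tol = tol)
}

#' @rdname as_specimens
#' @param specimens A specimen tibble.
#' @export
write_specimens <- function(specimens, path) {
  readr::write_csv(as_specimens(specimens), path)
  invisible(path)
}

#' Aterian assemblage sample sizes
#'
#' The published per-assemblage sample sizes of the aggregate Aterian
#' tanged-tool sample (seven excavated assemblages and twelve surface
#' collections from museum holdings), shipped as a plain-text table. The
#' excavated and surface subtotals are 395 and 112 specimens, 507 in total.
#'
#' @return A tibble with columns `assemblage`, `n`, `country`,
#'   `collection_class`.
#' @export
aterian_assemblages <- function() {
  path <- system.file("extdata", "aterian_assemblages.csv",
    package = "tangmorph", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}
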