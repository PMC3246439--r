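#' Outline tables
#'
#' An outline is an ordered, implicitly closed sequence of planar points
#' tracing one specimen's silhouette: the last point connects back to the
#' first and the first point is not repeated. Outlines travel through the
#' package as long tibbles with columns `specimen_id`, `point_index`, `x`,
#' `y`, one block of rows per specimen, so that every verb is a plain
#' data-frame-in / tibble-out operation.
#'
#' `as_outlines()` validates a data frame and brings it into this canonical
#' form: points are ordered by `point_index`, consecutive duplicate points
#' (a common digitization artifact, including a repeated closing point) are
#' dropped with a warning, and any specimen left with fewer than 8 distinct
#' points or a degenerate (zero-area) contour is an error naming the
#' offending specimens.
#'
#' @param x A data frame with columns `specimen_id`, `point_index`, `x`, `y`.
#' @return A tibble with columns `specimen_id`, `point_index`, `x`, `y`.
#' @export
as_outlines <- function(x) {
  required <- c("specimen_id", "point_index", "x", "y")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0(
      "outline table is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ), class = "tangmorph_format_error")
  }
  out <- tibble::as_tibble(x)[required]
  out$specimen_id <- as.character(out$specimen_id)
  out <- dplyr::arrange(out, .data$specimen_id, .data$point_index)

  dropped <- character(0)
  pieces <- lapply(split(out, out$specimen_id), function(df) {
    xy <- cbind(df$x, df$y)
    n <- nrow(xy)
    dup <- c(FALSE, rowSums(abs(xy[-1, , drop = FALSE] -
                                  xy[-n, , drop = FALSE])) == 0)
    # the implicit closing segment: a repeated first point is also a duplicate
    if (!dup[n] && n > 1 && all(xy[n, ] == xy[1, ])) dup[n] <- TRUE
    if (any(dup)) {
      dropped <<- c(dropped, df$specimen_id[1])
      df <- df[!dup, , drop = FALSE]
    }
    df$point_index <- seq_len(nrow(df))
    df
  })
  if (length(dropped) > 0) {
    rlang::warn(paste0(
      "dropped duplicated consecutive points for specimen(s): ",
      paste(unique(dropped), collapse = ", ")
    ))
  }
  out <- dplyr::bind_rows(pieces)

  counts <- table(out$specimen_id)
  bad <- names(counts)[counts < 8]
  if (length(bad) > 0) {
    rlang::abort(paste0(
      "degenerate outline(s) with fewer than 8 distinct points: ",
      paste(bad, collapse = ", ")
    ), class = "tangmorph_degenerate_outline")
  }
  flat <- names(which(vapply(
    split(out, out$specimen_id),
    function(df) abs(polygon_signed_area(cbind(df$x, df$y))) <=
      .Machine$double.eps,
    logical(1)
  )))
  if (length(flat) > 0) {
    rlang::abort(paste0(
      "outline(s) with zero signed area: ", paste(flat, collapse = ", ")
    ), class = "tangmorph_degenerate_outline")
  }
  out
}

# Split an outline tibble into a named list of n x 2 coordinate matrices,
# preserving first-appearance order of specimens.
outline_split <- function(outlines) {
  ids <- unique(outlines$specimen_id)
  lapply(stats::setNames(ids, ids), function(id) {
    df <- outlines[outlines$specimen_id == id, ]
    df <- df[order(df$point_index), ]
    cbind(x = df$x, y = df$y)
  })
}

# Rebuild the canonical tibble from a named list of coordinate matrices.
outline_bind <- function(mats) {
  dplyr::bind_rows(purrr::imap(mats, function(xy, id) {
    tibble::tibble(
      specimen_id = id,
      point_index = seq_len(nrow(xy)),
      x = xy[, 1],
      y = xy[, 2]
    )
  }))
}

#' Read and write outline tables
#'
#' The on-disk format is a comma-delimited table with a header row and
#' columns `specimen_id`, `point_index`, `x`, `y`, points grouped by
#' specimen and ordered by `point_index`.
#'
#' @param path Path to a delimited outline table.
#' @return `read_outlines()` returns the validated outline tibble;
#'   `write_outlines()` returns `path` invisibly.
#' @export
read_outlines <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  as_outlines(df)
}

#' @rdname read_outlines
#' @param outlines An outline tibble (see [as_outlines()]).
#' @export
write_outlines <- function(outlines, path) {
  readr::write_csv(as_outlines(outlines), path)
  invisible(path)
}

# Equal arc-length resampling of one polygon, relaxed to a fixed point so
# that resampling is idempotent: after convergence every segment of the
# result has the same length, so resampling the result reproduces it.
resample_xy <- function(xy, n_points, tol = 1e-12, max_iter = 512) {
  cur <- xy
  for (it in seq_len(max_iter)) {
    closed <- rbind(cur, cur[1, ])
    seg <- sqrt(diff(closed[, 1])^2 + diff(closed[, 2])^2)
    cs <- c(0, cumsum(seg))
    total <- cs[length(cs)]
    if (total <= 0) {
      rlang::abort("cannot resample a zero-perimeter outline",
        class = "tangmorph_degenerate_outline")
    }
    s <- total * (seq_len(n_points) - 1) / n_points
    ix <- findInterval(s, cs, rightmost.closed = TRUE)
    ix[ix > nrow(cur)] <- nrow(cur)
    frac <- (s - cs[ix]) / seg[ix]
    frac[!is.finite(frac)] <- 0
    nxt <- cbind(
      closed[ix, 1] + frac * (closed[ix + 1, 1] - closed[ix, 1]),
      closed[ix, 2] + frac * (closed[ix + 1, 2] - closed[ix, 2])
    )
    if (nrow(cur) == n_points && max(abs(nxt - cur)) < tol) {
      return(nxt)
    }
    cur <- nxt
  }
  cur
}

#' Resample outlines to equally spaced points
#'
#' Returns each outline as `n_points` points equally spaced by arc length
#' along the closed polygon, keeping the original start point. The spacing
#' is relaxed to a fixed point (a few passes of re-spacing) so that
#' resampling an already-resampled outline reproduces it exactly; the
#' perimeter is preserved to well within 0.1 %.
#'
#' @param outlines An outline tibble.
#' @param n_points Number of points per outline, at least 32. The default of
#'   512 comfortably supports an 11-harmonic Fourier fit.
#' @return An outline tibble with `n_points` rows per specimen.
#' @export
resample_outlines <- function(outlines, n_points = 512) {
  if (n_points < 32) {
    rlang::abort("n_points must be at least 32",
      class = "tangmorph_parameter_error")
  }
  outlines <- as_outlines(outlines)
  outline_bind(lapply(outline_split(outlines), resample_xy,
    n_points = n_points))
}

#' Orient outlines tang-left and counterclockwise
#'
#' Brings every outline into the analysis convention: counterclockwise
#' traversal (positive signed area) with the tang — the narrow hafted end —
#' at smaller x. With `tang_side = "auto"` the tang is taken to be the
#' narrower end, comparing the mean half-width of the outer 25 % of the
#' x-extent on each side; a tie within 1 % is an error asking for an
#' explicit hint. With `"left"` or `"right"` the outline is rotated 180
#' degrees about its centroid when the detected tang is on the other side
#' (an undetectable, symmetric outline is left as-is). With `"asis"` the
#' input is trusted to follow the tang-left digitization convention
#' already and only the traversal direction is normalized — the detector
#' cannot tell a narrow stem from a pointed tip, so pre-oriented material
#' should never be re-detected.
#'
#' @param outlines An outline tibble.
#' @param tang_side `"auto"`, `"left"`, `"right"`, or `"asis"`: the side
#'   the tang should face after orientation (the analysis convention is
#'   left), or `"asis"` to keep the input's side.
#' @return An outline tibble.
#' @export
orient_outlines <- function(outlines,
                            tang_side = c("auto", "left", "right", "asis")) {
  tang_side <- match.arg(tang_side)
  outlines <- as_outlines(outlines)
  outline_bind(purrr::imap(outline_split(outlines), function(xy, id) {
    if (polygon_signed_area(xy) < 0) {
      xy <- xy[rev(seq_len(nrow(xy))), , drop = FALSE]
    }
    if (tang_side == "asis") {
      return(xy)
    }
    side <- narrow_end(xy)
    if (tang_side == "auto") {
      if (side == "tie") {
        rlang::abort(paste0(
          "cannot tell which end of '", id, "' is the tang (both ends are ",
          "equally wide); supply tang_side = \"left\" or \"right\""
        ), class = "tangmorph_ambiguous_orientation")
      }
      want <- "left"
    } else {
      want <- tang_side
    }
    if (side != "tie" && side != want) {
      ctr <- polygon_centroid(xy)
      xy <- cbind(2 * ctr[1] - xy[, 1], 2 * ctr[2] - xy[, 2])
    }
    xy
  }))
}

#' Basic outline geometry
#'
#' Computes, per specimen, the shoelace area, the polygon centroid, the
#' length (x-extent) and the maximum width (y-extent) of an oriented
#' outline. Area is the size measure used by the Fourier standardization.
#'
#' @param outlines An outline tibble.
#' @return A tibble with one row per specimen and columns `specimen_id`,
#'   `area`, `centroid_x`, `centroid_y`, `length`, `max_width`.
#' @export
measure_outlines <- function(outlines) {
  outlines <- as_outlines(outlines)
  dplyr::bind_rows(purrr::imap(outline_split(outlines), function(xy, id) {
    ctr <- polygon_centroid(xy)
    tibble::tibble(
      specimen_id = id,
      area = polygon_area(xy),
      centroid_x = ctr[1],
      centroid_y = ctr[2],
      length = diff(range(xy[, 1])),
      max_width = diff(range(xy[, 2]))
    )
  }))
}
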