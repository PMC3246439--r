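#' Trace specimen outlines from a binary mask
#'
#' Finds the connected foreground components of a binary raster mask and
#' traces the outer boundary of each at sub-pixel precision (marching
#' squares at the 0.5 level, with linear interpolation between pixel
#' centers). Holes inside a component are ignored: specimens are
#' silhouettes. The raster row order is flipped so that y increases upward
#' ("dorsal side up"); pixel centers sit at integer coordinates.
#'
#' @param mask A numeric, integer, or logical matrix with background 0 and
#'   foreground 1, rows running top to bottom as in an image raster.
#' @param min_area Minimum number of foreground pixels for a component to
#'   count as a specimen.
#' @return An outline tibble (see [as_outlines()]) with one outline per
#'   qualifying component, specimens named `mask_1`, `mask_2`, ... in scan
#'   order. An all-background mask gives an empty tibble with a warning.
#' @export
trace_mask <- function(mask, min_area = 20) {
  if (!is.matrix(mask)) {
    rlang::abort("mask must be a matrix", class = "tangmorph_format_error")
  }
  m <- mask
  if (is.logical(m)) m <- m * 1L
  vals <- unique(as.vector(m))
  if (!all(vals %in% c(0, 1))) {
    rlang::abort("mask is not binary: values other than 0 and 1 present",
      class = "tangmorph_format_error")
  }
  labels <- label_components(m == 1)
  sizes <- tabulate(labels[labels > 0])
  keep <- which(sizes >= min_area)
  if (length(keep) == 0) {
    rlang::warn("no connected component reaches min_area; returning no outlines")
    return(tibble::tibble(
      specimen_id = character(0), point_index = integer(0),
      x = double(0), y = double(0)
    ))
  }

  nr <- nrow(m); nc <- ncol(m)
  mats <- purrr::map(seq_along(keep), function(i) {
    comp <- (labels == keep[i]) * 1
    # orient with y up, pad with background so edge components close
    z <- t(comp[nr:1, , drop = FALSE])
    zp <- matrix(0, nc + 2, nr + 2)
    zp[2:(nc + 1), 2:(nr + 1)] <- z
    cl <- grDevices::contourLines(
      x = 0:(nc + 1), y = 0:(nr + 1), z = zp, levels = 0.5
    )
    areas <- vapply(cl, function(ct) {
      xy <- cbind(ct$x, ct$y)
      if (all(xy[nrow(xy), ] == xy[1, ])) xy <- xy[-nrow(xy), , drop = FALSE]
      polygon_area(xy)
    }, double(1))
    ct <- cl[[which.max(areas)]]
    xy <- cbind(ct$x, ct$y)
    if (all(xy[nrow(xy), ] == xy[1, ])) xy <- xy[-nrow(xy), , drop = FALSE]
    if (polygon_signed_area(xy) < 0) xy <- xy[rev(seq_len(nrow(xy))), ]
    xy
  })
  names(mats) <- paste0("mask_", seq_along(mats))
  as_outlines(outline_bind(mats))
}

# 8-connected component labelling by iterative flood fill.
label_components <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  labels <- matrix(0L, nr, nc)
  nxt <- 0L
  offsets <- expand.grid(dr = -1:1, dc = -1:1)
  offsets <- offsets[!(offsets$dr == 0 & offsets$dc == 0), ]
  for (start in which(fg)) {
    if (labels[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    labels[start] <- nxt
    while (length(queue) > 0) {
      idx <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- ((idx - 1L) %% nr) + 1L
      cc <- ((idx - 1L) %/% nr) + 1L
      rr <- r + offsets$dr; ccn <- cc + offsets$dc
      ok <- rr >= 1 & rr <= nr & ccn >= 1 & ccn <= nc
      nb <- (ccn[ok] - 1L) * nr + rr[ok]
      nb <- nb[fg[nb] & labels[nb] == 0L]
      labels[nb] <- nxt
      queue <- c(queue, nb)
    }
  }
  labels
}

#' Read a binary mask from disk
#'
#' Supports ASCII PGM (`P1`/`P2`), delimited 0/1 text matrices, and — when
#' the `png` package is installed — single-channel PNG with foreground
#' greater than 0. Non-binary images are a format error.
#'
#' @param path Path to the mask file.
#' @return A 0/1 matrix suitable for [trace_mask()].
#' @export
read_mask <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) {
      rlang::abort("reading PNG masks requires the 'png' package")
    }
    img <- png::readPNG(path)
    if (length(dim(img)) == 3) img <- img[, , 1]
    vals <- sort(unique(as.vector(img)))
    if (length(vals) > 2) {
      rlang::abort("PNG mask is not binary", class = "tangmorph_format_error")
    }
    return((img > 0) * 1L)
  }
  if (ext %in% c("pgm", "pbm")) {
    return(read_pgm(path))
  }
  m <- as.matrix(utils::read.table(path, header = FALSE, sep = ""))
  dimnames(m) <- NULL
  storage.mode(m) <- "double"
  m
}

# Plain ASCII PGM/PBM reader (P1 bitmap, P2 graymap), comments allowed.
read_pgm <- function(path) {
  tokens <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  magic <- tokens[1]
  if (!magic %in% c("P1", "P2")) {
    rlang::abort("only ASCII PGM/PBM (P1, P2) masks are supported",
      class = "tangmorph_format_error")
  }
  dims <- as.integer(tokens[2:3])
  if (magic == "P2") {
    maxval <- as.numeric(tokens[4])
    px <- as.numeric(tokens[-(1:4)])
    px <- (px > 0) * 1
    vals <- unique(as.numeric(tokens[-(1:4)]))
    if (length(vals) > 2) {
      rlang::abort("PGM mask is not binary", class = "tangmorph_format_error")
    }
  } else {
    px <- as.numeric(tokens[-(1:3)])
  }
  matrix(px, nrow = dims[2], ncol = dims[1], byrow = TRUE)
}
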