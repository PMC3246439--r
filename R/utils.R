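# Internal polygon helpers. All polygons are n x 2 matrices of vertices of a
# closed outline; the first vertex is NOT repeated at the end (closure is
# implicit), so every formula below appends the closing segment itself.

polygon_signed_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  0.5 * sum(x * yn - xn * y)
}

polygon_area <- function(xy) abs(polygon_signed_area(xy))

polygon_centroid <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- 0.5 * sum(cr)
  if (abs(a) < .Machine$double.eps) {
    return(c(mean(x), mean(y)))
  }
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

polygon_perimeter <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
}

# Minimum distance from point p to the closed polyline through xy.
point_polygon_distance <- function(p, xy) {
  a <- xy
  b <- xy[c(seq_len(nrow(xy))[-1], 1), , drop = FALSE]
  abx <- b[, 1] - a[, 1]; aby <- b[, 2] - a[, 2]
  apx <- p[1] - a[, 1]; apy <- p[2] - a[, 2]
  len2 <- abx^2 + aby^2
  t <- ifelse(len2 > 0, pmin(1, pmax(0, (apx * abx + apy * aby) / len2)), 0)
  dx <- apx - t * abx; dy <- apy - t * aby
  sqrt(min(dx^2 + dy^2))
}

# Directed Hausdorff-style distance between two closed outlines: the largest
# distance from a vertex of one to the polygon of the other, symmetrized.
outline_hausdorff <- function(xy1, xy2) {
  d12 <- max(apply(xy1, 1, point_polygon_distance, xy = xy2))
  d21 <- max(apply(xy2, 1, point_polygon_distance, xy = xy1))
  max(d12, d21)
}

# Which end of an oriented outline is the narrow one? Compares the mean
# half-width (half the y-range) of the vertices in the outer `frac` of the
# x-extent on each side. Returns "left", "right", or "tie" (within rel_tol).
narrow_end <- function(xy, frac = 0.25, rel_tol = 0.01) {
  xr <- range(xy[, 1])
  ext <- diff(xr)
  if (ext <= 0) {
    return("tie")
  }
  left <- xy[xy[, 1] <= xr[1] + frac * ext, 2]
  right <- xy[xy[, 1] >= xr[2] - frac * ext, 2]
  hw_l <- (max(left) - min(left)) / 2
  hw_r <- (max(right) - min(right)) / 2
  m <- max(hw_l, hw_r)
  if (m <= 0 || abs(hw_l - hw_r) <= rel_tol * m) {
    return("tie")
  }
  if (hw_l < hw_r) "left" else "right"
}

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's state afterwards. seed = NULL leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
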