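# Shape constructors and independent oracles shared across the suite.

outline_tbl <- function(xy, id = "shape") {
  tibble::tibble(
    specimen_id = id,
    point_index = seq_len(nrow(xy)),
    x = xy[, 1],
    y = xy[, 2]
  )
}

circle_xy <- function(n, r = 1, cx = 0, cy = 0, clockwise = FALSE) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  if (clockwise) th <- -th
  cbind(cx + r * cos(th), cy + r * sin(th))
}

ellipse_xy <- function(n, a = 2, b = 1, cx = 0, cy = 0) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(cx + a * cos(th), cy + b * sin(th))
}

# Unit square traversed counterclockwise from the origin, n points equally
# spaced along the perimeter.
square_xy <- function(n = 400) {
  s <- seq(0, 4, length.out = n + 1)[seq_len(n)]
  side <- floor(s)
  f <- s - side
  xy <- matrix(0, n, 2)
  xy[side == 0, ] <- cbind(f[side == 0], 0)
  xy[side == 1, ] <- cbind(1, f[side == 1])
  xy[side == 2, ] <- cbind(1 - f[side == 2], 1)
  xy[side == 3, ] <- cbind(0, 1 - f[side == 3])
  xy
}

# Random star-convex polygon: random radii at equally spaced angles.
star_xy <- function(n = 64, seed = 1) {
  r <- withr::with_seed(seed, stats::runif(n, 0.5, 1.5))
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(r * cos(th), r * sin(th))
}

rotate_xy <- function(xy, angle, about = c(0, 0)) {
  ca <- cos(angle); sa <- sin(angle)
  dx <- xy[, 1] - about[1]; dy <- xy[, 2] - about[2]
  cbind(about[1] + ca * dx - sa * dy, about[2] + sa * dx + ca * dy)
}

# Independent EFA oracle: dense trapezoid-rule Fourier integration of the
# same uniform-parameter piecewise-linear contour (each vertex at an equal
# parameter increment, k sample points per segment).
efa_oracle <- function(xy, H, k = 600) {
  n <- nrow(xy)
  nxt <- xy[c(seq_len(n)[-1], 1), , drop = FALSE]
  f <- (seq_len(k) - 0.5) / k  # midpoints within each segment
  t_all <- as.vector(outer(f / n, (seq_len(n) - 1) / n, `+`))
  xs <- as.vector(sapply(seq_len(n), function(i) {
    xy[i, 1] + f * (nxt[i, 1] - xy[i, 1])
  }))
  ys <- as.vector(sapply(seq_len(n), function(i) {
    xy[i, 2] + f * (nxt[i, 2] - xy[i, 2])
  }))
  w <- 1 / (n * k)  # midpoint rule weight
  res <- list(A0 = sum(xs) * w, C0 = sum(ys) * w)
  M <- matrix(0, H, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  for (h in seq_len(H)) {
    cs <- cos(2 * pi * h * t_all)
    sn <- sin(2 * pi * h * t_all)
    M[h, ] <- 2 * w * c(sum(xs * cs), sum(xs * sn),
      sum(ys * cs), sum(ys * sn))
  }
  res$M <- M
  res
}

# Flatten a coefficient tibble row into the named a/b/c/d vector order used
# by coefficient_matrix().
coeff_vec <- function(coeffs, i = 1) {
  H <- max(as.integer(sub("^[abcd]", "",
    grep("^[abcd][0-9]+$", names(coeffs), value = TRUE))))
  nm <- paste0(rep(c("a", "b", "c", "d"), H), rep(seq_len(H), each = 4))
  unlist(coeffs[i, nm])
}

# Direct-formula Welch oracle.
welch_oracle <- function(x, y) {
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Major-axis slope oracle via eigendecomposition of the 2x2 covariance.
ma_oracle <- function(x, y) {
  ev <- eigen(stats::cov(cbind(x, y)), symmetric = TRUE)
  v <- ev$vectors[, 1]
  v[2] / v[1]
}

# Standardized coefficient matrix of a set of generated tools.
standardized_coeffs <- function(outlines, harmonics = 11) {
  out <- resample_outlines(outlines, 512)
  efa_standardize(efa_forward(out, harmonics), measure_outlines(out))
}

# One fully processed synthetic world, computed once and reused by the
# acceptance suite (the expensive 400-specimen pipeline).
acceptance_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- generate_assemblage(assemblage_spec(n = 400, seed = 1))
      out <- resample_outlines(
        orient_outlines(sim$outlines, tang_side = "asis"), 512)
      std <- efa_standardize(efa_forward(out, 11), measure_outlines(out))
      space <- fit_shape_pca(std)
      cache <<- list(sim = sim, outlines = out, std = std, space = space)
    }
    cache
  }
})
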