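#' Principal-component shape space of Fourier coefficients
#'
#' Fits a PCA to the specimen-by-coefficient matrix of standardized
#' elliptical Fourier descriptors: an eigendecomposition of the coefficient
#' covariance matrix (not the correlation matrix — the coefficients share
#' units). The mean coefficient vector is the mean shape; scores are the
#' centered data projected on the eigenvectors. Near-constant columns fixed
#' by the normalization (b1, c1 close to 0) are retained: they contribute
#' essentially zero variance and keep the coefficient vector invertible
#' back to an outline. Each eigenvector's sign is fixed so that its
#' largest-magnitude loading is positive, making plots and tests
#' reproducible.
#'
#' @param coeffs A standardized coefficient tibble (see [efa_standardize()])
#'   or a plain numeric specimen-by-coefficient matrix.
#' @return An object of class `shape_space`: a list with `mean` (the mean
#'   coefficient vector), `rotation` (columns = eigenvectors),
#'   `eigenvalues`, `variance_fraction`, `scores` (a tibble with
#'   `specimen_id` and `PC1..PCk`), and the source column names.
#' @export
fit_shape_pca <- function(coeffs) {
  m <- if (is.matrix(coeffs)) coeffs else coefficient_matrix(coeffs)
  if (nrow(m) < 3) {
    rlang::abort("at least 3 specimens are required for a shape PCA",
      class = "tangmorph_parameter_error")
  }
  if (all(abs(sweep(m, 2, colMeans(m))) < .Machine$double.eps * 100)) {
    rlang::abort("zero-variance coefficient matrix",
      class = "tangmorph_parameter_error")
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  rot <- pc$rotation
  flip <- vapply(seq_len(ncol(rot)), function(j) {
    sign(rot[which.max(abs(rot[, j])), j])
  }, double(1))
  rot <- sweep(rot, 2, flip, `*`)
  scores <- sweep(pc$x, 2, flip, `*`)
  eig <- pc$sdev^2
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  scores_tbl <- tibble::as_tibble(scores)
  scores_tbl <- dplyr::bind_cols(tibble::tibble(specimen_id = ids), scores_tbl)
  structure(
    list(
      mean = pc$center,
      rotation = rot,
      eigenvalues = eig,
      variance_fraction = eig / sum(eig),
      scores = scores_tbl,
      columns = colnames(m),
      n = nrow(m)
    ),
    class = "shape_space"
  )
}

#' @export
print.shape_space <- function(x, ...) {
  cat("Shape space:", x$n, "specimens,", length(x$columns), "coefficients\n")
  k <- min(3, length(x$variance_fraction))
  cat(
    "First", k, "components:",
    paste0(sprintf("%.1f%%", 100 * x$variance_fraction[seq_len(k)]),
      collapse = ", "),
    sprintf("(%.1f%% together)\n", 100 * sum(x$variance_fraction[seq_len(k)]))
  )
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-component summary of a shape space
#'
#' @param x A `shape_space`.
#' @param ... Unused.
#' @return A tibble with one row per component: `component`, `eigenvalue`,
#'   `variance_fraction`, `cumulative_fraction`.
#' @export
tidy.shape_space <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$eigenvalues),
    eigenvalue = x$eigenvalues,
    variance_fraction = x$variance_fraction,
    cumulative_fraction = cumsum(x$variance_fraction)
  )
}

#' One-row summary of a shape space
#'
#' @param x A `shape_space`.
#' @param ... Unused.
#' @return A tibble with `n`, `n_coefficients`, `total_variance`, and the
#'   variance fraction captured by the first three components.
#' @export
glance.shape_space <- function(x, ...) {
  k <- min(3, length(x$variance_fraction))
  tibble::tibble(
    n = x$n,
    n_coefficients = length(x$columns),
    total_variance = sum(x$eigenvalues),
    var_first_three = sum(x$variance_fraction[seq_len(k)])
  )
}

#' Reconstruct the extreme shapes along a component
#'
#' The visual key to each component: the outlines obtained by adding to the
#' mean shape the extreme (maximum and minimum) observed scores along the
#' component, multiplied by the corresponding eigenvector, then inverted
#' through the Fourier series.
#'
#' @param space A `shape_space`.
#' @param component Component index (1-based).
#' @param n_points Points per reconstructed outline.
#' @return An outline tibble with two specimens, `PC<k>_min` and
#'   `PC<k>_max`.
#' @export
extreme_shapes <- function(space, component = 1, n_points = 512) {
  if (component > ncol(space$rotation)) {
    rlang::abort("component index out of range",
      class = "tangmorph_parameter_error")
  }
  sc <- space$scores[[paste0("PC", component)]]
  lo <- min(sc); hi <- max(sc)
  v <- space$rotation[, component]
  mats <- list(
    coeff_vector_xy(space$mean + lo * v, space$columns, n_points),
    coeff_vector_xy(space$mean + hi * v, space$columns, n_points)
  )
  names(mats) <- paste0("PC", component, c("_min", "_max"))
  outline_bind(mats)
}

# Invert a flat coefficient vector (a1 b1 c1 d1 ...) to an outline matrix.
coeff_vector_xy <- function(v, columns, n_points) {
  H <- length(columns) / 4
  M <- matrix(v, nrow = H, ncol = 4, byrow = TRUE)
  colnames(M) <- c("a", "b", "c", "d")
  efa_inverse_xy(list(A0 = 0, C0 = 0, M = M), n_points)
}

#' Project external specimens into an existing shape space
#'
#' Centers the external coefficient matrix on the space's mean shape and
#' projects it on the space's eigenvectors. The space is not refitted: this
#' is how a comparison population (for instance, known arrowheads) is
#' placed into the shape variation of a reference sample.
#'
#' @param space A `shape_space`.
#' @param coeffs A coefficient tibble (or matrix) with exactly the columns
#'   and normalization of the space's source data.
#' @return A score tibble with `specimen_id` and `PC1..PCk`.
#' @export
project_shapes <- function(space, coeffs) {
  m <- if (is.matrix(coeffs)) coeffs else coefficient_matrix(coeffs)
  if (!identical(colnames(m), space$columns)) {
    rlang::abort("coefficient columns do not match the shape space",
      class = "tangmorph_parameter_error")
  }
  sc <- sweep(m, 2, space$mean) %*% space$rotation
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  dplyr::bind_cols(
    tibble::tibble(specimen_id = ids),
    tibble::as_tibble(sc)
  )
}

#' Confidence ellipse of a 2-D score cloud
#'
#' The data ellipse of a set of score pairs: the contour of the fitted
#' bivariate normal containing the given probability mass, i.e. the 2-by-2
#' score covariance scaled by the chi-square quantile at `level` with 2
#' degrees of freedom. With `type = "mean"` the standard-error ellipse of
#' the centroid is returned instead (covariance divided by n). Cluster
#' summaries in shape-space plots conventionally use the data ellipse.
#'
#' @param scores A data frame of scores.
#' @param vars Character vector of the two score columns to use.
#' @param level Confidence level in (0, 1).
#' @param group Optional column name to compute one ellipse per group.
#' @param type `"data"` for the data ellipse (default) or `"mean"` for the
#'   standard-error ellipse of the centroid.
#' @return A tibble with columns `group`, `center_x`, `center_y`,
#'   `semi_major`, `semi_minor`, `angle` (radians, major axis from +x),
#'   `level`, `n`.
#' @export
confidence_ellipse <- function(scores, vars = c("PC1", "PC2"), level = 0.95,
                               group = NULL, type = c("data", "mean")) {
  type <- match.arg(type)
  if (level <= 0 || level >= 1) {
    rlang::abort("level must lie in (0, 1)",
      class = "tangmorph_parameter_error")
  }
  groups <- if (is.null(group)) {
    list(all = scores)
  } else {
    split(scores, scores[[group]])
  }
  dplyr::bind_rows(purrr::imap(groups, function(df, g) {
    pts <- as.matrix(df[vars])
    if (nrow(pts) < 3) {
      rlang::abort("at least 3 points are needed for a confidence ellipse",
        class = "tangmorph_parameter_error")
    }
    S <- stats::cov(pts)
    ev <- eigen(S, symmetric = TRUE)
    if (ev$values[2] <= 1e-12 * max(ev$values[1], .Machine$double.eps)) {
      rlang::abort(paste0(
        "degenerate score covariance (points collinear) for group '", g, "'"
      ), class = "tangmorph_degenerate_covariance")
    }
    scale2 <- stats::qchisq(level, df = 2)
    if (type == "mean") scale2 <- scale2 / nrow(pts)
    tibble::tibble(
      group = g,
      center_x = mean(pts[, 1]),
      center_y = mean(pts[, 2]),
      semi_major = sqrt(ev$values[1] * scale2),
      semi_minor = sqrt(ev$values[2] * scale2),
      angle = atan2(ev$vectors[2, 1], ev$vectors[1, 1]),
      level = level,
      n = nrow(pts)
    )
  }))
}

ellipse_polygon <- function(e, n_vertices = 256) {
  th <- 2 * pi * (seq_len(n_vertices) - 1) / n_vertices
  ca <- cos(e$angle); sa <- sin(e$angle)
  ex <- e$semi_major * cos(th); ey <- e$semi_minor * sin(th)
  cbind(e$center_x + ca * ex - sa * ey, e$center_y + sa * ex + ca * ey)
}

point_in_ellipse <- function(pts, e) {
  dx <- pts[, 1] - e$center_x; dy <- pts[, 2] - e$center_y
  ca <- cos(e$angle); sa <- sin(e$angle)
  u <- (ca * dx + sa * dy) / e$semi_major
  v <- (-sa * dx + ca * dy) / e$semi_minor
  u^2 + v^2 <= 1 + 1e-9
}

#' Categorical relation between two confidence ellipses
#'
#' Classifies two ellipses in the same score plane as `"disjoint"`,
#' `"overlapping"` (boundaries cross), or `"nested"` (one lies entirely
#' inside the other, identical ellipses included), using polygonal
#' approximations with at least 256 vertices.
#'
#' @param e1,e2 Single-row ellipse tibbles from [confidence_ellipse()].
#' @param n_vertices Vertices of the polygonal approximation.
#' @return One of `"disjoint"`, `"overlapping"`, `"nested"`.
#' @export
ellipse_overlap <- function(e1, e2, n_vertices = 256) {
  p1 <- ellipse_polygon(e1, n_vertices)
  p2 <- ellipse_polygon(e2, n_vertices)
  in12 <- point_in_ellipse(p1, e2)
  in21 <- point_in_ellipse(p2, e1)
  if (all(in12) || all(in21)) {
    return("nested")
  }
  if (any(in12) || any(in21)) {
    return("overlapping")
  }
  "disjoint"
}
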