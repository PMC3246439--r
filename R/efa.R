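#' Elliptical Fourier analysis of closed outlines
#'
#' `efa_forward()` decomposes each closed outline into elliptical Fourier
#' descriptors: two offset terms `A0`, `C0` (the parametric mean, i.e. the
#' centroid of the traversal) and four real coefficients `a_n`, `b_n`,
#' `c_n`, `d_n` per harmonic,
#' \deqn{x(t) = A_0 + \sum_n a_n \cos nt + b_n \sin nt, \quad
#'       y(t) = C_0 + \sum_n c_n \cos nt + d_n \sin nt.}
#'
#' The coefficients are computed by exact per-segment integration of the
#' piecewise-linear contour (Kuhl–Giardina form), not by a point-sampled
#' FFT, so they are exact for polygons and independent of sampling phase.
#' Each vertex occupies an equal parameter increment; resample the outline
#' by arc length first (the pipeline default, see [resample_outlines()]) to
#' obtain the classical chord-length parametrization. Under this convention
#' an ellipse traced at uniform parameter is exactly one harmonic.
#'
#' @param outlines An outline tibble (see [as_outlines()]), oriented and
#'   resampled.
#' @param harmonics Number of harmonics H; must satisfy
#'   `1 <= H <= floor(n_points / 2) - 1`.
#' @return A coefficient tibble with columns `specimen_id`, `A0`, `C0`,
#'   `a1, b1, c1, d1, ..., aH, bH, cH, dH` (in that fixed order) and a
#'   `normalization` bookkeeping column (empty for raw coefficients).
#' @export
efa_forward <- function(outlines, harmonics = 11) {
  outlines <- as_outlines(outlines)
  mats <- outline_split(outlines)
  n_min <- min(vapply(mats, nrow, integer(1)))
  if (harmonics < 1 || harmonics > floor(n_min / 2) - 1) {
    rlang::abort(paste0(
      "harmonics must lie in [1, ", floor(n_min / 2) - 1,
      "] for outlines with ", n_min, " points"
    ), class = "tangmorph_parameter_error")
  }
  rows <- purrr::imap(mats, function(xy, id) {
    cf <- efa_xy(xy, harmonics)
    coeff_row(id, cf$A0, cf$C0, cf$M, normalization = "")
  })
  dplyr::bind_rows(rows)
}

# Exact segment-wise Fourier integrals of the piecewise-linear closed
# contour, each vertex at an equal parameter increment. Returns A0, C0 and
# an H x 4 matrix with columns a, b, c, d.
efa_xy <- function(xy, H) {
  n <- nrow(xy)
  x <- xy[, 1]; y <- xy[, 2]
  dx <- diff(c(x, x[1])); dy <- diff(c(y, y[1]))
  t1 <- seq_len(n) / n
  t0 <- t1 - 1 / n
  A0 <- sum((x + c(x[-1], x[1])) / 2) / n
  C0 <- sum((y + c(y[-1], y[1])) / 2) / n
  k <- seq_len(H)
  ph1 <- outer(t1, k) * (2 * pi)
  ph0 <- outer(t0, k) * (2 * pi)
  dcos <- cos(ph1) - cos(ph0)
  dsin <- sin(ph1) - sin(ph0)
  slope_x <- dx * n   # dx / dt with dt = 1/n
  slope_y <- dy * n
  K <- 1 / (2 * pi^2 * k^2)
  M <- cbind(
    a = K * colSums(slope_x * dcos),
    b = K * colSums(slope_x * dsin),
    c = K * colSums(slope_y * dcos),
    d = K * colSums(slope_y * dsin)
  )
  list(A0 = A0, C0 = C0, M = M)
}

coeff_row <- function(id, A0, C0, M, normalization) {
  H <- nrow(M)
  vals <- as.vector(t(M))  # a1 b1 c1 d1 a2 ...
  nm <- paste0(rep(c("a", "b", "c", "d"), H), rep(seq_len(H), each = 4))
  out <- tibble::tibble(specimen_id = id, A0 = A0, C0 = C0)
  out[nm] <- as.list(vals)
  out$normalization <- normalization
  out
}

# Inverse of coeff_row: list(A0, C0, M) from one tibble row.
coeff_unrow <- function(row) {
  H <- coeff_harmonics(row)
  nm <- paste0(rep(c("a", "b", "c", "d"), H), rep(seq_len(H), each = 4))
  M <- matrix(as.numeric(row[1, nm]), nrow = H, ncol = 4, byrow = TRUE)
  colnames(M) <- c("a", "b", "c", "d")
  list(A0 = row$A0[1], C0 = row$C0[1], M = M)
}

# Harmonic count implied by the columns of a coefficient tibble.
coeff_harmonics <- function(coeffs) {
  nm <- grep("^[abcd][0-9]+$", names(coeffs), value = TRUE)
  H <- max(as.integer(sub("^[abcd]", "", nm)))
  expected <- paste0(rep(c("a", "b", "c", "d"), H), rep(seq_len(H), each = 4))
  if (!all(expected %in% nm)) {
    rlang::abort("incomplete coefficient columns",
      class = "tangmorph_format_error")
  }
  H
}

full_normalization <- function() {
  "translated+area_scaled+rotation_standardized+start_normalized"
}

#' Standardize Fourier coefficients for shape analysis
#'
#' Applies, in coefficient space, the standardizations used throughout the
#' analysis: (1) translation — the offset terms are set to zero; (2) size —
#' every harmonic coefficient is divided by the square root of the
#' outline's area, so the reconstructed outline has unit area (equivalent
#' to dividing the coordinates by the square root of their area);
#' (3) rotation — the whole coefficient set is rotated so the best-fitting
#' (first-harmonic) ellipse's major axis lies along +x, *without* dividing
#' by the semi-major axis length, so elongation is retained; and (4) start
#' point — the parametric start is moved to the major-axis end at larger x.
#' The residual 180-degree ambiguity of the ellipse axis is resolved by the
#' minimal in-plane rotation (never more than a quarter turn), which
#' preserves the tang-left orientation established by [orient_outlines()] —
#' an oriented outline is a precondition here, and the standardization is
#' then invariant to input rotations up to a quarter turn beyond the
#' ellipse tilt.
#'
#' A degenerate first harmonic (a circle: semi-axes equal within 1e-9)
#' leaves rotation and start unstandardized with a warning, since its
#' orientation is undefined; the normalization state is recorded anyway.
#'
#' @param coeffs A raw coefficient tibble from [efa_forward()].
#' @param areas Source outline areas: either the tibble returned by
#'   [measure_outlines()] (columns `specimen_id`, `area`) or a numeric
#'   vector named by specimen.
#' @return A coefficient tibble with `normalization` set to
#'   `"translated+area_scaled+rotation_standardized+start_normalized"`.
#' @export
efa_standardize <- function(coeffs, areas) {
  if (is.data.frame(areas)) {
    areas <- stats::setNames(areas$area, areas$specimen_id)
  }
  missing_area <- setdiff(coeffs$specimen_id, names(areas))
  if (length(missing_area) > 0) {
    rlang::abort(paste0(
      "no area supplied for specimen(s): ",
      paste(missing_area, collapse = ", ")
    ), class = "tangmorph_parameter_error")
  }
  rows <- purrr::map(seq_len(nrow(coeffs)), function(i) {
    row <- coeffs[i, ]
    area <- areas[[row$specimen_id]]
    if (!is.finite(area) || area <= 0) {
      rlang::abort(paste0("nonpositive area for specimen ", row$specimen_id),
        class = "tangmorph_parameter_error")
    }
    cf <- coeff_unrow(row)
    M <- cf$M / sqrt(area)
    M <- standardize_rotation(M, row$specimen_id)
    coeff_row(row$specimen_id, 0, 0, M, normalization = full_normalization())
  })
  dplyr::bind_rows(rows)
}

# Rotation + start-point standardization of one coefficient matrix.
standardize_rotation <- function(M, id = "") {
  h1 <- matrix(c(M[1, "a"], M[1, "c"], M[1, "b"], M[1, "d"]), 2, 2)
  sv <- svd(h1)$d
  if (abs(sv[1] - sv[2]) < 1e-9) {
    rlang::warn(paste0(
      "first-harmonic ellipse of '", id,
      "' is a circle; rotation left unstandardized"
    ))
    return(M)
  }
  a1 <- M[1, "a"]; b1 <- M[1, "b"]; c1 <- M[1, "c"]; d1 <- M[1, "d"]
  theta <- 0.5 * atan2(2 * (a1 * b1 + c1 * d1), a1^2 + c1^2 - b1^2 - d1^2)
  Mt <- shift_start(M, theta)
  if (Mt[1, "a"]^2 + Mt[1, "c"]^2 < Mt[1, "b"]^2 + Mt[1, "d"]^2) {
    theta <- theta + pi / 2
    Mt <- shift_start(M, theta)
  }
  psi <- atan2(Mt[1, "c"], Mt[1, "a"])
  # break the 180-degree axis ambiguity by the minimal in-plane rotation:
  # the input arrives tang-left from orient(), and re-detecting the tang
  # here would misfire on pointed tips (narrower than the stem), so the
  # standardization preserves the established orientation instead
  if (abs(psi) > pi / 2) {
    theta <- theta + pi
    Mt <- shift_start(M, theta)
    psi <- atan2(Mt[1, "c"], Mt[1, "a"])
  }
  rotate_space(Mt, -psi)
}

# Move the parametric start by theta: t -> t + theta (in first-harmonic
# phase units); harmonic n picks up phase n*theta.
shift_start <- function(M, theta) {
  H <- nrow(M)
  out <- M
  for (n in seq_len(H)) {
    cn <- cos(n * theta); sn <- sin(n * theta)
    R <- matrix(c(cn, sn, -sn, cn), 2, 2)
    out[n, c("a", "b")] <- M[n, c("a", "b")] %*% R
    out[n, c("c", "d")] <- M[n, c("c", "d")] %*% R
  }
  out
}

# Rigid rotation of the coordinate plane by angle phi applied to every
# harmonic: (x, y) -> (x cos phi - y sin phi, x sin phi + y cos phi).
rotate_space <- function(M, phi) {
  cp <- cos(phi); sp <- sin(phi)
  out <- M
  out[, "a"] <- cp * M[, "a"] - sp * M[, "c"]
  out[, "c"] <- sp * M[, "a"] + cp * M[, "c"]
  out[, "b"] <- cp * M[, "b"] - sp * M[, "d"]
  out[, "d"] <- sp * M[, "b"] + cp * M[, "d"]
  out
}

efa_inverse_xy <- function(cf, n_points) {
  th <- 2 * pi * (seq_len(n_points) - 1) / n_points
  k <- seq_len(nrow(cf$M))
  CS <- cos(outer(th, k)); SN <- sin(outer(th, k))
  cbind(
    cf$A0 + CS %*% cf$M[, "a"] + SN %*% cf$M[, "b"],
    cf$C0 + CS %*% cf$M[, "c"] + SN %*% cf$M[, "d"]
  )
}

#' Inverse elliptical Fourier transform
#'
#' Synthesizes a closed outline from each coefficient row by evaluating the
#' Fourier series at `n_points` equal parameter increments.
#'
#' @param coeffs A coefficient tibble.
#' @param n_points Number of points per reconstructed outline.
#' @return An outline tibble.
#' @export
efa_inverse <- function(coeffs, n_points = 512) {
  mats <- purrr::map(seq_len(nrow(coeffs)), function(i) {
    efa_inverse_xy(coeff_unrow(coeffs[i, ]), n_points)
  })
  names(mats) <- coeffs$specimen_id
  outline_bind(mats)
}

#' Harmonic power spectrum
#'
#' The power of harmonic n is half the squared sum of its four
#' coefficients, \eqn{(a_n^2 + b_n^2 + c_n^2 + d_n^2) / 2}; the cumulative
#' fraction of total power is the usual criterion for choosing a
#' truncation order.
#'
#' @param coeffs A coefficient tibble.
#' @return A tibble with columns `specimen_id`, `harmonic`, `power`,
#'   `cumulative_fraction`.
#' @export
harmonic_spectrum <- function(coeffs) {
  H <- coeff_harmonics(coeffs)
  dplyr::bind_rows(purrr::map(seq_len(nrow(coeffs)), function(i) {
    cf <- coeff_unrow(coeffs[i, ])
    p <- rowSums(cf$M^2) / 2
    total <- sum(p)
    if (total <= 0) {
      rlang::abort(paste0(
        "all-zero coefficients for specimen ", coeffs$specimen_id[i],
        ": power fractions undefined"
      ), class = "tangmorph_parameter_error")
    }
    tibble::tibble(
      specimen_id = coeffs$specimen_id[i],
      harmonic = seq_len(H),
      power = p,
      cumulative_fraction = cumsum(p) / total
    )
  }))
}

#' Choose a harmonic truncation order from cumulative power
#'
#' Returns the smallest harmonic count H such that every specimen's
#' cumulative power fraction at H reaches `threshold`. The conventional
#' choice for tanged-tool outlines is 11 harmonics (44 coefficients),
#' which captures more than 99 % of the cumulative harmonic power.
#'
#' Because the cumulative fraction of the last available harmonic is 1 by
#' construction, a threshold that is reached only there cannot be told
#' apart from an unreachable one; that case is an error reporting the
#' worst specimen, and the spectra should be recomputed at a larger H.
#'
#' @param spectrum A spectrum tibble from [harmonic_spectrum()], computed at
#'   a common, sufficiently large H.
#' @param threshold Required cumulative power fraction, in (0, 1).
#' @return An integer harmonic count.
#' @export
choose_harmonics <- function(spectrum, threshold = 0.99) {
  if (threshold <= 0 || threshold >= 1) {
    rlang::abort("threshold must lie in (0, 1)",
      class = "tangmorph_parameter_error")
  }
  h_max <- max(spectrum$harmonic)
  per <- dplyr::summarise(
    dplyr::group_by(spectrum, .data$specimen_id),
    h_needed = {
      ok <- which(.data$cumulative_fraction >= threshold - 1e-12)
      h <- if (length(ok) == 0) NA_integer_ else min(.data$harmonic[ok])
      # reaching the threshold only at the final, self-normalized harmonic
      # is indistinguishable from not reaching it at all
      if (!is.na(h) && h == h_max && h_max > 1) NA_integer_ else h
    },
    worst = .data$cumulative_fraction[.data$harmonic == max(h_max - 1, 1)],
    .groups = "drop"
  )
  if (anyNA(per$h_needed)) {
    worst <- per[which.min(per$worst), ]
    rlang::abort(paste0(
      "threshold ", threshold, " unreachable at the available harmonics; ",
      "worst specimen '", worst$specimen_id, "' reaches only ",
      signif(worst$worst, 6)
    ), class = "tangmorph_parameter_error")
  }
  max(per$h_needed)
}

#' Specimen-by-coefficient matrix
#'
#' Flattens a coefficient tibble into the numeric matrix consumed by the
#' shape-space PCA: one row per specimen, columns in the fixed order
#' `a1, b1, c1, d1, ..., aH, bH, cH, dH` (the offset terms are excluded:
#' they are zero after translation standardization). All specimens must
#' share the harmonic count and the normalization state.
#'
#' @param coeffs A coefficient tibble.
#' @return A numeric matrix with specimen ids as row names.
#' @export
coefficient_matrix <- function(coeffs) {
  if (length(unique(coeffs$normalization)) > 1) {
    rlang::abort("specimens have mixed normalization states",
      class = "tangmorph_parameter_error")
  }
  H <- coeff_harmonics(coeffs)
  nm <- paste0(rep(c("a", "b", "c", "d"), H), rep(seq_len(H), each = 4))
  m <- as.matrix(coeffs[nm])
  if (anyNA(m)) {
    rlang::abort("mixed harmonic counts (NA coefficients present)",
      class = "tangmorph_parameter_error")
  }
  rownames(m) <- coeffs$specimen_id
  m
}

#' Read and write coefficient tables
#'
#' Plain comma-delimited text, one row per specimen with `specimen_id`,
#' `A0`, `C0`, the per-harmonic coefficients, and the normalization-state
#' column; values round-trip bit-exactly.
#'
#' @param path File path.
#' @param coeffs A coefficient tibble.
#' @return The coefficient tibble (`read_coefficients`) or `path`,
#'   invisibly (`write_coefficients`).
#' @export
read_coefficients <- function(path) {
  # base strtod parsing is correctly rounded, giving bit-exact round trips
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  df$normalization <- as.character(df$normalization)
  df$normalization[is.na(df$normalization)] <- ""
  coeff_harmonics(df)  # validates completeness
  tibble::as_tibble(df)
}

#' @rdname read_coefficients
#' @export
write_coefficients <- function(coeffs, path) {
  out <- coeffs
  num <- vapply(out, is.numeric, logical(1))
  # 17 significant digits guarantee a bit-exact double round trip
  out[num] <- lapply(out[num], function(v) sprintf("%.17g", v))
  readr::write_csv(out, path)
  invisible(path)
}
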