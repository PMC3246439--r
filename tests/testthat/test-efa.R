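test_that("an ellipse is exactly one harmonic", {
  cf <- efa_forward(outline_tbl(ellipse_xy(8192)), harmonics = 5)
  expect_equal(cf$a1, 2, tolerance = 1e-6)
  expect_equal(cf$d1, 1, tolerance = 1e-6)
  expect_lt(abs(cf$b1) + abs(cf$c1), 1e-6)
  higher <- coeff_vec(cf)[-(1:4)]
  expect_lt(max(abs(higher)), 1e-6)

  cfc <- efa_forward(outline_tbl(circle_xy(8192)), harmonics = 3)
  expect_equal(c(cfc$a1, cfc$d1), c(1, 1), tolerance = 1e-6)
  expect_lt(abs(cfc$b1) + abs(cfc$c1), 1e-6)
})

test_that("segment-exact coefficients match dense numerical integration", {
  sq <- square_xy(64)
  got <- tangmorph:::efa_xy(sq, 8)
  want <- efa_oracle(sq, 8)
  expect_equal(got$A0, want$A0, tolerance = 1e-6)
  expect_equal(got$C0, want$C0, tolerance = 1e-6)
  expect_equal(unname(got$M), unname(want$M), tolerance = 1e-6)
})

test_that("harmonic range is validated", {
  o <- outline_tbl(circle_xy(64))
  expect_error(efa_forward(o, harmonics = 32),
    class = "tangmorph_parameter_error")
  expect_error(efa_forward(o, harmonics = 0),
    class = "tangmorph_parameter_error")
  expect_silent(efa_forward(o, harmonics = 31))
})

test_that("standardized coefficients are invariant to position, scale and rotation", {
  tool <- generate_tool(tool_truth(asymmetry = 0.15, noise_sd = 0, seed = 1))
  xy <- cbind(tool$x, tool$y)
  base <- standardized_coeffs(tool)

  moved <- outline_tbl(
    rotate_xy(xy * 3.7, pi / 6, about = c(11, -4)) +
      matrix(rep(c(250, -80), each = nrow(xy)), ncol = 2),
    "tool"
  )
  other <- standardized_coeffs(moved)
  expect_lt(max(abs(coeff_vec(base) - coeff_vec(other))), 1e-6)
  expect_equal(base$normalization,
    "translated+area_scaled+rotation_standardized+start_normalized")
})

test_that("size standardization yields unit area and keeps elongation", {
  # circle of radius 2: reconstructed area 1 (radius 1/sqrt(pi)); the
  # first-harmonic ellipse is degenerate, so rotation is skipped with a
  # warning but the state is still recorded
  circ <- outline_tbl(circle_xy(512, r = 2))
  cf <- efa_forward(circ, 8)
  expect_warning(std <- efa_standardize(cf, measure_outlines(circ)),
    "circle")
  rec <- efa_inverse(std, 512)
  expect_equal(measure_outlines(rec)$area, 1, tolerance = 1e-3)
  expect_equal(std$normalization,
    "translated+area_scaled+rotation_standardized+start_normalized")
  expect_equal(c(std$A0, std$C0), c(0, 0))

  # ellipse (2, 1): elongation a1/d1 = 2 survives (no semi-major division)
  ell <- outline_tbl(ellipse_xy(1024))
  std <- efa_standardize(efa_forward(ell, 8), measure_outlines(ell))
  expect_equal(std$a1 / std$d1, 2, tolerance = 1e-4)

  # nonpositive or missing area is a parameter error
  expect_error(
    efa_standardize(efa_forward(ell, 8), c(shape = -1)),
    class = "tangmorph_parameter_error"
  )
  expect_error(
    efa_standardize(efa_forward(ell, 8), c(other = 4)),
    class = "tangmorph_parameter_error"
  )
})

test_that("rotation standardization aligns the best-fitting ellipse with +x", {
  tool <- generate_tool(tool_truth(asymmetry = 0.2, noise_sd = 0, seed = 2))
  xy <- rotate_xy(cbind(tool$x, tool$y), 0.5)
  std <- standardized_coeffs(outline_tbl(xy, "tool"))
  # first-harmonic ellipse axis angle after standardization
  h1 <- matrix(c(std$a1, std$c1, std$b1, std$d1), 2, 2)
  sv <- svd(h1)
  angle <- atan2(sv$u[2, 1], sv$u[1, 1])
  expect_lt(min(abs(angle), abs(abs(angle) - pi)), 1e-6)
  # start point maps to the larger-x end of the major axis
  expect_gt(std$a1, 0)
  expect_lt(abs(std$c1), 1e-9)
})

test_that("mirror symmetry shows in the b and c coefficients", {
  # mirror-symmetric outline with start on the axis: b_n = c_n = 0
  ell <- tangmorph:::efa_xy(ellipse_xy(512, 3, 1), 8)
  expect_lt(max(abs(ell$M[, c("b", "c")])), 1e-6)

  # superellipse-like symmetric blob, still symmetric about x
  th <- 2 * pi * (0:511) / 512
  blob <- cbind((2 + 0.4 * cos(2 * th)) * cos(th),
    (1 + 0.4 * cos(2 * th)) * sin(th))
  cf <- tangmorph:::efa_xy(blob, 8)
  expect_lt(max(abs(cf$M[, c("b", "c")])), 1e-6)

  # mirroring an asymmetric outline negates every b_n and c_n
  tool <- generate_tool(tool_truth(asymmetry = 0.25, noise_sd = 0, seed = 3))
  xy <- cbind(tool$x, tool$y)
  mir <- cbind(xy[, 1], -xy[, 2])[rev(seq_len(nrow(xy))), ]  # restore ccw
  c1 <- standardized_coeffs(tool)
  c2 <- standardized_coeffs(outline_tbl(mir, "tool"))
  v1 <- coeff_vec(c1); v2 <- coeff_vec(c2)
  bc <- grepl("^[bc]", names(v1))
  expect_equal(unname(v2[bc]), unname(-v1[bc]), tolerance = 1e-6)
  expect_equal(unname(v2[!bc]), unname(v1[!bc]), tolerance = 1e-6)
})

test_that("total power is invariant under rotation standardization", {
  for (seed in 1:5) {
    M <- matrix(withr::with_seed(seed, stats::rnorm(44, sd = 0.2)), 11, 4)
    colnames(M) <- c("a", "b", "c", "d")
    M[1, ] <- c(2, 0.3, -0.2, 1)  # non-degenerate first harmonic
    Ms <- tangmorph:::standardize_rotation(M)
    expect_equal(sum(Ms^2), sum(M^2), tolerance = 1e-9)
  }
})

test_that("inverse transform round-trips", {
  # inverse of forward of an ellipse at H = 1 reproduces the ellipse; the
  # segment-exact integrals converge quadratically in point density
  ell512 <- ellipse_xy(512)
  cf <- efa_forward(outline_tbl(ell512), 1)
  rec <- efa_inverse(cf, 512)
  expect_lt(max(abs(rec$x - ell512[, 1]), abs(rec$y - ell512[, 2])), 1e-4)
  cf <- efa_forward(outline_tbl(ellipse_xy(8192)), 1)
  rec <- efa_inverse(cf, 8192)
  expect_lt(max(abs(rec$x - ellipse_xy(8192)[, 1])), 1e-6)

  # forward of inverse recovers arbitrary coefficients at dense sampling
  cf0 <- tibble::tibble(
    specimen_id = "free", A0 = 0.3, C0 = -0.2,
    a1 = 1.8, b1 = 0.05, c1 = -0.02, d1 = 1.0,
    a2 = 0.1, b2 = -0.08, c2 = 0.06, d2 = -0.04,
    a3 = -0.05, b3 = 0.02, c3 = 0.03, d3 = 0.05,
    normalization = ""
  )
  rec <- efa_inverse(cf0, 131072)
  back <- efa_forward(rec, 3)
  expect_lt(max(abs(coeff_vec(back) - coeff_vec(cf0))), 1e-9)
  expect_equal(back$A0, cf0$A0, tolerance = 1e-9)

  # square reconstruction error strictly decreases with harmonic count
  sq <- square_xy(512)
  rms <- vapply(c(1, 3, 11, 25), function(H) {
    cf <- tangmorph:::efa_xy(sq, H)
    rec <- tangmorph:::efa_inverse_xy(cf, 512)
    sqrt(mean((rec[, 1] - sq[, 1])^2 + (rec[, 2] - sq[, 2])^2))
  }, double(1))
  expect_true(all(diff(rms) < 0))
})

test_that("harmonic power spectrum and truncation choice behave", {
  one <- tibble::tibble(specimen_id = "h1", A0 = 0, C0 = 0,
    a1 = 1, b1 = 0, c1 = 0, d1 = 1, normalization = "")
  sp <- harmonic_spectrum(one)
  expect_equal(sp$power, 1)
  expect_equal(sp$cumulative_fraction, 1)

  ell <- efa_forward(outline_tbl(ellipse_xy(4096)), 11)
  sp <- harmonic_spectrum(ell)
  expect_equal(sp$cumulative_fraction[1], 1, tolerance = 1e-9)
  expect_equal(choose_harmonics(sp, 0.99), 1)

  # random coefficients: nondecreasing cumulative fraction ending at 1
  rnd <- one
  for (h in 2:11) {
    for (lett in c("a", "b", "c", "d")) {
      rnd[[paste0(lett, h)]] <- withr::with_seed(h, stats::rnorm(1, sd = 0.1))
    }
  }
  sp <- harmonic_spectrum(rnd)
  expect_true(all(diff(sp$cumulative_fraction) >= -1e-15))
  expect_equal(sp$cumulative_fraction[11], 1, tolerance = 1e-12)

  zero <- one
  zero[c("a1", "d1")] <- 0
  expect_error(harmonic_spectrum(zero), class = "tangmorph_parameter_error")

  # ellipse + square at threshold 0.95: the square sets the requirement
  sq_cf <- efa_forward(outline_tbl(square_xy(512), "sq"), 11)
  sq_sp <- harmonic_spectrum(sq_cf)
  h_square <- min(sq_sp$harmonic[sq_sp$cumulative_fraction >= 0.95])
  both <- dplyr::bind_rows(
    harmonic_spectrum(efa_forward(outline_tbl(ellipse_xy(512), "el"), 11)),
    sq_sp
  )
  expect_equal(choose_harmonics(both, 0.95), h_square)

  # near-1 threshold unreachable at 11 harmonics for a square
  err <- expect_error(choose_harmonics(sq_sp, 0.9999999),
    class = "tangmorph_parameter_error")
  expect_match(conditionMessage(err), "sq")
})

test_that("coefficient matrices have the fixed 4H layout", {
  sim <- generate_assemblage(assemblage_spec(n = 3, seed = 5))
  std <- standardized_coeffs(sim$outlines)
  m <- coefficient_matrix(std)
  expect_equal(dim(m), c(3, 44))
  expect_equal(colnames(m)[1:5], c("a1", "b1", "c1", "d1", "a2"))

  single <- coefficient_matrix(std[1, ])
  expect_equal(dim(single), c(1, 44))

  mixed <- dplyr::bind_rows(std[1, ],
    efa_forward(resample_outlines(sim$outlines, 64)[1:64, ], 8))
  expect_error(coefficient_matrix(mixed), class = "tangmorph_parameter_error")
})

test_that("coefficient tables round-trip bit-exactly", {
  sim <- generate_assemblage(assemblage_spec(n = 2, seed = 9))
  std <- standardized_coeffs(sim$outlines)
  path <- withr::local_tempfile(fileext = ".csv")
  write_coefficients(std, path)
  back <- read_coefficients(path)
  expect_identical(coefficient_matrix(back), coefficient_matrix(std))
  expect_identical(back$normalization, std$normalization)
})
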