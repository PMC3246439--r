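test_that("the shape PCA matches a brute-force covariance eigendecomposition", {
  for (seed in 1:3) {
    m <- matrix(withr::with_seed(seed, stats::rnorm(20 * 8)), 20, 8)
    colnames(m) <- paste0(rep(c("a", "b", "c", "d"), 2), rep(1:2, each = 4))
    rownames(m) <- sprintf("s%02d", 1:20)
    space <- fit_shape_pca(m)

    ev <- eigen(stats::cov(m), symmetric = TRUE)
    expect_equal(space$eigenvalues, ev$values, tolerance = 1e-9)
    expect_equal(space$variance_fraction, ev$values / sum(ev$values),
      tolerance = 1e-9)
    # align oracle eigenvector signs with the package convention
    vecs <- apply(ev$vectors, 2, function(v) v * sign(v[which.max(abs(v))]))
    expect_equal(unname(space$rotation), unname(vecs), tolerance = 1e-9)
    sc <- sweep(m, 2, colMeans(m)) %*% vecs
    expect_equal(unname(as.matrix(space$scores[, -1])), unname(sc),
      tolerance = 1e-9)
  }
})

test_that("shape space satisfies its structural invariants", {
  sim <- generate_assemblage(assemblage_spec(n = 25, seed = 6))
  std <- standardized_coeffs(sim$outlines)
  space <- fit_shape_pca(std)

  G <- crossprod(space$rotation)
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-9)
  expect_equal(sum(space$variance_fraction), 1, tolerance = 1e-9)
  expect_true(all(diff(space$eigenvalues) <= 1e-12))

  # full-rank reconstruction of every specimen from mean + scores
  m <- coefficient_matrix(std)
  rec <- sweep(as.matrix(space$scores[, -1]) %*% t(space$rotation),
    2, -space$mean)
  expect_lt(max(abs(rec - m)), 1e-9)

  # single dominant direction of variation
  base <- m[rep(1, 10), ]
  base[, "a2"] <- base[, "a2"] + withr::with_seed(1, stats::rnorm(10, sd = 0.05))
  rownames(base) <- sprintf("c%02d", 1:10)
  one <- fit_shape_pca(base)
  expect_gte(one$variance_fraction[1], 0.999)

  expect_error(fit_shape_pca(m[1:2, ]), class = "tangmorph_parameter_error")
  expect_error(fit_shape_pca(m[rep(1, 5), ]),
    class = "tangmorph_parameter_error")
})

test_that("broom-style accessors summarize the space", {
  sim <- generate_assemblage(assemblage_spec(n = 12, seed = 8))
  space <- fit_shape_pca(standardized_coeffs(sim$outlines))
  td <- tidy(space)
  expect_equal(nrow(td), length(space$eigenvalues))
  expect_equal(td$cumulative_fraction[nrow(td)], 1, tolerance = 1e-9)
  gl <- glance(space)
  expect_equal(gl$n, 12)
  expect_equal(gl$n_coefficients, 44)
})

test_that("extreme shapes bracket the sample and mirror asymmetry", {
  # a component with zero variance reproduces the mean shape at both ends
  m <- matrix(0.1, 5, 8)
  colnames(m) <- paste0(rep(c("a", "b", "c", "d"), 2), rep(1:2, each = 4))
  m[, "a1"] <- m[, "a1"] + c(-2:2) * 0.01
  m[, "d1"] <- 0.3
  space <- fit_shape_pca(m)
  ext <- extreme_shapes(space, component = 2, n_points = 128)
  lo <- ext[ext$specimen_id == "PC2_min", c("x", "y")]
  hi <- ext[ext$specimen_id == "PC2_max", c("x", "y")]
  expect_lt(max(abs(lo - hi)), 1e-9)

  # elongation-only sample: extreme aspect ratios bracket all specimens
  truths <- dplyr::bind_rows(purrr::map(seq(80, 130, length.out = 8),
    function(L) tool_truth(sprintf("L%03.0f", L), length = L,
      noise_sd = 0, seed = 1)))
  outs <- dplyr::bind_rows(purrr::map(seq_len(nrow(truths)),
    function(i) generate_tool(truths[i, ])))
  std <- standardized_coeffs(outs)
  space <- fit_shape_pca(std)
  ratios <- vapply(split(efa_inverse(std, 256), efa_inverse(std, 256)$specimen_id),
    function(df) diff(range(df$x)) / diff(range(df$y)), double(1))
  ext <- extreme_shapes(space, 1, n_points = 256)
  ext_r <- vapply(split(ext, ext$specimen_id),
    function(df) diff(range(df$x)) / diff(range(df$y)), double(1))
  expect_lte(min(ratios), max(ext_r) + 1e-6)
  expect_gte(max(ratios), min(ext_r) - 1e-6)
  expect_true(min(ext_r) <= min(ratios) + 0.2)

  # asymmetry-only sample: the two PC1 extremes are near mirror images
  truths <- dplyr::bind_rows(purrr::map(seq(-0.3, 0.3, length.out = 9),
    function(s) tool_truth(sprintf("s%+.2f", s), asymmetry = s,
      noise_sd = 0, seed = 1)))
  outs <- dplyr::bind_rows(purrr::map(seq_len(nrow(truths)),
    function(i) generate_tool(truths[i, ])))
  space <- fit_shape_pca(standardized_coeffs(outs))
  ext <- extreme_shapes(space, 1, n_points = 256)
  lo <- as.matrix(ext[ext$specimen_id == "PC1_min", c("x", "y")])
  hi <- as.matrix(ext[ext$specimen_id == "PC1_max", c("x", "y")])
  flipped <- cbind(hi[, 1], -hi[, 2])
  d <- tangmorph:::outline_hausdorff(lo, flipped)
  expect_lt(d / diff(range(lo[, 1])), 0.05)
})

test_that("projection into an existing space is exact and strict", {
  sim <- generate_assemblage(assemblage_spec(n = 15, seed = 2))
  std <- standardized_coeffs(sim$outlines)
  space <- fit_shape_pca(std)

  self <- project_shapes(space, std)
  expect_equal(as.matrix(self[, -1]), as.matrix(space$scores[, -1]),
    tolerance = 1e-12)

  mean_row <- matrix(space$mean, 1, dimnames = list("mean", space$columns))
  expect_lt(max(abs(project_shapes(space, mean_row)[, -1])), 1e-12)

  wrong <- coefficient_matrix(std)[, 1:40]
  expect_error(project_shapes(space, wrong),
    class = "tangmorph_parameter_error")
})

test_that("confidence ellipses use the chi-square data-ellipse scaling", {
  pts <- withr::with_seed(42,
    tibble::tibble(PC1 = stats::rnorm(10000), PC2 = stats::rnorm(10000)))
  e <- confidence_ellipse(pts, level = 0.95)
  expect_equal(e$semi_major, sqrt(stats::qchisq(0.95, 2)), tolerance = 0.05)
  expect_equal(e$semi_minor, sqrt(stats::qchisq(0.95, 2)), tolerance = 0.05)
  # the centroid lies inside
  expect_true(tangmorph:::point_in_ellipse(
    cbind(mean(pts$PC1), mean(pts$PC2)), e))

  line <- tibble::tibble(PC1 = 1:10, PC2 = 2 * (1:10))
  expect_error(confidence_ellipse(line),
    class = "tangmorph_degenerate_covariance")
  expect_error(confidence_ellipse(pts, level = 1.2),
    class = "tangmorph_parameter_error")

  # the mean (standard-error) ellipse shrinks with n
  em <- confidence_ellipse(pts, type = "mean")
  expect_lt(em$semi_major, e$semi_major / 50)
})

test_that("ellipse overlap classification distinguishes the three relations", {
  mk <- function(cx, cy, a = 1, b = 1, ang = 0) tibble::tibble(
    group = "g", center_x = cx, center_y = cy, semi_major = a,
    semi_minor = b, angle = ang, level = 0.95, n = 10)
  expect_equal(ellipse_overlap(mk(0, 0), mk(0, 0)), "nested")
  expect_equal(ellipse_overlap(mk(0, 0, 2, 2), mk(0.3, 0, 0.5, 0.5)), "nested")
  expect_equal(ellipse_overlap(mk(0, 0), mk(20, 0)), "disjoint")
  expect_equal(ellipse_overlap(mk(0, 0), mk(1, 0)), "overlapping")
})
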