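test_that("read_outlines validates structure and rejects degenerate outlines", {
  path <- withr::local_tempfile(fileext = ".csv")

  # two 4-point squares: below the 8-point minimum, both specimens named
  sq <- square_xy(4)
  df <- dplyr::bind_rows(outline_tbl(sq, "sq1"), outline_tbl(sq, "sq2"))
  readr::write_csv(df, path)
  err <- expect_error(read_outlines(path), class = "tangmorph_degenerate_outline")
  expect_match(conditionMessage(err), "sq1")
  expect_match(conditionMessage(err), "sq2")

  # a 64-point circle is one valid outline
  readr::write_csv(outline_tbl(circle_xy(64), "c1"), path)
  out <- read_outlines(path)
  expect_equal(unique(out$specimen_id), "c1")
  expect_equal(nrow(out), 64)

  # a duplicated consecutive point is dropped with a warning
  circ <- outline_tbl(circle_xy(64), "c1")
  dup <- dplyr::bind_rows(circ[1:10, ], circ[10, ], circ[11:64, ])
  dup$point_index <- seq_len(nrow(dup))
  readr::write_csv(dup, path)
  expect_warning(out <- read_outlines(path), "duplicated")
  expect_equal(nrow(out), 64)

  # missing column is a format error
  readr::write_csv(circ[c("specimen_id", "x", "y")], path)
  expect_error(read_outlines(path), class = "tangmorph_format_error")
})

test_that("outline tables round-trip through write/read", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- dplyr::bind_rows(
    outline_tbl(circle_xy(64), "a"),
    outline_tbl(ellipse_xy(100), "b")
  )
  write_outlines(df, path)
  back <- read_outlines(path)
  expect_equal(back, as_outlines(df))
})

test_that("resampling spaces points by arc length and preserves geometry", {
  # circle: 1000 -> 256 points, all radii 1 within 1e-3
  res <- resample_outlines(outline_tbl(circle_xy(1000)), 256)
  expect_true(all(abs(sqrt(res$x^2 + res$y^2) - 1) < 1e-3))

  # square: perimeter preserved within 0.1 %
  sq <- outline_tbl(square_xy(40), "sq")
  res <- resample_outlines(sq, 400)
  xy <- cbind(res$x, res$y)
  perim <- sum(sqrt(diff(c(xy[, 1], xy[1, 1]))^2 +
    diff(c(xy[, 2], xy[1, 2]))^2))
  expect_lt(abs(perim - 4) / 4, 0.001)

  # idempotence to 1e-9
  r1 <- resample_outlines(outline_tbl(star_xy(64, seed = 2)), 256)
  r2 <- resample_outlines(r1, 256)
  expect_lt(max(abs(r2$x - r1$x), abs(r2$y - r1$y)), 1e-9)

  # area of convex shapes preserved within 0.5 % at >= 256 points
  for (shape in list(circle_xy(1000), ellipse_xy(900, 3, 1.5))) {
    orig <- abs(tangmorph:::polygon_signed_area(shape))
    res <- resample_outlines(outline_tbl(shape), 256)
    got <- abs(tangmorph:::polygon_signed_area(cbind(res$x, res$y)))
    expect_lt(abs(got - orig) / orig, 0.005)
  }

  expect_error(resample_outlines(outline_tbl(circle_xy(64)), 16),
    class = "tangmorph_parameter_error")
})

test_that("orientation normalizes traversal and tang side", {
  # clockwise circle becomes counterclockwise (positive signed area)
  cw <- outline_tbl(circle_xy(64, clockwise = TRUE))
  out <- orient_outlines(cw, tang_side = "asis")
  expect_gt(tangmorph:::polygon_signed_area(cbind(out$x, out$y)), 0)

  # blunt tool generated tang-left then rotated 180 degrees: hint flips back
  tool <- generate_tool(tool_truth(pointedness = 3, noise_sd = 0))
  xy <- cbind(tool$x, tool$y)
  flipped <- outline_tbl(rotate_xy(xy, pi, about = colMeans(xy)), "tool")
  expect_equal(tangmorph:::narrow_end(cbind(flipped$x, flipped$y)), "right")
  fixed <- orient_outlines(flipped, tang_side = "left")
  # the bounding box swaps ends: extents match, tang measured on the left
  expect_equal(diff(range(fixed$x)), diff(range(tool$x)), tolerance = 1e-8)
  expect_equal(
    measure_tang_tip(fixed)$tang_length,
    measure_tang_tip(tool)$tang_length,
    tolerance = 0.05
  )

  # symmetric ellipse is ambiguous under auto detection
  expect_error(orient_outlines(outline_tbl(ellipse_xy(128)), "auto"),
    class = "tangmorph_ambiguous_orientation")

  # orient is idempotent
  o1 <- orient_outlines(outline_tbl(star_xy(64, 3)), tang_side = "auto")
  o2 <- orient_outlines(o1, tang_side = "auto")
  expect_equal(o1, o2)
})

test_that("measure_outlines returns shoelace area, centroid and extents", {
  sq <- outline_tbl(square_xy(40), "sq")
  m <- measure_outlines(sq)
  expect_equal(m$area, 1, tolerance = 1e-12)
  expect_equal(c(m$centroid_x, m$centroid_y), c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(c(m$length, m$max_width), c(1, 1), tolerance = 1e-12)

  # ellipse (2, 1): area = 2 pi within 0.5 % at 512 points
  m <- measure_outlines(outline_tbl(ellipse_xy(512)))
  expect_lt(abs(m$area - 2 * pi) / (2 * pi), 0.005)

  # area invariant under rotation to 1e-9
  star <- star_xy(64, 4)
  a1 <- measure_outlines(outline_tbl(star))$area
  a2 <- measure_outlines(outline_tbl(rotate_xy(star, 0.7, c(3, -2))))$area
  expect_lt(abs(a1 - a2), 1e-9)
})

test_that("specimen tables enforce vocabulary and length decomposition", {
  sp <- tibble::tibble(
    specimen_id = c("a", "b"), assemblage = "x",
    collection_class = c("excavated", "surface"),
    retouched = c(TRUE, FALSE),
    length = c(100, 90), tip_length = c(70, 60), tang_length = c(30, 30)
  )
  expect_silent(as_specimens(sp))
  bad <- sp; bad$collection_class <- c("excavated", "museum")
  expect_error(as_specimens(bad), class = "tangmorph_format_error")
  neg <- sp; neg$tip_length[1] <- -1
  expect_error(as_specimens(neg), class = "tangmorph_format_error")
  off <- sp; off$tip_length[2] <- 40
  expect_warning(as_specimens(off), "tolerance")
})
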