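# Max projection, rotated-frame profile extraction, normalization, and
# group aggregation.

test_that("max projection is the per-pixel max over non-missing slices", {
  # single slice: identity
  st1 <- random_stack(5, 6, 1, 1, seed = 51)
  expect_equal(max_project(st1)[, ], st1$voxels[, , 1, 1])

  st <- random_stack(6, 7, 4, 1, seed = 52, na_frac = 0.3)
  proj <- max_project(st)
  # max property: projected pixel >= every slice value
  for (zi in 1:4) {
    sl <- st$voxels[, , zi, 1]
    ok <- !is.na(sl) & !is.na(proj)
    expect_true(all(proj[ok] >= sl[ok]))
  }
  # brute-force per-pixel oracle, missing iff missing in every slice
  oracle <- matrix(NA_real_, 6, 7)
  for (iy in 1:6) for (ix in 1:7) {
    v <- st$voxels[iy, ix, , 1]
    v <- v[!is.na(v)]
    if (length(v) > 0) oracle[iy, ix] <- max(v)
  }
  expect_equal(proj[, ], oracle)
  expect_equal(attr(proj, "pixel_size"), st$voxel_size[c("y", "x")])
})

test_that("profiles over uniform images are flat; bin count follows the rounding rule", {
  img <- flat_image(80, 200, value = 3.5)
  roi <- rect_roi(center = c(25, 10), length = 37, width = 6, angle = 0)
  prof <- extract_profile(img, roi, 0.41)
  expect_length(prof$values, 90L)  # round(37 / 0.41)
  expect_true(all(abs(prof$values - 3.5) < 1e-9))
  expect_equal(prof$positions[1], -37 / 2 + prof$bin_width / 2)
  expect_equal(diff(range(diff(prof$positions))), 0, tolerance = 1e-12)
})

test_that("axis-aligned profiles of a linear ramp equal the ramp at bin centres", {
  # image value = 2 x + 1 (um), constant across y
  ny <- 60; nx <- 240; px <- c(y = 0.25, x = 0.25)
  xs <- (seq_len(nx) - 0.5) * px["x"]
  img <- matrix(rep(2 * xs + 1, each = ny), ny, nx)
  attr(img, "pixel_size") <- px
  roi <- rect_roi(center = c(30, 7.5), length = 37, width = 5, angle = 0)
  prof <- extract_profile(img, roi, 0.41)
  expected <- 2 * (30 + prof$positions) + 1
  expect_lt(max(abs(prof$values - expected)) / diff(range(expected)), 1e-6)
})

test_that("profile extraction commutes with ROI translation in a uniform image", {
  img <- flat_image(100, 100, value = 2)
  p1 <- extract_profile(img, rect_roi(c(12, 12), 15, 4, angle = 20), 0.41)
  p2 <- extract_profile(img, rect_roi(c(14, 11), 15, 4, angle = 20), 0.41)
  expect_equal(p1$values, p2$values, tolerance = 1e-12)
  expect_equal(p1$positions, p2$positions)
})

test_that("profiles are robust to ROI rotation when the pattern co-rotates", {
  ny <- nx <- 240; px <- c(y = 0.25, x = 0.25)
  band <- function(theta) {
    a <- theta * pi / 180
    xs <- (seq_len(nx) - 0.5) * px["x"]; ys <- (seq_len(ny) - 0.5) * px["y"]
    S <- outer(ys, xs, function(y, x)
      (x - 30) * cos(a) + (y - 30) * sin(a))
    img <- 10 + 8 * sin(2 * pi * S / 9)
    attr(img, "pixel_size") <- px
    img
  }
  p0 <- extract_profile(band(0), rect_roi(c(30, 30), 30, 5, angle = 0), 0.41)
  p30 <- extract_profile(band(30), rect_roi(c(30, 30), 30, 5, angle = 30), 0.41)
  rms <- sqrt(mean((p0$values - p30$values)^2))
  expect_lt(rms / diff(range(p0$values)), 0.02)
})

test_that("an ROI reaching outside the image is an error", {
  img <- flat_image(20, 20)
  expect_error(extract_profile(img, rect_roi(c(2, 2), 30, 4), 0.41),
               "outside the image")
})

test_that("normalization divides by the max, is idempotent and scale invariant", {
  prof <- manual_profile(seq(-1, 1, by = 0.5), c(2, 4, 8, 4, 2))
  norm <- normalize_profile(prof)
  expect_equal(norm$values, c(0.25, 0.5, 1, 0.5, 0.25))
  expect_true(norm$normalized)
  expect_equal(normalize_profile(norm)$values, norm$values)

  # constant profile: all bins 1
  expect_true(all(normalize_profile(
    manual_profile(1:5, rep(3, 5)))$values == 1))
  # degenerate profiles are errors
  expect_error(normalize_profile(manual_profile(1:5, rep(0, 5))),
               "not positive")
  expect_error(normalize_profile(manual_profile(1:3, rep(NA_real_, 3))),
               "not positive")

  # scale invariance through the image pipeline
  img <- flat_image(60, 200)
  set.seed(61)
  img[] <- runif(length(img), 5, 50)
  roi <- rect_roi(c(20, 7), 30, 3, angle = 10)
  n1 <- normalize_profile(extract_profile(img, roi, 0.41))
  img10 <- img * 10
  attr(img10, "pixel_size") <- attr(img, "pixel_size")
  n2 <- normalize_profile(extract_profile(img10, roi, 0.41))
  expect_lt(max(abs(n1$values - n2$values)), 1e-9)
})

test_that("group aggregation computes per-bin mean and SEM over non-missing values", {
  p1 <- manual_profile(1:4, c(0.2, 0.4, 1, 0.5), normalized = TRUE)
  p2 <- manual_profile(1:4, c(0.4, 0.2, 1, NA), normalized = TRUE)
  g <- aggregate_group(list(p1, p2))
  expect_equal(g$mean, c(0.3, 0.3, 1, 0.5))
  expect_equal(g$sem[1], sd(c(0.2, 0.4)) / sqrt(2))
  expect_equal(g$sem[3], 0)
  expect_identical(g$n, c(2L, 2L, 2L, 1L))

  # identical profiles: mean = profile, SEM = 0
  gg <- aggregate_group(list(p1, p1, p1))
  expect_equal(gg$mean, p1$values)
  expect_true(all(gg$sem == 0))

  # n = 1: warning, SEM 0
  expect_warning(g1 <- aggregate_group(list(p1)), "single profile")
  expect_equal(g1$mean, p1$values)
  expect_true(all(g1$sem == 0))

  # mismatched grids
  p3 <- manual_profile(seq(1, 2.5, by = 0.5), c(1, 1, 1, 1), normalized = TRUE)
  expect_error(aggregate_group(list(p1, p3)), "mismatched")
})
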