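test_that("rgb_to_hsb matches the closed-form conversion on key pixels", {
  red <- rgb_to_hsb(rgb_image(matrix(255), matrix(0), matrix(0)))
  expect_equal(red$h[1, 1], 0)
  expect_equal(red$v[1, 1], 255)

  green <- rgb_to_hsb(rgb_image(matrix(0), matrix(255), matrix(0)))
  expect_equal(green$h[1, 1], 85)  # 120 deg * 255 / 360
  expect_equal(green$v[1, 1], 255)

  gray <- rgb_to_hsb(rgb_image(matrix(128), matrix(128), matrix(128)))
  expect_equal(gray$s[1, 1], 0)
  expect_equal(gray$v[1, 1], 128)
  expect_equal(gray$h[1, 1], 0)  # achromatic convention

  expect_error(rgb_image(matrix(0, 2, 2), matrix(0, 2, 3), matrix(0, 2, 2)),
               "same shape")
})

test_that("hsb_to_rgb / rgb_to_hsb round-trip is exact for saturated pixels", {
  set.seed(11)
  h <- matrix(sample(0:254, 100, replace = TRUE), 10)
  s <- matrix(runif(100, 100, 255), 10)
  v <- matrix(runif(100, 40, 255), 10)
  back <- rgb_to_hsb(hsb_to_rgb(h, s, v))
  expect_equal(back$h, h, tolerance = 1e-10)
  expect_equal(back$s, s, tolerance = 1e-10)
  expect_equal(back$v, v, tolerance = 1e-10)
})

test_that("zmax_project equals a brute-force per-pixel maximum", {
  expect_equal(zmax_project(channel_stack(list(matrix(7, 3, 3))))$pixels,
               matrix(7, 3, 3))
  st <- channel_stack(list(matrix(10, 4, 4), matrix(50, 4, 4), matrix(30, 4, 4)))
  expect_equal(zmax_project(st)$pixels, matrix(50, 4, 4))

  set.seed(21)
  slices <- lapply(1:3, function(i) matrix(runif(64, 0, 255), 8))
  proj <- zmax_project(channel_stack(slices))$pixels
  brute <- matrix(0, 8, 8)
  for (r in 1:8) for (c in 1:8)
    brute[r, c] <- max(vapply(slices, function(s) s[r, c], numeric(1)))
  expect_identical(proj, brute)
  for (s in slices) expect_true(all(proj >= s))

  expect_error(channel_stack(list()), "non-empty")
  expect_error(channel_stack(list(matrix(0, 2, 2), matrix(0, 3, 3))), "same shape")
})

test_that("tile_mosaic places tiles row-major and round-trips with crop_tile", {
  one <- tile_mosaic(list(matrix(3, 2, 2)), 1, 1)
  expect_equal(one$pixels, matrix(3, 2, 2))

  tiles <- list(matrix(10, 2, 2), matrix(20, 2, 2), matrix(30, 2, 2), matrix(40, 2, 2))
  mos <- tile_mosaic(tiles, 2, 2)
  expect_equal(dim(mos$pixels), c(4L, 4L))
  expect_equal(mos$pixels[1, 1], 10)
  expect_equal(mos$pixels[1, 4], 20)
  expect_equal(mos$pixels[4, 1], 30)
  expect_equal(mos$pixels[4, 4], 40)

  set.seed(31)
  rtiles <- lapply(1:6, function(i) matrix(runif(15, 0, 255), 3, 5))
  rmos <- tile_mosaic(rtiles, 2, 3)
  for (i in 1:2) for (j in 1:3)
    expect_identical(crop_tile(rmos, i, j, 3, 5)$pixels, rtiles[[(i - 1) * 3 + j]])

  expect_error(tile_mosaic(rtiles, 2, 2), "layout")
  expect_error(tile_mosaic(list(matrix(0, 2, 2), matrix(0, 3, 3)), 1, 2), "ragged")
})

test_that("downsample_bin is exact block averaging and conserves the mean", {
  img <- raster_image(matrix(runif(64, 0, 255), 8))
  expect_equal(downsample_bin(img, 8)$pixels, img$pixels, tolerance = 1e-12)

  expect_equal(downsample_bin(raster_image(matrix(42, 4, 4)), 2)$pixels,
               matrix(42, 2, 2))

  cb <- matrix(0, 4, 4)
  cb[(row(cb) + col(cb)) %% 2 == 0] <- 255
  expect_equal(downsample_bin(raster_image(cb), 2)$pixels, matrix(127.5, 2, 2))

  set.seed(41)
  for (dims in list(c(16, 16), c(13, 17), c(30, 7))) {
    m <- matrix(runif(prod(dims), 0, 255), dims[1])
    for (tw in c(3, 5, dims[2])) {
      out <- downsample_bin(raster_image(m), tw)
      expect_equal(mean(out$pixels), mean(m), tolerance = 1e-9,
                   label = sprintf("mean conservation %dx%d -> %d", dims[1], dims[2], tw))
    }
  }
  expect_error(downsample_bin(raster_image(matrix(0, 4, 4)), 5), "target_width")
})

test_that("rasterize_roi fills by even-odd rule and matches shoelace area", {
  sq <- polygon_roi(rbind(c(0, 0), c(0, 10), c(10, 10), c(10, 0)))
  m <- rasterize_roi(sq, c(20, 20))
  expect_equal(sum(m), 100)
  expect_equal(attr(m, "area_px"), 100L)
  expect_true(all(which(m, arr.ind = TRUE) <= 10))

  expect_error(polygon_roi(rbind(c(0, 0), c(1, 1), c(2, 2))), "degenerate")
  expect_error(polygon_roi(rbind(c(0, 0), c(0, 5))), "3 vertices")

  set.seed(51)
  for (k in 1:5) {
    roi <- random_convex_polygon(center = c(60, 60), radius = 45)
    m <- rasterize_roi(roi, c(120, 120))
    expect_lt(abs(sum(m) - shoelace_area(roi$vertices)) / shoelace_area(roi$vertices),
              0.02)
  }
})

test_that("threshold_mask is inclusive at both ends and range-consistent", {
  img <- const_image(34)
  expect_equal(sum(threshold_mask(img, 0, 255)), 64)
  expect_equal(sum(threshold_mask(img, 35, 255)), 0)
  expect_equal(sum(threshold_mask(const_image(35), 35, 255)), 64)

  set.seed(61)
  img <- raster_image(matrix(runif(400, 0, 255), 20))
  lowband <- threshold_mask(img, 0, 100)
  highband <- threshold_mask(img, 101, 255)
  expect_equal(sum(lowband & highband), 0)
  expect_equal(sum(lowband | highband), 400)
  expect_error(threshold_mask(img, 100, 50), "lo")
})

test_that("intermodes threshold handles deltas, symmetry and unimodal input", {
  h <- numeric(256)
  h[10 + 1] <- 100; h[200 + 1] <- 100
  expect_identical(intermodes_threshold(h), 105L)

  sym <- dnorm(0:255, 50, 10) + dnorm(0:255, 150, 10)
  expect_identical(intermodes_threshold(sym), 100L)

  expect_error(intermodes_threshold(dnorm(0:255, 100, 20)), "unimodal")
  expect_error(intermodes_threshold(c(5, numeric(255))), "two nonempty")
})

test_that("intermodes lands between well-separated modes on sampled histograms", {
  set.seed(71)
  for (k in 1:20) {
    samp <- c(rnorm(4000, 30, 10), rnorm(4000, 180, 10))
    h <- tabulate(pmin(pmax(round(samp), 0), 255) + 1, nbins = 256)
    thr <- intermodes_threshold(h)
    expect_gt(thr, 60)
    expect_lt(thr, 150)
  }
})
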