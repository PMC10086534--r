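test_that("subtract_background removes flat fields and preserves sharp peaks", {
  expect_equal(subtract_background(const_image(120), 10)$pixels, matrix(0, 8, 8))

  set.seed(201)
  m <- matrix(runif(32 * 32, 0, 255), 32)
  out <- subtract_background(raster_image(m), 5)$pixels
  expect_true(all(out >= 0))
  expect_true(all(out <= m + 1e-9))

  spot <- matrix(0, 64, 64)
  spot[32, 32] <- 200
  out <- subtract_background(raster_image(spot), 40)$pixels
  expect_gte(out[32, 32], 0.9 * 200)
})

test_that("unsharp fixes constants, sharpens edges and validates weight", {
  expect_equal(unsharp(const_image(77), 1, 0.6)$pixels, matrix(77, 8, 8),
               tolerance = 1e-9)

  step <- matrix(50, 16, 16); step[, 9:16] <- 150
  out <- unsharp(raster_image(step), 1, 0.6)$pixels
  expect_gt(max(out), 150)  # overshoot at the edge
  expect_lt(min(out), 50)   # undershoot on the dark side

  near_id <- unsharp(raster_image(step), 1, 1e-4)$pixels
  expect_equal(near_id, step, tolerance = 1e-2)

  expect_error(unsharp(const_image(1), 1, 0), "weight")
  expect_error(unsharp(const_image(1), 1, 1), "weight")
})

test_that("mask morphology: dilation, hole filling, median", {
  m <- matrix(FALSE, 9, 9); m[5, 5] <- TRUE
  expect_equal(sum(dilate_mask(m)), 9)

  # hollow square ring: interior becomes foreground after fill
  ring <- matrix(FALSE, 12, 12)
  ring[3:9, 3] <- TRUE; ring[3:9, 9] <- TRUE; ring[3, 3:9] <- TRUE; ring[9, 3:9] <- TRUE
  filled <- fill_holes_mask(ring)
  expect_true(all(filled[4:8, 4:8]))
  expect_equal(sum(filled), 49)  # 7x7 solid block
  expect_false(any(filled[1, ]))

  # isolated single-pixel noise is removed by the median; solid blocks survive
  noisy <- matrix(FALSE, 12, 12)
  noisy[2, 2] <- TRUE
  noisy[6:9, 6:9] <- TRUE
  med <- median_filter_mask(noisy)
  expect_false(med[2, 2])
  expect_true(all(med[7:8, 7:8]))
})

test_that("nerve mask chain: degenerate stacks and generator ground truth", {
  zero <- channel_stack(list(matrix(0, 32, 32), matrix(0, 32, 32)))
  expect_equal(sum(make_nerve_mask(zero)), 0)
  # constant-bright stack: background subtraction removes everything
  flat <- channel_stack(list(matrix(255, 32, 32)))
  expect_equal(sum(make_nerve_mask(flat)), 0)
  expect_equal(sum(make_vessel_mask(zero)), 0)

  sc <- gen_depot_scene(depot_scene_spec(noise_sd = 0), seed = 5)
  nm <- make_nerve_mask(sc$nerve)
  truth <- logical(length(nm)); truth[sc$truth$nerve_idx] <- TRUE
  recovered <- sum(nm & truth) / sum(truth)
  false_pos <- sum(nm & !truth) / max(1, sum(nm))
  expect_gte(recovered, 0.95)
  expect_lte(false_pos, 0.02)
})

test_that("vessel mask chain fills lumens and covers the vessel tree", {
  # hollow tube cross-section in one slice
  size <- 64
  ring <- matrix(0, size, size)
  for (r in 20:44) for (c in 20:44)
    if (abs(sqrt((r - 32)^2 + (c - 32)^2) - 10) < 1.5) ring[r, c] <- 150
  vm <- make_vessel_mask(channel_stack(list(ring)))
  interior <- sum((row(ring) - 32)^2 + (col(ring) - 32)^2 < 8^2)
  expect_gte(sum(vm), interior)
  expect_true(vm[32, 32])  # lumen filled

  sc <- gen_depot_scene(depot_scene_spec(noise_sd = 0), seed = 6)
  vm <- make_vessel_mask(sc$vessel)
  expect_gte(sum(vm & sc$truth$vessel_mask) / sum(sc$truth$vessel_mask), 0.95)
})

test_that("relative_density is exact arithmetic with validation", {
  roi <- matrix(FALSE, 100, 100); roi[1:100, 1:100] <- TRUE
  empty <- matrix(FALSE, 100, 100)
  expect_equal(relative_density(empty, roi)$relative_density, 0)
  expect_equal(relative_density(roi, roi)$relative_density, 1)
  m <- matrix(FALSE, 100, 100); m[1:5, 1:100] <- TRUE
  expect_equal(relative_density(m, roi)$relative_density, 0.05)
  expect_error(relative_density(m, empty), "empty ROI")
  expect_error(relative_density(m, matrix(TRUE, 2, 2)), "shape")
})

test_that("Mander's coefficients: analytic cases, symmetry, monotonicity", {
  a <- matrix(FALSE, 20, 20); a[1:100] <- TRUE
  expect_equal(manders_overlap(a, a), list(m1 = 1, m2 = 1, moc = 1,
                                           area_a_px = 100L, area_b_px = 100L,
                                           overlap_px = 100L))
  b <- matrix(FALSE, 20, 20); b[101:200] <- TRUE
  dis <- manders_overlap(a, b)
  expect_equal(c(dis$m1, dis$m2, dis$moc), c(0, 0, 0))

  # |A| = 100, |B| = 80, |A intersect B| = 40
  b2 <- matrix(FALSE, 20, 20); b2[61:140] <- TRUE
  res <- manders_overlap(a, b2)
  expect_equal(res$m1, 0.40)
  expect_equal(res$m2, 0.50)
  expect_equal(res$moc, 40 / sqrt(100 * 80))
  expect_equal(round(res$moc, 4), 0.4472)

  set.seed(211)
  for (k in 1:10) {
    x <- random_mask(15, 15, 0.4); y <- random_mask(15, 15, 0.3)
    if (sum(x) == 0 || sum(y) == 0) next
    rxy <- manders_overlap(x, y); ryx <- manders_overlap(y, x)
    expect_identical(rxy$m1, ryx$m2)
    expect_identical(rxy$moc, ryx$moc)
    # enlarging B never decreases m1(a, b)
    ybig <- y | random_mask(15, 15, 0.2)
    expect_gte(manders_overlap(x, ybig)$m1, rxy$m1)
  }

  none <- matrix(FALSE, 5, 5)
  expect_error(manders_overlap(none, a[1:5, 1:5]), "mask `a` is empty")
  expect_error(manders_overlap(a[1:5, 1:5], none), "mask `b` is empty")
})

test_that("nan_summary counts points and neighbors against an O(n^2) oracle", {
  shape <- c(200, 200)
  expect_equal(nan_summary(matrix(numeric(0), ncol = 2), shape, 10)$count, 0L)

  spread <- rbind(c(10, 10), c(100, 100), c(190, 10))
  res <- nan_summary(spread, shape, 10)
  expect_equal(res$neighbor_counts, c(0L, 0L, 0L))

  set.seed(221)
  pts <- cbind(runif(10, 0, 199), runif(10, 0, 199))
  res <- nan_summary(pts, shape, 40)
  brute <- vapply(1:10, function(i)
    sum(sqrt((pts[i, 1] - pts[-i, 1])^2 + (pts[i, 2] - pts[-i, 2])^2) <= 40),
    integer(1))
  expect_equal(res$neighbor_counts, brute)

  expect_error(nan_summary(rbind(c(500, 10)), shape, 10), "outside")

  roi <- matrix(FALSE, 200, 200); roi[1:120, ] <- TRUE
  res_roi <- nan_summary(spread, shape, 10, roi = roi)
  expect_equal(res_roi$count, 2L)  # the point at row 190 is outside the ROI
})

test_that("depot densities and per-tissue overlap are deterministic", {
  sc <- gen_depot_scene(depot_scene_spec(size = 128L, nerve_n_px = 500L,
                                         vessel_steps = 80L), seed = 9)
  roi <- rasterize_roi(sc$roi, c(128, 128))
  dd <- depot_densities(zmax_project(sc$nerve), zmax_project(sc$vessel), roi)
  expect_true(dd$nerve$relative_density >= 0 && dd$nerve$relative_density <= 1)
  expect_true(dd$vessel$relative_density >= 0 && dd$vessel$relative_density <= 1)

  run <- function() {
    scenes <- lapply(1:2, function(s)
      gen_depot_scene(depot_scene_spec(size = 128L, nerve_n_px = 300L,
                                       vessel_steps = 60L), seed = s))
    overlap_tissue(lapply(scenes, function(s) list(nerve = s$nerve, vessel = s$vessel)))
  }
  r1 <- run(); r2 <- run()
  expect_identical(r1, r2)
})
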