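test_that("generators are pure functions of spec and seed", {
  g1 <- gen_psr_pair(psr_scene_spec(size = 96L, n_fibers = 8L), seed = 42)
  g2 <- gen_psr_pair(psr_scene_spec(size = 96L, n_fibers = 8L), seed = 42)
  expect_identical(g1, g2)
  g3 <- gen_psr_pair(psr_scene_spec(size = 96L, n_fibers = 8L), seed = 43)
  expect_false(identical(g1$polarized$r, g3$polarized$r))

  d1 <- gen_depot_scene(depot_scene_spec(size = 96L, nerve_n_px = 200L,
                                         vessel_steps = 50L), seed = 7)
  d2 <- gen_depot_scene(depot_scene_spec(size = 96L, nerve_n_px = 200L,
                                         vessel_steps = 50L), seed = 7)
  expect_identical(d1, d2)

  i1 <- gen_ienf_section(0.05, size = 96L, band = c(30, 60), seed = 7)
  i2 <- gen_ienf_section(0.05, size = 96L, band = c(30, 60), seed = 7)
  expect_identical(i1, i2)

  for (kind in c("nmj", "vonfrey", "dose_response"))
    expect_identical(gen_tables(kind, seed = 5), gen_tables(kind, seed = 5))

  # generators leave the global RNG stream untouched
  set.seed(99); before <- .Random.seed
  invisible(gen_psr_pair(psr_scene_spec(size = 64L, n_fibers = 4L), seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("emitted ground truth is self-consistent with the images", {
  g <- gen_psr_pair(psr_scene_spec(size = 128L, n_fibers = 8L, noise_sd = 0), seed = 2)
  expect_identical(unname(g$truth$class_counts),
                   vapply(g$truth$class_idx, length, integer(1), USE.NAMES = FALSE))
  expect_equal(sum(g$truth$class_counts), length(g$truth$fiber_idx))
  expect_equal(g$truth$stain_area_px,
               round(0.30 * 128 * 128))
  expect_equal(g$truth$thin_fraction + g$truth$thick_fraction, 1)

  d <- gen_depot_scene(depot_scene_spec(size = 128L, nerve_n_px = 400L,
                                        vessel_steps = 60L, overlap_p = 0.25),
                       seed = 3)
  expect_equal(d$truth$n_on + d$truth$n_off, 400L)
  expect_equal(d$truth$p_realized, d$truth$n_on / 400)
  # programmed on-vessel pixels really lie on the vessel tree
  expect_true(all(d$truth$vessel_mask[d$truth$nerve_idx[
    d$truth$nerve_idx %in% which(d$truth$vessel_mask)]]))
  on_ct <- sum(d$truth$vessel_mask[d$truth$nerve_idx])
  expect_equal(on_ct, d$truth$n_on)
})

test_that("generated scenes respect the gate structure", {
  g <- gen_psr_pair(psr_scene_spec(size = 128L, n_fibers = 8L, noise_sd = 0), seed = 8)
  hsb <- rgb_to_hsb(g$polarized)
  fiber <- g$truth$fiber_idx
  expect_true(all(hsb$v[fiber] >= 35))
  background <- setdiff(seq_along(hsb$v), fiber)
  expect_true(all(hsb$v[background] < 35))

  s <- gen_ienf_section(0.05, noise_sd = 0, seed = 9)
  px <- s$image$pixels
  expect_true(all(px[s$truth$fiber_idx] == 200))
  expect_true(all(px[-s$truth$fiber_idx] == 40))
})

test_that("infeasible scene specifications are rejected", {
  expect_error(psr_scene_spec(class_fractions = c(green = 0.5, yellow = 0.5,
                                                  orange = 0.5, red = 0.5)),
               "sum to 1")
  expect_error(psr_scene_spec(stain_fraction = 0), "stain_fraction")
  expect_error(psr_scene_spec(fiber_brightness = c(10, 30)), "gate")
  expect_error(psr_scene_spec(background_brightness = c(0, 60)), "gate")
  expect_error(depot_scene_spec(overlap_p = 1.5), "overlap_p")
  expect_error(gen_ienf_section(0.9), "fiber_fraction")
  expect_error(gen_tables("nmj", list(p_status = c(occupied = 0.5, altered = 0.1,
                                                   unoccupied = 0.1))),
               "sum to 1")
})

test_that("table generators match their generating distributions", {
  # occupancy: mean over seeds approaches the programmed probability
  fr <- vapply(1:20, function(s)
    nmj_summary(gen_tables("nmj", seed = s)$table)$fraction_occupied, numeric(1))
  expect_lt(abs(mean(fr) - 0.9), 0.03)

  # saturated psychometric function: every trial positive, AUC = strength range
  g <- gen_tables("vonfrey", list(threshold_g = 1e-6, slope = 50), seed = 1)
  cur <- response_curve(g$table)
  expect_equal(cur$fraction, rep(1, 5))
  expect_equal(vonfrey_auc(cur), 3.98)

  # noiseless dose-response: exact 4PL recovery
  g2 <- gen_tables("dose_response", list(noise_sd = 0), seed = 1)
  fit <- fit_ec50(dose_response(g2$table$dose_M, g2$table$response))
  expect_lt(abs(fit$ec50 - 1e-6) / 1e-6, 1e-6)
})
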