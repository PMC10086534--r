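test_that("hue-bin spec validates intervals and rejects overlaps", {
  spec <- hue_bin_spec()
  # the four classes plus the 129-229 gap partition the integer hue axis
  class_of <- vapply(0:255, function(h) ref_classify_pixel(h, 100), character(1))
  expect_equal(sum(class_of == "unclassified"), 229 - 129 + 1)
  expect_false(anyNA(class_of))

  expect_error(hue_bin_spec(green = rbind(c(50, 128))), "overlapping")
  expect_error(hue_bin_spec(green = rbind(c(52, 300))), "invalid hue interval")
  expect_error(hue_bin_spec(brightness = c(200, 100)), "brightness")
})

test_that("single-pixel classification follows the hue bins and brightness gate", {
  classify_one <- function(hue, s, v) {
    res <- classify_birefringence(hsb_to_rgb(matrix(hue), s, v))
    names(res$class_counts_px)[res$class_counts_px == 1]
  }
  expect_equal(classify_one(60, 255, 100), "green")
  expect_equal(classify_one(240, 255, 200), "red")
  expect_length(classify_one(60, 255, 20), 0)  # excluded by the 35-255 gate
  res <- classify_birefringence(hsb_to_rgb(matrix(60), 255, 20))
  expect_equal(res$gate_px, 0)
})

test_that("vectorized classifier matches the per-pixel reference exactly", {
  set.seed(101)
  n <- 10000
  hue <- sample(0:255, n, replace = TRUE)
  bright <- sample(0:255, n, replace = TRUE)
  img <- hsb_to_rgb(matrix(hue, 100), 255, matrix(bright, 100))
  res <- classify_birefringence(img)

  ref <- vapply(seq_len(n), function(i) ref_classify_pixel(hue[i], bright[i]),
                character(1))
  ref_counts <- c(green = sum(ref == "green", na.rm = TRUE),
                  yellow = sum(ref == "yellow", na.rm = TRUE),
                  orange = sum(ref == "orange", na.rm = TRUE),
                  red = sum(ref == "red", na.rm = TRUE))
  expect_identical(res$class_counts_px, ref_counts)
  expect_identical(res$unclassified_bright_px,
                   sum(ref == "unclassified", na.rm = TRUE))
  expect_identical(res$gate_px, sum(!is.na(ref)))
  # partition: classified + unclassified = gate-passing, per pixel
  all_class <- Reduce(`|`, res$masks)
  expect_identical(sum(all_class) + res$unclassified_bright_px, res$gate_px)
  for (a in seq_along(res$masks))
    for (b in seq_len(a - 1))
      expect_equal(sum(res$masks[[a]] & res$masks[[b]]), 0)
})

test_that("fiber thickness fractions are exact arithmetic on class counts", {
  fr <- fiber_thickness_fractions(c(green = 50, yellow = 30, orange = 15, red = 5))
  expect_equal(fr$thin_fraction, 0.80)
  expect_equal(fr$thick_fraction, 0.20)
  expect_equal(sum(fr$class_fractions), 1)

  fr1 <- fiber_thickness_fractions(c(green = 100, yellow = 0, orange = 0, red = 0))
  expect_equal(fr1$thin_fraction, 1.0)
  expect_error(fiber_thickness_fractions(c(green = 0, yellow = 0, orange = 0, red = 0)),
               "undefined")
  # configurable class split (thick = orange + yellow variant)
  fr2 <- fiber_thickness_fractions(c(green = 50, yellow = 30, orange = 15, red = 5),
                                   thin = c("green", "red"),
                                   thick = c("orange", "yellow"))
  expect_equal(fr2$thick_fraction, 0.45)
})

test_that("total_collagen_ratio arithmetic, errors and inversion", {
  expect_equal(total_collagen_ratio(0, 1000), 0)
  expect_equal(total_collagen_ratio(1000, 1000), 1)
  expect_equal(total_collagen_ratio(250, 1000), 0.25)
  expect_equal(total_collagen_ratio(250, 1000, invert = TRUE), 4)
  expect_error(total_collagen_ratio(10, 0), "zero")
})

test_that("total collagen ratio is invariant under uniform pixel duplication", {
  g <- gen_psr_pair(psr_scene_spec(size = 128L, n_fibers = 8L, noise_sd = 0), seed = 7)
  f1 <- analyze_psr_field(g$brightfield, g$polarized)
  dup2 <- function(img) {
    d <- function(m) m[rep(seq_len(nrow(m)), each = 2), rep(seq_len(ncol(m)), each = 2)]
    rgb_image(d(img$r), d(img$g), d(img$b))
  }
  f2 <- analyze_psr_field(dup2(g$brightfield), dup2(g$polarized))
  expect_equal(f2$psr_area_px, 4 * f1$psr_area_px)
  expect_equal(f2$total_collagen_ratio, f1$total_collagen_ratio, tolerance = 1e-12)
  expect_equal(f2$thin_fraction, f1$thin_fraction, tolerance = 1e-12)
})

test_that("tissue analysis recovers programmed fractions and excludes degenerate fields", {
  spec <- psr_scene_spec(size = 256L, n_fibers = 25L,
                         class_fractions = c(green = 0.55, yellow = 0.30,
                                             orange = 0.10, red = 0.05),
                         noise_sd = 0)
  pairs <- lapply(1:3, function(s) {
    g <- gen_psr_pair(spec, seed = s)
    list(brightfield = g$brightfield, polarized = g$polarized)
  })
  res <- analyze_psr_tissue(pairs)
  expect_equal(res$tissue_means$thin_fraction, 0.85, tolerance = 0.011)
  expect_equal(res$tissue_means$n_fields_used, 3)

  # five identical fields: tissue means equal the single-field values
  same <- analyze_psr_tissue(rep(pairs[1], 5))
  expect_equal(same$tissue_means$total_collagen_ratio,
               res$fields[[1]]$total_collagen_ratio)

  # a stain-free white field is excluded with a warning
  white <- rgb_image(matrix(255, 256, 256), matrix(255, 256, 256), matrix(255, 256, 256))
  dark <- rgb_image(matrix(0, 256, 256), matrix(0, 256, 256), matrix(0, 256, 256))
  with_bad <- c(pairs, list(list(brightfield = white, polarized = dark)))
  expect_warning(res_bad <- analyze_psr_tissue(with_bad), "degenerate")
  expect_equal(res_bad$tissue_means$n_fields_used, 3)
  expect_equal(res_bad$tissue_means$thin_fraction, res$tissue_means$thin_fraction)
})

test_that("all-white and saturated-red bright-field segmentation edge cases", {
  white <- rgb_image(matrix(255, 8, 8), matrix(255, 8, 8), matrix(255, 8, 8))
  expect_equal(sum(segment_psr_brightfield(white)), 0)
  redf <- rgb_image(matrix(255, 8, 8), matrix(0, 8, 8), matrix(0, 8, 8))
  expect_equal(sum(segment_psr_brightfield(redf)), 64)
})
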