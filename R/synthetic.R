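# Seeded synthetic-data generators. Each generator is a pure function of its
# scene specification plus an explicit seed (no global RNG state leaks) and
# emits machine-readable ground truth consistent with the images/tables by
# construction, so every pipeline stage can be verified without raw
# micrographs.

disk_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= radius^2, , drop = FALSE]
}

# random-walk fibers with momentum; returns linear indices into a size x size
# grid (1-based, column-major)
walk_fiber_idx <- function(size, n_fibers, steps_range, radius, angle_jitter = 0.2) {
  offs <- disk_offsets(radius)
  idx <- integer(0)
  for (f in seq_len(n_fibers)) {
    r <- runif(1, 1, size); c <- runif(1, 1, size)
    ang <- runif(1, 0, 2 * pi)
    n_steps <- as.integer(runif(1, steps_range[1L], steps_range[2L]))
    pr <- numeric(n_steps); pc <- numeric(n_steps)
    for (s in seq_len(n_steps)) {
      ang <- ang + rnorm(1, 0, angle_jitter)
      r <- r + sin(ang); c <- c + cos(ang)
      if (r < 1 || r > size || c < 1 || c > size) break
      pr[s] <- r; pc[s] <- c
    }
    keep <- pr > 0
    if (!any(keep)) next
    rr <- outer(round(pr[keep]), offs$dr, `+`)
    cc <- outer(round(pc[keep]), offs$dc, `+`)
    ok <- rr >= 1 & rr <= size & cc >= 1 & cc <= size
    idx <- c(idx, (cc[ok] - 1L) * size + rr[ok])
  }
  unique(as.integer(idx))
}

# largest-remainder apportionment of n items into fractions
apportion <- function(n, fractions) {
  raw <- n * fractions / sum(fractions)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    o <- order(raw - base, decreasing = TRUE)
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Scene specification for synthetic picrosirius-red field pairs
#'
#' Defaults describe a plausible young-adult subcutaneous depot field:
#' 512 x 512 px, 30% of the field covered by stain, fibrillar birefringence
#' split 65:35 thin:thick (green 40%, yellow 25%, orange 22%, red 13%),
#' fiber brightness well above the 35-intensity gate, background below it,
#' additive Gaussian speckle of sd 10 clamped to the intensity range.
#'
#' @param size Field edge in pixels.
#' @param stain_fraction Fraction of pixels stained in the bright-field image.
#' @param n_fibers,fiber_radius Fiber count and half-width (px).
#' @param class_fractions Named fractions (green/yellow/orange/red) of
#'   birefringent pixels; must be nonnegative and sum to 1.
#' @param fiber_brightness,background_brightness Brightness ranges (0--255)
#'   for fiber and background pixels in the polarized image.
#' @param noise_sd Additive Gaussian speckle sd (0 disables).
#' @return Object of class `psr_scene_spec`.
#' @export
psr_scene_spec <- function(size = 512L,
                           stain_fraction = 0.30,
                           n_fibers = 60L,
                           fiber_radius = 1.5,
                           class_fractions = c(green = 0.40, yellow = 0.25,
                                               orange = 0.22, red = 0.13),
                           fiber_brightness = c(120, 230),
                           background_brightness = c(0, 12),
                           noise_sd = 10) {
  if (any(class_fractions < 0) || abs(sum(class_fractions) - 1) > 1e-9)
    stop("class fractions must be nonnegative and sum to 1", call. = FALSE)
  if (!all(c("green", "yellow", "orange", "red") %in% names(class_fractions)))
    stop("class fractions must name green, yellow, orange and red", call. = FALSE)
  if (stain_fraction <= 0 || stain_fraction > 1)
    stop("`stain_fraction` must lie in (0, 1]", call. = FALSE)
  if (fiber_brightness[1L] < 35)
    stop("fiber brightness must clear the 35-intensity gate", call. = FALSE)
  if (background_brightness[2L] >= 35)
    stop("background brightness must stay below the 35-intensity gate", call. = FALSE)
  structure(list(size = as.integer(size), stain_fraction = stain_fraction,
                 n_fibers = as.integer(n_fibers), fiber_radius = fiber_radius,
                 class_fractions = class_fractions,
                 fiber_brightness = fiber_brightness,
                 background_brightness = background_brightness,
                 noise_sd = noise_sd),
            class = "psr_scene_spec")
}

add_speckle <- function(m, sd) {
  if (sd <= 0) return(m)
  pmin(pmax(m + matrix(rnorm(length(m), 0, sd), nrow(m)), 0), 255)
}

# intensity (luminance) speckle: one Gaussian draw per pixel added to all
# three channels, modelling detector/illumination noise without scrambling
# hue (equal shifts leave channel differences intact away from clamping)
add_speckle_rgb <- function(img, sd) {
  if (sd <= 0) return(img)
  n <- matrix(rnorm(length(img$r), 0, sd), nrow(img$r))
  rgb_image(pmin(pmax(img$r + n, 0), 255),
            pmin(pmax(img$g + n, 0), 255),
            pmin(pmax(img$b + n, 0), 255),
            pixel_size_um = img$pixel_size_um)
}

sample_class_hue <- function(cls, n) {
  pool <- switch(cls,
                 green = 52:128, yellow = 39:51, orange = 10:38,
                 red = c(0:9, 230:255),
                 stop("unknown hue class: ", cls, call. = FALSE))
  sample(pool, n, replace = TRUE)
}

#' Generate a paired bright-field/polarized picrosirius-red scene
#'
#' Fibers are random walks thickened to the requested radius; their pixels
#' are partitioned across hue classes in exactly the programmed fractions
#' (largest-remainder apportionment) and painted with integer hues drawn
#' inside each class interval at full saturation. The bright-field stain
#' covers the fibers plus diffuse stained matrix, trimmed to exactly
#' `round(stain_fraction * size^2)` pixels.
#'
#' @param spec A [psr_scene_spec()].
#' @param seed Integer seed; the generator is a pure function of
#'   `(spec, seed)`.
#' @return List with `brightfield` and `polarized` [rgb_image()]s and
#'   `truth`: `fiber_idx`, per-class pixel index lists (`class_idx`),
#'   `class_counts`, `stain_idx`, `stain_area_px`, `thin_fraction`,
#'   `thick_fraction`.
#' @export
gen_psr_pair <- function(spec = psr_scene_spec(), seed = 1L) {
  stopifnot(inherits(spec, "psr_scene_spec"))
  withr::with_seed(seed, {
    size <- spec$size
    npx <- size * size
    fiber_idx <- walk_fiber_idx(size, spec$n_fibers, c(40, 160), spec$fiber_radius)
    target_stain <- round(spec$stain_fraction * npx)
    if (length(fiber_idx) > target_stain)
      stop("infeasible spec: fiber area exceeds the stained-area target", call. = FALSE)
    # assign fiber pixels to hue classes in exact programmed proportions
    fiber_idx <- sample(fiber_idx)
    counts <- apportion(length(fiber_idx), spec$class_fractions)
    names(counts) <- names(spec$class_fractions)
    splits <- cumsum(counts)
    class_idx <- list()
    start <- 1L
    for (k in seq_along(counts)) {
      cls <- names(counts)[k]
      class_idx[[cls]] <- if (counts[k] > 0) fiber_idx[start:splits[k]] else integer(0)
      start <- splits[k] + 1L
    }
    # polarized image: dim unsaturated background, saturated hued fibers
    h <- matrix(runif(npx, 0, 255), size)
    s <- matrix(runif(npx, 0, 255), size)
    v <- matrix(runif(npx, spec$background_brightness[1L],
                      spec$background_brightness[2L]), size)
    for (cls in names(class_idx)) {
      ii <- class_idx[[cls]]
      if (!length(ii)) next
      h[ii] <- sample_class_hue(cls, length(ii))
      s[ii] <- 255
      v[ii] <- runif(length(ii), spec$fiber_brightness[1L], spec$fiber_brightness[2L])
    }
    pol <- hsb_to_rgb(h, s, v)
    # bright-field: fibers + diffuse stained matrix blobs, trimmed to target
    stained <- logical(npx)
    stained[fiber_idx] <- TRUE
    while (sum(stained) < target_stain) {
      ctr <- c(runif(1, 1, size), runif(1, 1, size))
      offs <- disk_offsets(runif(1, 6, 18))
      rr <- round(ctr[1L]) + offs$dr; cc <- round(ctr[2L]) + offs$dc
      ok <- rr >= 1 & rr <= size & cc >= 1 & cc <= size
      stained[(cc[ok] - 1L) * size + rr[ok]] <- TRUE
    }
    excess <- sum(stained) - target_stain
    if (excess > 0) {
      removable <- setdiff(which(stained), fiber_idx)
      stained[sample(removable, excess)] <- FALSE
    }
    stain_idx <- which(stained)
    bh <- matrix(runif(npx, 0, 255), size)
    bs <- matrix(runif(npx, 0, 40), size)
    bv <- matrix(runif(npx, 230, 255), size)
    bh[stain_idx] <- sample(0:9, length(stain_idx), replace = TRUE)
    bs[stain_idx] <- runif(length(stain_idx), 150, 255)
    bv[stain_idx] <- runif(length(stain_idx), 100, 220)
    bf <- hsb_to_rgb(bh, bs, bv)
    pol <- add_speckle_rgb(pol, spec$noise_sd)
    bf <- add_speckle_rgb(bf, spec$noise_sd)
    fr <- counts / max(1L, sum(counts))
    list(brightfield = bf, polarized = pol,
         truth = list(fiber_idx = sort(fiber_idx),
                      class_idx = class_idx,
                      class_counts = counts,
                      stain_idx = stain_idx,
                      stain_area_px = length(stain_idx),
                      thin_fraction = unname(fr["green"] + fr["yellow"]),
                      thick_fraction = unname(fr["orange"] + fr["red"])))
  })
}

#' Scene specification for synthetic two-channel depot fields
#'
#' Emulates a high-magnification field of innervated vasculature: a branching
#' vessel tree (random walks thickened to tubes) in the vessel channel, and
#' point-like sympathetic nerve signal of which a programmed fraction `p`
#' lies on vessels. Default noise sd is 2 (not the 10 used for bright-field
#' scenes): confocal fluorescence background is photon-limited and dark, and
#' the low 15-intensity vessel gate combined with the 2.5x unsharp gain
#' requires background that genuinely stays below the gate, matching the
#' rule that generated background must not pass the relevant thresholds.
#'
#' @param size Field edge (px).
#' @param n_slices Z-slices per stack.
#' @param n_vessels,vessel_steps,vessel_radius Vessel-tree walk parameters.
#' @param nerve_n_px Total nerve pixels placed.
#' @param overlap_p Programmed fraction of nerve pixels on vessels, in
#'   `[0, 1]`.
#' @param vessel_intensity,nerve_intensity,background Channel intensities.
#' @param noise_sd Additive Gaussian noise per slice.
#' @return Object of class `depot_scene_spec`.
#' @export
depot_scene_spec <- function(size = 512L, n_slices = 3L,
                             n_vessels = 6L, vessel_steps = 300L,
                             vessel_radius = 2.5,
                             nerve_n_px = 3000L, overlap_p = 0.5,
                             vessel_intensity = 140, nerve_intensity = 200,
                             background = 6, noise_sd = 2) {
  if (overlap_p < 0 || overlap_p > 1) stop("`overlap_p` must lie in [0, 1]", call. = FALSE)
  structure(list(size = as.integer(size), n_slices = as.integer(n_slices),
                 n_vessels = as.integer(n_vessels),
                 vessel_steps = as.integer(vessel_steps),
                 vessel_radius = vessel_radius,
                 nerve_n_px = as.integer(nerve_n_px), overlap_p = overlap_p,
                 vessel_intensity = vessel_intensity,
                 nerve_intensity = nerve_intensity,
                 background = background, noise_sd = noise_sd),
            class = "depot_scene_spec")
}

#' Generate a two-channel depot scene with programmed nerve-on-vessel overlap
#'
#' On-vessel nerve pixels are sampled from the vessel tube; off-vessel pixels
#' from positions more than 4 px (Chebyshev) away from any vessel, so the
#' one-dilation boundary refinement of the vessel mask cannot absorb them.
#'
#' @param spec A [depot_scene_spec()].
#' @param seed Integer seed.
#' @return List with `nerve` and `vessel` [channel_stack()]s, `roi`
#'   ([polygon_roi()] of the tissue), and `truth`: `vessel_mask`,
#'   `nerve_idx`, `n_on`, `n_off`, `p_realized`.
#' @export
gen_depot_scene <- function(spec = depot_scene_spec(), seed = 1L) {
  stopifnot(inherits(spec, "depot_scene_spec"))
  withr::with_seed(seed, {
    size <- spec$size
    vidx <- walk_fiber_idx(size, spec$n_vessels,
                           c(spec$vessel_steps * 0.5, spec$vessel_steps),
                           spec$vessel_radius, angle_jitter = 0.1)
    V <- matrix(FALSE, size, size)
    V[vidx] <- TRUE
    far <- V
    for (k in 1:4) far <- dilate3x3_cpp(far)
    far_idx <- which(!far)
    n_on <- round(spec$overlap_p * spec$nerve_n_px)
    n_off <- spec$nerve_n_px - n_on
    if (n_on > length(vidx) || n_off > length(far_idx))
      stop("infeasible spec: not enough candidate pixels for the requested overlap",
           call. = FALSE)
    on_idx <- if (n_on > 0) sample(vidx, n_on) else integer(0)
    off_idx <- if (n_off > 0) sample(far_idx, n_off) else integer(0)
    nerve_idx <- c(on_idx, off_idx)
    make_stack <- function(struct_idx, intensity, all_slices) {
      slice_of <- if (all_slices) NULL else sample.int(spec$n_slices,
                                                       length(struct_idx),
                                                       replace = TRUE)
      slices <- lapply(seq_len(spec$n_slices), function(z) {
        m <- matrix(spec$background, size, size)
        ii <- if (all_slices) struct_idx else struct_idx[slice_of == z]
        m[ii] <- intensity
        add_speckle(m, spec$noise_sd)
      })
      channel_stack(slices, z_step_um = 2.5, pixel_size_um = 1)
    }
    nerve <- make_stack(nerve_idx, spec$nerve_intensity, all_slices = FALSE)
    vessel <- make_stack(vidx, spec$vessel_intensity, all_slices = TRUE)
    inset <- 10
    roi <- polygon_roi(rbind(c(inset, inset), c(inset, size - inset),
                             c(size - inset, size - inset), c(size - inset, inset)))
    list(nerve = nerve, vessel = vessel, roi = roi,
         truth = list(vessel_mask = V, nerve_idx = sort(nerve_idx),
                      n_on = n_on, n_off = n_off,
                      p_realized = if (spec$nerve_n_px > 0)
                        n_on / spec$nerve_n_px else NA_real_))
  })
}

#' Generate a synthetic skin section with an epidermal band ROI
#'
#' Background autofluorescence at one intensity mode, nerve fibers crossing
#' the epidermal band at a second, well-separated mode, so the ROI histogram
#' is bimodal by construction. The fiber pixel count inside the ROI is
#' trimmed/augmented to exactly `round(fiber_fraction * roi_area)`.
#'
#' @param fiber_fraction Target fraction of ROI pixels that are fiber.
#' @param size Section edge (px).
#' @param band Epidermal band rows `c(top, bottom)` (0-based).
#' @param intensities Named vector `c(background =, fiber =)`; modes must be
#'   separated or intermodes may legitimately fail (itself a test case).
#' @param noise_sd Additive Gaussian noise.
#' @param seed Integer seed.
#' @return List with `image` ([raster_image()]), `roi` ([polygon_roi()]),
#'   and `truth`: `fiber_idx`, `roi_area_px`, `fiber_fraction_realized`.
#' @export
gen_ienf_section <- function(fiber_fraction, size = 256L, band = c(80, 160),
                             intensities = c(background = 40, fiber = 200),
                             noise_sd = 10, seed = 1L) {
  if (fiber_fraction < 0 || fiber_fraction > 0.5)
    stop("`fiber_fraction` must lie in [0, 0.5]", call. = FALSE)
  if (diff(intensities[c("background", "fiber")]) < 30)
    warning("intensity modes overlap; intermodes thresholding may fail",
            call. = FALSE)
  withr::with_seed(seed, {
    size <- as.integer(size)
    img <- matrix(intensities[["background"]], size, size)
    inset <- 2
    roi <- polygon_roi(rbind(c(band[1L], inset), c(band[1L], size - inset),
                             c(band[2L], size - inset), c(band[2L], inset)))
    roi_mask <- as_mask(rasterize_roi(roi, c(size, size)))
    roi_idx <- which(roi_mask)
    n_target <- round(fiber_fraction * length(roi_idx))
    fiber <- logical(length(img))
    if (n_target > 0) {
      # wavy fibers crossing the band top-to-bottom
      n_fibers <- max(1L, round(n_target / (band[2L] - band[1L])))
      for (f in seq_len(n_fibers)) {
        col <- runif(1, inset + 2, size - inset - 2)
        for (r in seq(band[1L], band[2L])) {
          col <- col + rnorm(1, 0, 0.6)
          cc <- round(col); rr <- r + 1L
          if (cc >= 1 && cc <= size && rr >= 1 && rr <= size)
            fiber[(cc - 1L) * size + rr] <- TRUE
        }
      }
      fiber[setdiff(which(fiber), roi_idx)] <- FALSE  # count fibers inside ROI only
      n_have <- sum(fiber)
      if (n_have > n_target) {
        fiber[sample(which(fiber), n_have - n_target)] <- FALSE
      } else if (n_have < n_target) {
        pool <- setdiff(roi_idx, which(fiber))
        fiber[sample(pool, n_target - n_have)] <- TRUE
      }
    }
    img[fiber] <- intensities[["fiber"]]
    img <- add_speckle(img, noise_sd)
    list(image = raster_image(img, pixel_size_um = 1, channel_label = "PGP9.5"),
         roi = roi,
         truth = list(fiber_idx = which(fiber), roi_area_px = length(roi_idx),
                      fiber_fraction_realized = sum(fiber) / length(roi_idx)))
  })
}

#' Generate annotation/physiology tables with ground truth
#'
#' * `"nmj"`: multinomial junction statuses (default 50 junctions/tissue,
#'   occupancy probabilities 0.9/0.05/0.05) with Poisson tSC counts.
#' * `"vonfrey"`: per-trial Bernoulli responses from a logistic psychometric
#'   function of log filament strength (default threshold 0.4 g, slope 2).
#' * `"dose_response"`: 4PL curve (default bottom 0, top 100, Hill 1,
#'   EC50 1 uM) on the default 2 nM--10 uM ladder plus Gaussian noise.
#'
#' @param kind One of `"nmj"`, `"vonfrey"`, `"dose_response"`.
#' @param params Named list overriding the defaults listed above.
#' @param seed Integer seed.
#' @return List with `table` (data frame fixture) and `truth` (generating
#'   parameters, plus derived per-filament probabilities for von Frey).
#' @export
gen_tables <- function(kind = c("nmj", "vonfrey", "dose_response"),
                       params = list(), seed = 1L) {
  kind <- match.arg(kind)
  withr::with_seed(seed, {
    switch(kind,
      nmj = {
        p <- modifyList(list(tissues = "T1", n = 50L,
                             p_status = c(occupied = 0.9, altered = 0.05,
                                          unoccupied = 0.05),
                             tsc_lambda = 2.5), params)
        if (abs(sum(p$p_status) - 1) > 1e-9 || any(p$p_status < 0))
          stop("status probabilities must be nonnegative and sum to 1", call. = FALSE)
        tabs <- lapply(p$tissues, function(tid) {
          status <- sample(names(p$p_status), p$n, replace = TRUE, prob = p$p_status)
          data.frame(tissue = tid, junction = seq_len(p$n), status = status,
                     tsc_count = rpois(p$n, p$tsc_lambda),
                     stringsAsFactors = FALSE)
        })
        list(table = do.call(rbind, tabs), truth = p)
      },
      vonfrey = {
        p <- modifyList(list(animals = "A1", filaments = vonfrey_filaments(),
                             trials = 5L, threshold_g = 0.4, slope = 2), params)
        prob <- stats::plogis(p$slope * (log(p$filaments) - log(p$threshold_g)))
        rows <- expand.grid(trial = seq_len(p$trials),
                            filament_g = p$filaments, animal = p$animals,
                            stringsAsFactors = FALSE)
        pr <- prob[match(rows$filament_g, p$filaments)]
        rows$response <- rbinom(nrow(rows), 1L, pr)
        list(table = rows[, c("animal", "filament_g", "trial", "response")],
             truth = c(p, list(prob = setNames(prob, p$filaments))))
      },
      dose_response = {
        p <- modifyList(list(doses = default_dose_ladder(), bottom = 0,
                             top = 100, hill = 1, ec50 = 1e-6, noise_sd = 2),
                        params)
        mu <- p$bottom + (p$top - p$bottom) / (1 + (p$ec50 / p$doses)^p$hill)
        resp <- mu + rnorm(length(mu), 0, p$noise_sd)
        list(table = data.frame(dose_M = p$doses, response = resp),
             truth = p)
      })
  })
}
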