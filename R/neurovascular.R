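# Neurovascular quantification: engineered masks for sympathetic nerves (TH)
# and vasculature (IB4), whole-depot relative densities, Mander's overlap and
# neuro-adipose nexus (NAN) annotation tallies.

#' Filter-chain specification for nerve/vessel mask engineering
#'
#' Holds every tunable of the mask pipelines. Defaults mirror the published
#' chain: background removal by subtracting a sigma-80 Gaussian blur; unsharp
#' mask (radius 1, weight 0.60) on the vessel channel only; intensity gates
#' nerve 100--255 and vessel 15--255 for high-magnification stacks, nerve
#' 35--255 and vessel 45--255 for projected whole-depot mosaics; one 3x3
#' binary dilation, border-flood hole filling and a radius-1 (3x3) median on
#' the vessel mask.
#'
#' @param background_sigma_px Gaussian sigma for background estimation.
#' @param unsharp_radius_px,unsharp_weight Unsharp-mask parameters
#'   (vessel channel only); weight strictly inside (0, 1).
#' @param nerve_highmag,vessel_highmag,nerve_depot,vessel_depot Inclusive
#'   intensity gates, length-2 each.
#' @param dilate,fill_holes Logical morphology toggles for the vessel mask.
#' @param median_radius 0 disables the median; 1 = 3x3 neighborhood.
#' @return Object of class `filter_chain_spec`.
#' @export
filter_chain_spec <- function(background_sigma_px = 80,
                              unsharp_radius_px = 1,
                              unsharp_weight = 0.60,
                              nerve_highmag = c(100, 255),
                              vessel_highmag = c(15, 255),
                              nerve_depot = c(35, 255),
                              vessel_depot = c(45, 255),
                              dilate = TRUE,
                              fill_holes = TRUE,
                              median_radius = 1) {
  if (background_sigma_px <= 0) stop("`background_sigma_px` must be > 0", call. = FALSE)
  if (unsharp_weight <= 0 || unsharp_weight >= 1)
    stop("`unsharp_weight` must lie strictly inside (0, 1)", call. = FALSE)
  for (g in list(nerve_highmag, vessel_highmag, nerve_depot, vessel_depot))
    if (length(g) != 2L || g[1L] > g[2L] || g[1L] < 0 || g[2L] > 255)
      stop("intensity gates must be valid intervals within [0, 255]", call. = FALSE)
  structure(list(background_sigma_px = background_sigma_px,
                 unsharp_radius_px = unsharp_radius_px,
                 unsharp_weight = unsharp_weight,
                 nerve_highmag = nerve_highmag, vessel_highmag = vessel_highmag,
                 nerve_depot = nerve_depot, vessel_depot = vessel_depot,
                 dilate = dilate, fill_holes = fill_holes,
                 median_radius = median_radius),
            class = "filter_chain_spec")
}

#' Gaussian blur
#'
#' Separable Gaussian convolution (kernel truncated at 3 sigma, renormalized,
#' replicate boundaries). A constant image is an exact fixed point.
#'
#' @param image [raster_image()] or matrix.
#' @param sigma_px Standard deviation in pixels (> 0).
#' @return Same type as the input pixels (a [raster_image()] when given one).
#' @export
gaussian_blur <- function(image, sigma_px) {
  px <- as_pixels(image)
  out <- gaussian_blur_cpp(px, sigma_px)
  wrap_like(image, pmin(pmax(out, 0), 255))
}

wrap_like <- function(template, px) {
  if (inherits(template, "raster_image"))
    raster_image(px, pixel_size_um = template$pixel_size_um,
                 channel_label = template$channel_label)
  else px
}

#' Subtract a Gaussian-blur background estimate
#'
#' `output = max(0, input - gaussian(input, sigma))`. Removes smooth
#' background (e.g. out-of-focus haze) while preserving structures much
#' smaller than sigma.
#'
#' @inheritParams gaussian_blur
#' @return Background-subtracted image; never negative, never above the input.
#' @export
subtract_background <- function(image, sigma_px = 80) {
  px <- as_pixels(image)
  bg <- gaussian_blur_cpp(px, sigma_px)
  wrap_like(image, pmax(px - bg, 0))
}

#' Unsharp mask
#'
#' `output = clamp((input - weight * gaussian(input, radius)) / (1 - weight))`
#' on the 0--255 scale -- the convention under which a fractional "mask
#' weight" is meaningful, and which leaves constant images unchanged.
#'
#' @param image [raster_image()] or matrix.
#' @param radius_px Gaussian sigma of the blur (pixels).
#' @param weight Mask weight, strictly inside (0, 1).
#' @return Sharpened image clamped to `[0, 255]`.
#' @export
unsharp <- function(image, radius_px = 1, weight = 0.60) {
  if (weight <= 0 || weight >= 1)
    stop("`weight` must lie strictly inside (0, 1)", call. = FALSE)
  px <- as_pixels(image)
  out <- (px - weight * gaussian_blur_cpp(px, radius_px)) / (1 - weight)
  wrap_like(image, pmin(pmax(out, 0), 255))
}

#' Binary mask morphology
#'
#' `dilate_mask()`: one pass of 3x3 dilation. `fill_holes_mask()`: background
#' 4-connected to the border stays background; enclosed holes become
#' foreground. `median_filter_mask()`: 3x3 majority vote (removes isolated
#' single-pixel noise; out-of-bounds neighbors count as background).
#'
#' @param mask Logical matrix or [binary_mask()].
#' @return A [binary_mask()].
#' @export
dilate_mask <- function(mask) {
  m <- as_mask(mask)
  binary_mask(dilate3x3_cpp(m), provenance = "dilate3x3")
}

#' @rdname dilate_mask
#' @export
fill_holes_mask <- function(mask) {
  m <- as_mask(mask)
  binary_mask(fill_holes_cpp(m), provenance = "fill_holes")
}

#' @rdname dilate_mask
#' @export
median_filter_mask <- function(mask) {
  m <- as_mask(mask)
  binary_mask(median3x3_cpp(m), provenance = "median3x3")
}

#' Engineer a nerve mask from a high-magnification Z-stack
#'
#' Chain: Z-maximum projection, Gaussian-background subtraction
#' (sigma = `spec$background_sigma_px`), then the nerve high-magnification
#' gate (default 100--255).
#'
#' @param stack A [channel_stack()] (nerve channel, e.g. TH).
#' @param spec A [filter_chain_spec()].
#' @return A [binary_mask()].
#' @export
make_nerve_mask <- function(stack, spec = filter_chain_spec()) {
  proj <- zmax_project(stack)
  bs <- subtract_background(proj, spec$background_sigma_px)
  m <- as_mask(threshold_mask(bs, spec$nerve_highmag[1L], spec$nerve_highmag[2L]))
  binary_mask(m, provenance = "nerve:zmax>bgsub>gate")
}

#' Engineer a vessel mask from a high-magnification Z-stack
#'
#' Chain: Z-maximum projection, background subtraction, unsharp mask
#' (radius 1, weight 0.60), vessel gate (default 15--255), then boundary
#' refinement: one 3x3 dilation, hole filling and a 3x3 median, in that
#' order.
#'
#' @param stack A [channel_stack()] (vessel channel, e.g. IB4).
#' @param spec A [filter_chain_spec()].
#' @return A [binary_mask()].
#' @export
make_vessel_mask <- function(stack, spec = filter_chain_spec()) {
  proj <- zmax_project(stack)
  bs <- subtract_background(proj, spec$background_sigma_px)
  sh <- unsharp(bs, spec$unsharp_radius_px, spec$unsharp_weight)
  m <- as_mask(threshold_mask(sh, spec$vessel_highmag[1L], spec$vessel_highmag[2L]))
  if (isTRUE(spec$dilate)) m <- dilate3x3_cpp(m)
  if (isTRUE(spec$fill_holes)) m <- fill_holes_cpp(m)
  if (spec$median_radius >= 1) m <- median3x3_cpp(m)
  binary_mask(m, provenance = "vessel:zmax>bgsub>unsharp>gate>dilate>fill>median")
}

#' Relative density of a mask within a tissue ROI
#'
#' `density = |mask AND roi| / |roi|`; the standard whole-depot readout
#' (labeled area normalized to total tissue area).
#'
#' @param mask,roi Logical matrices of the same shape; `roi` nonempty.
#' @return List with `mask_area_px`, `roi_area_px`, `relative_density`.
#' @export
relative_density <- function(mask, roi) {
  m <- as_mask(mask); r <- as_mask(roi)
  if (!all(dim(m) == dim(r))) stop("mask and roi must share the same shape", call. = FALSE)
  roi_area <- sum(r)
  if (roi_area == 0L) stop("empty ROI", call. = FALSE)
  inside <- sum(m & r)
  list(mask_area_px = inside, roi_area_px = roi_area,
       relative_density = inside / roi_area)
}

#' Whole-depot densities from projected mosaics
#'
#' Applies the whole-depot gates (no background subtraction) to the projected
#' nerve and vessel mosaics within the tissue ROI and reports relative nerve
#' density, relative vessel density and the nerve/vessel area ratio.
#'
#' @param nerve_mosaic,vessel_mosaic [raster_image()]s (projected mosaics).
#' @param roi Logical tissue mask (e.g. from [rasterize_roi()]).
#' @param spec A [filter_chain_spec()].
#' @return List with `nerve`, `vessel` (each a [relative_density()] result)
#'   and `neurovascular_ratio` (nerve area / vessel area, `NA` if no vessel).
#' @export
depot_densities <- function(nerve_mosaic, vessel_mosaic, roi,
                            spec = filter_chain_spec()) {
  nm <- threshold_mask(nerve_mosaic, spec$nerve_depot[1L], spec$nerve_depot[2L])
  vm <- threshold_mask(vessel_mosaic, spec$vessel_depot[1L], spec$vessel_depot[2L])
  dn <- relative_density(nm, roi)
  dv <- relative_density(vm, roi)
  list(nerve = dn, vessel = dv,
       neurovascular_ratio = if (dv$mask_area_px > 0)
         dn$mask_area_px / dv$mask_area_px else NA_real_)
}

#' Mander's overlap coefficients between two masks
#'
#' `m1 = |A AND B| / |A|` (fraction of mask A inside B), `m2 = |A AND B| / |B|`,
#' and the symmetric overlap coefficient `moc = |A AND B| / sqrt(|A| |B|)`.
#'
#' @param a,b Logical matrices of the same shape, both nonempty.
#' @return List with `m1`, `m2`, `moc` and the raw pixel counts.
#' @export
manders_overlap <- function(a, b) {
  ma <- as_mask(a); mb <- as_mask(b)
  if (!all(dim(ma) == dim(mb))) stop("masks must share the same shape", call. = FALSE)
  na <- sum(ma); nb <- sum(mb)
  if (na == 0L && nb == 0L) stop("both masks are empty: coefficients undefined", call. = FALSE)
  if (na == 0L) stop("mask `a` is empty: m1 and moc undefined", call. = FALSE)
  if (nb == 0L) stop("mask `b` is empty: m2 and moc undefined", call. = FALSE)
  nab <- sum(ma & mb)
  list(m1 = nab / na, m2 = nab / nb, moc = nab / sqrt(na * nb),
       area_a_px = na, area_b_px = nb, overlap_px = nab)
}

#' Summarize point annotations of neuro-adipose nexuses (NANs)
#'
#' NANs are identified visually and marked as points on the whole-depot
#' mosaic; this tallies them and computes, for the density color coding, how
#' many neighboring annotations fall within `radius` of each point. When a
#' tissue ROI is supplied only points inside it are counted.
#'
#' @param points Two-column matrix of 0-based (row, col) positions (may have
#'   zero rows).
#' @param mosaic_shape Integer `c(rows, cols)` bounds.
#' @param radius Neighbor-overlap radius in pixels.
#' @param roi Optional logical tissue mask of shape `mosaic_shape`.
#' @return List with `count`, `neighbor_counts` (one per retained point) and
#'   the retained `points`.
#' @export
nan_summary <- function(points, mosaic_shape, radius, roi = NULL) {
  pts <- matrix(as.numeric(points), ncol = 2L)
  if (nrow(pts) > 0L) {
    if (any(pts[, 1L] < 0) || any(pts[, 1L] >= mosaic_shape[1L]) ||
        any(pts[, 2L] < 0) || any(pts[, 2L] >= mosaic_shape[2L]))
      stop("annotation point outside the mosaic bounds", call. = FALSE)
  }
  if (!is.null(roi) && nrow(pts) > 0L) {
    r <- as_mask(roi)
    keep <- r[cbind(floor(pts[, 1L]) + 1L, floor(pts[, 2L]) + 1L)]
    pts <- pts[keep, , drop = FALSE]
  }
  if (nrow(pts) == 0L)
    return(list(count = 0L, neighbor_counts = integer(0), points = pts))
  list(count = nrow(pts),
       neighbor_counts = neighbor_counts_cpp(pts[, 1L], pts[, 2L], radius),
       points = pts)
}

#' Mean nerve-on-vessel overlap across fields of a tissue
#'
#' Runs the high-magnification mask chains on each (nerve, vessel) stack pair
#' and averages the per-field coefficients -- the per-tissue summary used
#' when five representative vessel fields are imaged per tissue. The headline
#' coefficient is m1 with A = nerve mask, B = vessel mask (fraction of nerve
#' signal lying on vessels); all three coefficients are reported.
#'
#' @param stack_pairs List of `list(nerve =, vessel =)` [channel_stack()]s.
#' @param spec A [filter_chain_spec()].
#' @return List with per-field coefficient rows (`fields`) and tissue means
#'   `m1`, `m2`, `moc`.
#' @export
overlap_tissue <- function(stack_pairs, spec = filter_chain_spec()) {
  if (length(stack_pairs) < 1L) stop("need at least one stack pair", call. = FALSE)
  per <- lapply(stack_pairs, function(sp) {
    nm <- make_nerve_mask(sp$nerve, spec)
    vm <- make_vessel_mask(sp$vessel, spec)
    manders_overlap(nm, vm)
  })
  list(fields = per,
       m1 = mean(vapply(per, `[[`, numeric(1), "m1")),
       m2 = mean(vapply(per, `[[`, numeric(1), "m2")),
       moc = mean(vapply(per, `[[`, numeric(1), "moc")))
}
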