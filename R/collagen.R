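# Picrosirius-red collagen quantification.
#
# Under circularly polarized light, birefringent collagen fibers appear with
# hues that track fiber thickness: green/yellow for thin fibrils, orange/red
# for thick ones. Total collagen is scored as the ratio of birefringent area
# (polarized image) to total stained area (bright-field image), a ratiometric
# readout insensitive to adipocyte size and number.

#' Hue-bin specification for birefringence classification
#'
#' Inclusive hue intervals on the 0--255 scale for each birefringence color
#' class, plus the brightness gate applied before classification. Defaults:
#' green 52--128, yellow 39--51, orange 10--38, red 0--9 and 230--255;
#' brightness gate 35--255. Hues 129--229 pass no class and are tallied as
#' `unclassified_bright` for QC. Saturation is not used.
#'
#' @param green,yellow,orange,red Two-column matrices of inclusive
#'   `[lo, hi]` hue intervals (one row per interval).
#' @param brightness Length-2 inclusive brightness gate.
#' @return Object of class `hue_bin_spec`.
#' @export
hue_bin_spec <- function(green = rbind(c(52, 128)),
                         yellow = rbind(c(39, 51)),
                         orange = rbind(c(10, 38)),
                         red = rbind(c(0, 9), c(230, 255)),
                         brightness = c(35, 255)) {
  spec <- structure(
    list(classes = list(green = as_intervals(green), yellow = as_intervals(yellow),
                        orange = as_intervals(orange), red = as_intervals(red)),
         brightness = brightness),
    class = "hue_bin_spec"
  )
  validate_hue_bin_spec(spec)
  spec
}

as_intervals <- function(x) {
  m <- matrix(as.numeric(x), ncol = 2L)
  colnames(m) <- c("lo", "hi")
  m
}

#' Validate a hue-bin specification
#'
#' Checks every interval lies within `[0, 255]` with `lo <= hi`, that the
#' brightness gate is a valid interval, and -- by enumeration over the 256
#' integer hues -- that no hue belongs to two classes.
#'
#' @param spec A [hue_bin_spec()].
#' @return The spec, invisibly; errors name the violation.
#' @export
validate_hue_bin_spec <- function(spec) {
  b <- spec$brightness
  if (length(b) != 2L || b[1L] > b[2L] || b[1L] < 0 || b[2L] > 255)
    stop("invalid brightness gate", call. = FALSE)
  member <- matrix(FALSE, 256L, length(spec$classes),
                   dimnames = list(NULL, names(spec$classes)))
  for (cls in names(spec$classes)) {
    iv <- spec$classes[[cls]]
    if (any(iv[, "lo"] > iv[, "hi"]) || any(iv < 0) || any(iv > 255))
      stop(sprintf("invalid hue interval in class '%s'", cls), call. = FALSE)
    for (k in seq_len(nrow(iv)))
      member[(0:255) >= iv[k, "lo"] & (0:255) <= iv[k, "hi"], cls] <- TRUE
  }
  n_classes <- rowSums(member)
  if (any(n_classes > 1L)) {
    hue <- which(n_classes > 1L)[1L] - 1L
    clash <- paste(colnames(member)[member[hue + 1L, ]], collapse = ", ")
    stop(sprintf("overlapping hue intervals: hue %d belongs to classes %s",
                 hue, clash), call. = FALSE)
  }
  invisible(spec)
}

#' Classify birefringent pixels by hue
#'
#' Converts the polarized-light image to HSB, applies the brightness gate,
#' rounds hue to the nearest integer bin and assigns each gate-passing pixel
#' to at most one hue class. Gate-passing pixels whose hue falls in no class
#' interval (the 129--229 band under the default spec) are tallied as
#' `unclassified_bright` and excluded from the birefringent area.
#'
#' @param polarized An [rgb_image()] captured under polarized light.
#' @param spec A [hue_bin_spec()].
#' @return List with `class_counts_px` (named integer vector), `masks`
#'   (per-class [binary_mask()]s), `birefringent_area_px`,
#'   `unclassified_bright_px` and `gate_px`.
#' @export
classify_birefringence <- function(polarized, spec = hue_bin_spec()) {
  validate_hue_bin_spec(spec)
  hsb <- rgb_to_hsb(polarized)
  gate <- hsb$v >= spec$brightness[1L] & hsb$v <= spec$brightness[2L]
  hue <- round(hsb$h)
  masks <- list()
  counts <- integer(length(spec$classes))
  names(counts) <- names(spec$classes)
  classified <- matrix(FALSE, nrow(hue), ncol(hue))
  for (cls in names(spec$classes)) {
    iv <- spec$classes[[cls]]
    inclass <- matrix(FALSE, nrow(hue), ncol(hue))
    for (k in seq_len(nrow(iv)))
      inclass <- inclass | (hue >= iv[k, "lo"] & hue <= iv[k, "hi"])
    m <- gate & inclass
    masks[[cls]] <- binary_mask(m, provenance = paste0("hue:", cls))
    counts[[cls]] <- sum(m)
    classified <- classified | m
  }
  list(class_counts_px = counts,
       masks = masks,
       birefringent_area_px = sum(counts),
       unclassified_bright_px = sum(gate & !classified),
       gate_px = sum(gate))
}

#' Segment picrosirius-red stain in a bright-field image
#'
#' Default gate: hue in the red/orange band (0--38 or 230--255) and
#' saturation at least `min_saturation`. Thresholds are configuration, not
#' biology: the stain segmentation method is a package choice.
#'
#' @param image Bright-field [rgb_image()].
#' @param hue_intervals Two-column matrix of inclusive hue intervals.
#' @param min_saturation Minimum saturation (0--255) for a stained pixel.
#' @return A [binary_mask()] of stained pixels.
#' @export
segment_psr_brightfield <- function(image,
                                    hue_intervals = rbind(c(0, 38), c(230, 255)),
                                    min_saturation = 60) {
  hsb <- rgb_to_hsb(image)
  hue <- round(hsb$h)
  iv <- as_intervals(hue_intervals)
  sel <- matrix(FALSE, nrow(hue), ncol(hue))
  for (k in seq_len(nrow(iv)))
    sel <- sel | (hue >= iv[k, "lo"] & hue <= iv[k, "hi"])
  binary_mask(sel & hsb$s >= min_saturation, provenance = "psr_brightfield")
}

#' Total-collagen ratio
#'
#' Ratio of birefringent collagen area (polarized light) to total
#' picrosirius-red stained area (bright field). Being a ratio of areas within
#' the same section, it is unaffected by uniform changes in cell size or
#' number. `invert = TRUE` reports stain/birefringence instead.
#'
#' @param birefringent_area_px,psr_area_px Pixel counts.
#' @param invert Report the reciprocal orientation.
#' @return Dimensionless ratio.
#' @export
total_collagen_ratio <- function(birefringent_area_px, psr_area_px,
                                 invert = FALSE) {
  if (psr_area_px <= 0)
    stop("undefined field: bright-field PSR area is zero", call. = FALSE)
  if (birefringent_area_px < 0) stop("areas must be nonnegative", call. = FALSE)
  if (invert) {
    if (birefringent_area_px <= 0)
      stop("undefined field: birefringent area is zero (invert = TRUE)", call. = FALSE)
    psr_area_px / birefringent_area_px
  } else {
    birefringent_area_px / psr_area_px
  }
}

#' Thin/thick fiber fractions from hue-class counts
#'
#' Thin fibers = green + yellow; thick fibers = orange + red (the class split
#' is configurable). Fractions are of classified (birefringent) pixels and
#' sum to 1.
#'
#' @param class_counts Named numeric vector of per-class pixel counts.
#' @param thin,thick Character vectors naming the classes in each group.
#' @return List with `thin_fraction`, `thick_fraction` and `class_fractions`.
#' @export
fiber_thickness_fractions <- function(class_counts,
                                      thin = c("green", "yellow"),
                                      thick = c("orange", "red")) {
  if (length(class_counts) == 0L || any(class_counts < 0))
    stop("class counts must be nonnegative", call. = FALSE)
  total <- sum(class_counts)
  if (total <= 0)
    stop("undefined field: no classified birefringent pixels", call. = FALSE)
  fr <- class_counts / total
  list(thin_fraction = sum(fr[names(fr) %in% thin]),
       thick_fraction = sum(fr[names(fr) %in% thick]),
       class_fractions = fr)
}

#' Analyze one bright-field/polarized field pair
#'
#' @param brightfield,polarized [rgb_image()]s of the same field.
#' @param spec A [hue_bin_spec()].
#' @param ... Passed to [segment_psr_brightfield()].
#' @return A `psr_field_result` list: `psr_area_px`, `class_counts_px`,
#'   `birefringent_area_px`, `unclassified_bright_px`, `total_collagen_ratio`,
#'   `thin_fraction`, `thick_fraction`, `class_fractions`. Fields with zero
#'   stain or zero classified pixels carry `NA` ratios and a `degenerate`
#'   flag.
#' @export
analyze_psr_field <- function(brightfield, polarized, spec = hue_bin_spec(), ...) {
  if (!all(dim(brightfield$r) == dim(polarized$r)))
    stop("bright-field and polarized images must share the same shape", call. = FALSE)
  stain <- segment_psr_brightfield(brightfield, ...)
  cls <- classify_birefringence(polarized, spec)
  psr_area <- attr(stain, "area_px")
  res <- list(psr_area_px = psr_area,
              class_counts_px = cls$class_counts_px,
              birefringent_area_px = cls$birefringent_area_px,
              unclassified_bright_px = cls$unclassified_bright_px,
              total_collagen_ratio = NA_real_,
              thin_fraction = NA_real_, thick_fraction = NA_real_,
              class_fractions = rep(NA_real_, length(cls$class_counts_px)),
              degenerate = FALSE)
  if (psr_area > 0) {
    res$total_collagen_ratio <- total_collagen_ratio(cls$birefringent_area_px, psr_area)
  } else {
    res$degenerate <- TRUE
  }
  if (cls$birefringent_area_px > 0) {
    fr <- fiber_thickness_fractions(cls$class_counts_px)
    res$thin_fraction <- fr$thin_fraction
    res$thick_fraction <- fr$thick_fraction
    res$class_fractions <- fr$class_fractions
  } else {
    res$degenerate <- TRUE
  }
  structure(res, class = "psr_field_result")
}

#' Analyze a tissue from multiple field pairs
#'
#' Runs [analyze_psr_field()] on each (bright-field, polarized) pair -- the
#' standard design captures five representative fields per tissue -- and
#' returns per-field results plus per-tissue arithmetic means. Degenerate
#' fields (zero stain or zero birefringence) are excluded from the means with
#' a warning.
#'
#' @param field_pairs List of `list(brightfield =, polarized =)` pairs.
#' @param spec A [hue_bin_spec()].
#' @param ... Passed to [segment_psr_brightfield()].
#' @return A `psr_tissue_result`: `fields` (list of field results) and
#'   `tissue_means` (ratio, thin/thick and per-class fractions, with
#'   `n_fields_used`).
#' @export
analyze_psr_tissue <- function(field_pairs, spec = hue_bin_spec(), ...) {
  if (!is.list(field_pairs) || length(field_pairs) < 1L)
    stop("need at least one field pair", call. = FALSE)
  fields <- lapply(field_pairs, function(fp)
    analyze_psr_field(fp$brightfield, fp$polarized, spec = spec, ...))
  ok <- !vapply(fields, `[[`, logical(1), "degenerate")
  if (!all(ok))
    warning(sprintf("%d degenerate field(s) excluded from tissue means", sum(!ok)),
            call. = FALSE)
  if (!any(ok)) stop("all fields degenerate; no tissue means", call. = FALSE)
  mean_of <- function(f) mean(vapply(fields[ok], `[[`, numeric(1), f))
  class_mat <- do.call(rbind, lapply(fields[ok], `[[`, "class_fractions"))
  structure(
    list(fields = fields,
         tissue_means = list(
           total_collagen_ratio = mean_of("total_collagen_ratio"),
           thin_fraction = mean_of("thin_fraction"),
           thick_fraction = mean_of("thick_fraction"),
           class_fractions = colMeans(class_mat),
           n_fields_used = sum(ok))),
    class = "psr_tissue_result"
  )
}
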