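# Intraepidermal nerve-fiber (IENF) density: pan-neuronal fluorescence within
# an epidermal ROI, auto-thresholded per image with the intermodes method to
# remove skin autofluorescence.

#' Intraepidermal nerve-fiber density for one section
#'
#' Computes the intensity histogram within the epidermal ROI (or the whole
#' image, if requested), finds the intermodes threshold, and reports the
#' fraction of ROI pixels at or above it. The upper gate is fixed at 255;
#' intermodes supplies the lower gate only. A manual `threshold` overrides
#' the automatic one (QC escape hatch when the ROI histogram is not bimodal).
#'
#' @param image A [raster_image()] (e.g. PGP9.5 channel).
#' @param epidermis A [polygon_roi()] outlining the epidermal band.
#' @param threshold Optional manual lower threshold (0--255); skips
#'   intermodes.
#' @param whole_image_hist Compute the histogram over the whole image rather
#'   than the ROI (default `FALSE`).
#' @return An `ienf_result` list: `threshold_used`, `nerve_area_px`,
#'   `roi_area_px`, `density`.
#' @export
ienf_density <- function(image, epidermis, threshold = NULL,
                         whole_image_hist = FALSE) {
  px <- as_pixels(image)
  roi <- rasterize_roi(epidermis, dim(px))
  roi_area <- sum(roi)
  if (roi_area == 0L) stop("epidermal ROI covers no pixels", call. = FALSE)
  thr <- if (!is.null(threshold)) {
    if (threshold < 0 || threshold > 255)
      stop("manual threshold must lie within [0, 255]", call. = FALSE)
    threshold
  } else {
    vals <- if (whole_image_hist) px else px[roi]
    h <- tabulate(pmin(pmax(as.integer(round(vals)), 0L), 255L) + 1L, nbins = 256L)
    tryCatch(intermodes_threshold(h), error = function(e)
      stop(paste0(conditionMessage(e),
                  " (supply `threshold =` to override manually)"), call. = FALSE))
  }
  nerve_area <- sum(px[roi] >= thr)
  structure(list(threshold_used = thr, nerve_area_px = nerve_area,
                 roi_area_px = roi_area, density = nerve_area / roi_area),
            class = "ienf_result")
}

#' Per-tissue IENF density over multiple sections
#'
#' @param sections List of `list(image =, roi =)` pairs.
#' @param ... Passed to [ienf_density()].
#' @return List with per-section results and their mean `density`.
#' @export
ienf_tissue <- function(sections, ...) {
  if (length(sections) < 1L) stop("need at least one section", call. = FALSE)
  per <- lapply(sections, function(s) ienf_density(s$image, s$roi, ...))
  list(sections = per,
       density = mean(vapply(per, `[[`, numeric(1), "density")))
}
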