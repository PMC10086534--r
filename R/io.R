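# Plain-text interchange formats. No TIFF reader ships in the supported
# environment, so rasters travel as headerless TSV matrices (one row per
# image row), masks as 0/1 TSV, ROIs and tables as CSV, configs and reports
# as JSON.

#' Read/write a raster as a headerless TSV matrix
#'
#' @param image A [raster_image()] (or matrix for `write_raster_tsv`).
#' @param path File path.
#' @param pixel_size_um,channel_label Metadata attached on read.
#' @return `read_raster_tsv` returns a [raster_image()].
#' @export
write_raster_tsv <- function(image, path) {
  data.table::fwrite(as.data.frame(as_pixels(image)), path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_raster_tsv
#' @export
read_raster_tsv <- function(path, pixel_size_um = 1, channel_label = "") {
  m <- as.matrix(data.table::fread(path, sep = "\t", header = FALSE))
  dimnames(m) <- NULL
  raster_image(m, pixel_size_um = pixel_size_um, channel_label = channel_label)
}

#' Read/write a binary mask as 0/1 TSV
#'
#' @param mask A [binary_mask()] or logical matrix.
#' @param path File path.
#' @return `read_mask_tsv` returns a [binary_mask()].
#' @export
write_mask_tsv <- function(mask, path) {
  data.table::fwrite(as.data.frame(as_mask(mask) * 1L), path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_mask_tsv
#' @export
read_mask_tsv <- function(path) {
  m <- as.matrix(data.table::fread(path, sep = "\t", header = FALSE))
  dimnames(m) <- NULL
  binary_mask(m != 0, provenance = path)
}

#' Read/write a polygon ROI as CSV vertex list (columns row, col)
#'
#' @param roi A [polygon_roi()].
#' @param path File path.
#' @return `read_roi_csv` returns a [polygon_roi()].
#' @export
write_roi_csv <- function(roi, path) {
  data.table::fwrite(as.data.frame(roi$vertices), path)
  invisible(path)
}

#' @rdname write_roi_csv
#' @export
read_roi_csv <- function(path) {
  df <- data.table::fread(path, header = TRUE)
  if (!all(c("row", "col") %in% names(df)))
    stop("ROI CSV must have columns `row` and `col`", call. = FALSE)
  polygon_roi(cbind(df$row, df$col))
}
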