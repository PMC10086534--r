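# Raster substrate: images on the 0-255 intensity scale, pixel coordinates
# 0-based and row-major, pixel (r, c) covering the unit square
# [r, r+1) x [c, c+1) with its center at (r + 0.5, c + 0.5).

#' Single-channel raster image
#'
#' Constructs an intensity image on the 0--255 scale with a physical pixel
#' size. All pipelines in the package operate on this type (or on
#' [rgb_image()] / [channel_stack()] built from it).
#'
#' @param pixels Numeric matrix with all values in `[0, 255]`.
#' @param pixel_size_um Micrometers per pixel edge (> 0).
#' @param channel_label Free-text channel description (e.g. `"TH"`, `"IB4"`).
#' @return An object of class `raster_image` with fields `pixels`,
#'   `pixel_size_um` and `channel_label`.
#' @export
raster_image <- function(pixels, pixel_size_um = 1, channel_label = "") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must have at least one row and one column", call. = FALSE)
  if (anyNA(pixels) || any(pixels < 0) || any(pixels > 255))
    stop("pixel intensities must lie within [0, 255]", call. = FALSE)
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L || pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number", call. = FALSE)
  structure(
    list(pixels = pixels, pixel_size_um = pixel_size_um,
         channel_label = as.character(channel_label)),
    class = "raster_image"
  )
}

#' @export
print.raster_image <- function(x, ...) {
  cat(sprintf("<raster_image> %d x %d px, %.4g um/px%s\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
              if (nzchar(x$channel_label)) paste0(" [", x$channel_label, "]") else ""))
  invisible(x)
}

as_pixels <- function(image) {
  if (inherits(image, "raster_image")) image$pixels
  else if (is.matrix(image) && is.numeric(image)) image
  else stop("expected a raster_image or numeric matrix", call. = FALSE)
}

#' Three-plane RGB image
#'
#' @param r,g,b Numeric matrices of identical shape, values in `[0, 255]`.
#' @param pixel_size_um Micrometers per pixel edge.
#' @return Object of class `rgb_image`.
#' @export
rgb_image <- function(r, g, b, pixel_size_um = 1) {
  planes <- list(r = r, g = g, b = b)
  for (nm in names(planes)) {
    p <- planes[[nm]]
    if (!is.matrix(p) || !is.numeric(p))
      stop(sprintf("plane `%s` must be a numeric matrix", nm), call. = FALSE)
    if (anyNA(p) || any(p < 0) || any(p > 255))
      stop(sprintf("plane `%s` must lie within [0, 255]", nm), call. = FALSE)
  }
  if (!all(dim(g) == dim(r)) || !all(dim(b) == dim(r)))
    stop("RGB planes must share the same shape", call. = FALSE)
  structure(list(r = r, g = g, b = b, pixel_size_um = pixel_size_um),
            class = "rgb_image")
}

#' Hue/saturation/brightness image on the 0-255 scale
#'
#' Hue is carried on a 0--255 wraparound scale (360 degrees mapped linearly
#' onto 256 steps); saturation and brightness on 0--255. Saturation is carried
#' for completeness but ignored by the polarized-light collagen classifier.
#'
#' @param h,s,v Numeric matrices of identical shape; `h` in `[0, 255]`.
#' @param pixel_size_um Micrometers per pixel edge.
#' @return Object of class `hsb_image`.
#' @export
hsb_image <- function(h, s, v, pixel_size_um = 1) {
  if (!all(dim(s) == dim(h)) || !all(dim(v) == dim(h)))
    stop("HSB planes must share the same shape", call. = FALSE)
  if (any(h < 0) || any(h > 255)) stop("hue must lie within [0, 255]", call. = FALSE)
  structure(list(h = h, s = s, v = v, pixel_size_um = pixel_size_um),
            class = "hsb_image")
}

#' Convert RGB to hue/saturation/brightness
#'
#' Standard RGB-to-HSV conversion with the hue angle rescaled from degrees to
#' the 0--255 scale (`hue = degrees * 255 / 360`) and brightness defined as
#' `max(R, G, B)`. Achromatic pixels get hue 0 by convention.
#'
#' @param image An [rgb_image()].
#' @return An [hsb_image()] of the same shape.
#' @examples
#' px <- rgb_to_hsb(rgb_image(matrix(0), matrix(255), matrix(0)))
#' px$h  # 85 = 120 degrees on the 0-255 scale
#' @export
rgb_to_hsb <- function(image) {
  if (!inherits(image, "rgb_image")) stop("`image` must be an rgb_image", call. = FALSE)
  r <- image$r / 255; g <- image$g / 255; b <- image$b / 255
  v <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  d <- v - mn
  s <- ifelse(v > 0, d / v, 0)
  h6 <- matrix(0, nrow(r), ncol(r))
  nz <- d > 0
  is_r <- nz & (v == r)
  is_g <- nz & !is_r & (v == g)
  is_b <- nz & !is_r & !is_g
  h6[is_r] <- (((g - b) / d)[is_r]) %% 6
  h6[is_g] <- ((b - r) / d)[is_g] + 2
  h6[is_b] <- ((r - g) / d)[is_b] + 4
  hsb_image(h = h6 * 60 * 255 / 360, s = s * 255, v = v * 255,
            pixel_size_um = image$pixel_size_um)
}

#' Convert hue/saturation/brightness planes to RGB
#'
#' Inverse of [rgb_to_hsb()] (hue on the 0--255 scale). Used by the synthetic
#' generators to paint pixels with exactly known hue.
#'
#' @param h,s,v Numeric matrices (or scalars recycled to `h`'s shape).
#' @param pixel_size_um Micrometers per pixel edge.
#' @return An [rgb_image()].
#' @export
hsb_to_rgb <- function(h, s, v, pixel_size_um = 1) {
  if (!is.matrix(h)) h <- as.matrix(h)
  if (length(s) == 1L) s <- matrix(s, nrow(h), ncol(h))
  if (length(v) == 1L) v <- matrix(v, nrow(h), ncol(h))
  hd <- (h * 360 / 255) %% 360
  sv <- s / 255; vv <- v / 255
  c_ <- vv * sv
  x_ <- c_ * (1 - abs((hd / 60) %% 2 - 1))
  m_ <- vv - c_
  sector <- pmin(floor(hd / 60), 5)
  r <- g <- b <- matrix(0, nrow(h), ncol(h))
  pick <- function(vals, sec) {
    out <- matrix(0, nrow(h), ncol(h))
    for (k in 0:5) {
      sel <- sector == k
      out[sel] <- vals[[k + 1L]][sel]
    }
    out
  }
  r <- pick(list(c_, x_, 0 * c_, 0 * c_, x_, c_))
  g <- pick(list(x_, c_, c_, x_, 0 * c_, 0 * c_))
  b <- pick(list(0 * c_, 0 * c_, x_, c_, c_, x_))
  rgb_image((r + m_) * 255, (g + m_) * 255, (b + m_) * 255,
            pixel_size_um = pixel_size_um)
}

#' Z-stack of single-channel slices
#'
#' @param slices List of numeric matrices or [raster_image()]s, all the same
#'   shape.
#' @param z_step_um Axial step between slices in micrometers (> 0).
#' @param pixel_size_um Micrometers per pixel edge.
#' @param channel_label Channel description.
#' @return Object of class `channel_stack`.
#' @export
channel_stack <- function(slices, z_step_um = 2.5, pixel_size_um = 1,
                          channel_label = "") {
  if (!is.list(slices) || length(slices) < 1L)
    stop("`slices` must be a non-empty list", call. = FALSE)
  mats <- lapply(slices, as_pixels)
  d0 <- dim(mats[[1L]])
  if (!all(vapply(mats, function(m) all(dim(m) == d0), logical(1))))
    stop("all slices must share the same shape", call. = FALSE)
  if (z_step_um <= 0) stop("`z_step_um` must be > 0", call. = FALSE)
  structure(list(slices = mats, z_step_um = z_step_um,
                 pixel_size_um = pixel_size_um,
                 channel_label = as.character(channel_label)),
            class = "channel_stack")
}

#' Maximum-intensity Z projection
#'
#' Each output pixel is the maximum over slices at that position, the standard
#' way confocal Z-stacks are flattened before tiling and masking.
#'
#' @param stack A [channel_stack()].
#' @return A [raster_image()].
#' @export
zmax_project <- function(stack) {
  if (!inherits(stack, "channel_stack")) stop("`stack` must be a channel_stack", call. = FALSE)
  raster_image(Reduce(pmax, stack$slices),
               pixel_size_um = stack$pixel_size_um,
               channel_label = stack$channel_label)
}

#' Tile images into an abutting mosaic
#'
#' Tiles are laid out row-major with no overlap; tile `(i, j)` of a
#' `rows x cols` layout occupies output rows `(i-1)*tile_h .. i*tile_h - 1`.
#'
#' @param tiles List of matrices/[raster_image()]s in row-major order.
#' @param rows,cols Layout dimensions; `rows * cols` must equal `length(tiles)`.
#' @return A [raster_image()] of shape `(rows * tile_h, cols * tile_w)`.
#' @seealso [crop_tile()] for the inverse operation.
#' @export
tile_mosaic <- function(tiles, rows, cols) {
  mats <- lapply(tiles, as_pixels)
  if (length(mats) != rows * cols)
    stop("layout does not match the number of tiles", call. = FALSE)
  d0 <- dim(mats[[1L]])
  if (!all(vapply(mats, function(m) all(dim(m) == d0), logical(1))))
    stop("ragged tiles: all tiles must share the same shape", call. = FALSE)
  band <- function(i) do.call(cbind, mats[((i - 1L) * cols + 1L):(i * cols)])
  px <- do.call(rbind, lapply(seq_len(rows), band))
  psz <- if (inherits(tiles[[1L]], "raster_image")) tiles[[1L]]$pixel_size_um else 1
  raster_image(px, pixel_size_um = psz)
}

#' Crop one tile back out of a mosaic
#'
#' @param mosaic A [raster_image()] or matrix produced by [tile_mosaic()].
#' @param i,j Tile position (1-based row/column of the layout).
#' @param tile_h,tile_w Tile shape in pixels.
#' @return A [raster_image()].
#' @export
crop_tile <- function(mosaic, i, j, tile_h, tile_w) {
  px <- as_pixels(mosaic)
  rr <- ((i - 1L) * tile_h + 1L):(i * tile_h)
  cc <- ((j - 1L) * tile_w + 1L):(j * tile_w)
  if (max(rr) > nrow(px) || max(cc) > ncol(px))
    stop("tile position outside mosaic", call. = FALSE)
  psz <- if (inherits(mosaic, "raster_image")) mosaic$pixel_size_um else 1
  raster_image(px[rr, cc, drop = FALSE], pixel_size_um = psz)
}

#' Downsample by area-weighted (linear) binning
#'
#' Block-mean binning to a target width, with the row count chosen to keep the
#' aspect ratio (`round(h * target_width / w)`). Each output pixel is the area
#' average of the source region it covers, so the image mean is conserved
#' exactly; pixel size is rescaled accordingly.
#'
#' @param image A [raster_image()] or matrix.
#' @param target_width Output width in pixels, `1 <= target_width <= width`.
#' @return A [raster_image()].
#' @export
downsample_bin <- function(image, target_width) {
  px <- as_pixels(image)
  w <- ncol(px); h <- nrow(px)
  if (target_width < 1 || target_width > w)
    stop("`target_width` must be between 1 and the image width", call. = FALSE)
  target_width <- as.integer(target_width)
  target_height <- max(1L, as.integer(round(h * target_width / w)))
  out <- area_average_resize(px, target_height, target_width)
  psz <- if (inherits(image, "raster_image")) image$pixel_size_um else 1
  raster_image(pmin(pmax(out, 0), 255), pixel_size_um = psz * w / target_width,
               channel_label = if (inherits(image, "raster_image")) image$channel_label else "")
}

# Exact area-average resize using a 2-D cumulative integral. Treats each
# source pixel as constant over its unit square; output cell (i, j) is the
# integral over its (possibly fractional) source rectangle divided by area.
area_average_resize <- function(m, out_h, out_w) {
  h <- nrow(m); w <- ncol(m)
  cs <- m
  for (j in seq_len(w)) cs[, j] <- cumsum(cs[, j])
  for (i in seq_len(h)) cs[i, ] <- cumsum(cs[i, ])
  C <- matrix(0, h + 1L, w + 1L)
  C[-1L, -1L] <- cs
  # integral of the image over [0, y] x [0, x] for vectors of boundary coords
  Fgrid <- function(ys, xs) {
    iy <- pmin(floor(ys), h - 1L); fy <- ys - iy
    ix <- pmin(floor(xs), w - 1L); fx <- xs - ix
    iy <- as.integer(iy); ix <- as.integer(ix)
    A <- C[iy + 1L, ix + 1L, drop = FALSE]
    Ry <- C[iy + 2L, ix + 1L, drop = FALSE] - A
    Rx <- C[iy + 1L, ix + 2L, drop = FALSE] - A
    Mm <- m[iy + 1L, ix + 1L, drop = FALSE]
    A + fy * Ry + sweep(Rx, 2L, fx, `*`) + sweep(fy * Mm, 2L, fx, `*`)
  }
  ys <- seq(0, h, length.out = out_h + 1L)
  xs <- seq(0, w, length.out = out_w + 1L)
  Fg <- Fgrid(ys, xs)
  block <- Fg[-1L, -1L, drop = FALSE] - Fg[-(out_h + 1L), -1L, drop = FALSE] -
    Fg[-1L, -(out_w + 1L), drop = FALSE] + Fg[-(out_h + 1L), -(out_w + 1L), drop = FALSE]
  block / ((h / out_h) * (w / out_w))
}

#' Polygon region of interest
#'
#' Vertices in 0-based `(row, col)` pixel units, implicitly closed. A pixel
#' covers the unit square `[r, r+1) x [c, c+1)`, so an axis-aligned polygon
#' from `(0, 0)` to `(10, 10)` encloses exactly the 100 pixels of a 10 x 10
#' block.
#'
#' @param vertices Two-column numeric matrix (row, col), at least 3 vertices.
#' @return Object of class `polygon_roi`.
#' @export
polygon_roi <- function(vertices) {
  v <- as.matrix(vertices)
  if (ncol(v) != 2L) stop("`vertices` must have two columns (row, col)", call. = FALSE)
  if (nrow(v) < 3L) stop("a polygon needs at least 3 vertices", call. = FALSE)
  if (abs(shoelace_area(v)) <= 0)
    stop("degenerate polygon: enclosed area must be > 0", call. = FALSE)
  colnames(v) <- c("row", "col")
  structure(list(vertices = v), class = "polygon_roi")
}

#' Shoelace (signed-area magnitude) of a vertex list
#' @param vertices Two-column matrix (row, col).
#' @return Enclosed area in squared pixel units.
#' @export
shoelace_area <- function(vertices) {
  v <- as.matrix(vertices)
  y <- v[, 1L]; x <- v[, 2L]
  y2 <- c(y[-1L], y[1L]); x2 <- c(x[-1L], x[1L])
  abs(sum(x * y2 - x2 * y)) / 2
}

#' Rasterize a polygon ROI to a binary mask
#'
#' Even-odd scanline fill over pixel centers `(r + 0.5, c + 0.5)`; the polygon
#' is clipped to the image bounds.
#'
#' @param roi A [polygon_roi()].
#' @param shape Integer vector `c(rows, cols)` of the target image.
#' @return A logical matrix (class `binary_mask`) with attributes
#'   `area_px` (pixel count) and `provenance`.
#' @export
rasterize_roi <- function(roi, shape) {
  if (!inherits(roi, "polygon_roi")) stop("`roi` must be a polygon_roi", call. = FALSE)
  nr <- as.integer(shape[1L]); nc <- as.integer(shape[2L])
  v <- roi$vertices
  n <- nrow(v)
  y1 <- v[, 1L]; x1 <- v[, 2L]
  y2 <- c(y1[-1L], y1[1L]); x2 <- c(x1[-1L], x1[1L])
  keep <- y1 != y2
  y1 <- y1[keep]; x1 <- x1[keep]; y2 <- y2[keep]; x2 <- x2[keep]
  mask <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr) - 1L) {
    yc <- r + 0.5
    hit <- (pmin(y1, y2) <= yc) & (yc < pmax(y1, y2))
    if (!any(hit)) next
    xs <- sort(x1[hit] + (yc - y1[hit]) * (x2[hit] - x1[hit]) / (y2[hit] - y1[hit]))
    for (k in seq(1L, length(xs) - 1L, by = 2L)) {
      c_lo <- max(0L, ceiling(xs[k] - 0.5))
      c_hi <- min(nc - 1L, ceiling(xs[k + 1L] - 0.5) - 1L)
      if (c_lo <= c_hi) mask[r + 1L, (c_lo:c_hi) + 1L] <- TRUE
    }
  }
  binary_mask(mask, provenance = "rasterize_roi")
}

#' Binary mask with provenance
#'
#' @param mask Logical matrix.
#' @param provenance Free text describing the filter chain that produced it.
#' @return The logical matrix with class `binary_mask` and attributes
#'   `area_px`, `provenance`.
#' @export
binary_mask <- function(mask, provenance = "") {
  if (!is.matrix(mask) || !is.logical(mask))
    stop("`mask` must be a logical matrix", call. = FALSE)
  structure(mask, class = c("binary_mask", "matrix", "array"),
            area_px = sum(mask), provenance = provenance)
}

as_mask <- function(x) {
  if (is.matrix(x) && is.logical(x)) x
  else stop("expected a logical mask matrix", call. = FALSE)
}

#' Intensity-band threshold mask
#'
#' Selects pixels with `lo <= value <= hi` (both ends inclusive, the natural
#' reading of gates quoted as e.g. "35-255").
#'
#' @param image A [raster_image()] or matrix.
#' @param lo,hi Gate bounds, `0 <= lo <= hi <= 255`.
#' @return A [binary_mask()].
#' @export
threshold_mask <- function(image, lo, hi = 255) {
  if (lo > hi) stop("`lo` must not exceed `hi`", call. = FALSE)
  if (lo < 0 || hi > 255) stop("gate must lie within [0, 255]", call. = FALSE)
  px <- as_pixels(image)
  binary_mask(px >= lo & px <= hi,
              provenance = sprintf("threshold[%g,%g]", lo, hi))
}

#' Intermodes automatic threshold
#'
#' Iteratively smooths a 256-bin histogram with a 3-bin moving mean
#' (edge-replicated) until exactly two local maxima remain, then returns the
#' integer midpoint of the two peak bins. Plateau maxima are counted once, at
#' the leftmost bin of the plateau. Fails with an error if the histogram is
#' (or becomes) unimodal, or if bimodality is not reached within `max_iter`
#' passes.
#'
#' @param x A [raster_image()], a numeric matrix (intensities, rounded to the
#'   nearest integer bin), or a length-256 histogram of counts for bins
#'   0..255.
#' @param max_iter Smoothing-pass cap (default 10000).
#' @return Integer threshold in `[0, 255]` (midpoint between the two modes).
#' @export
intermodes_threshold <- function(x, max_iter = 10000L) {
  h <- if (is.numeric(x) && is.null(dim(x)) && length(x) == 256L) {
    as.numeric(x)
  } else {
    px <- as_pixels(x)
    tabulate(pmin(pmax(as.integer(round(px)), 0L), 255L) + 1L, nbins = 256L)
  }
  if (any(h < 0)) stop("histogram counts must be nonnegative", call. = FALSE)
  if (sum(h > 0) < 2L)
    stop("intermodes: histogram needs at least two nonempty bins", call. = FALSE)
  for (iter in seq_len(max_iter + 1L)) {
    pk <- histogram_peaks(h)
    if (length(pk) == 2L) return(as.integer(floor((pk[1L] + pk[2L]) / 2)))
    if (length(pk) < 2L)
      stop("intermodes: histogram is unimodal; supply a manual threshold override",
           call. = FALSE)
    if (iter > max_iter) break
    h <- (c(h[1L], h[-256L]) + h + c(h[-1L], h[256L])) / 3
  }
  stop("intermodes: failed to reach bimodality within the iteration cap",
       call. = FALSE)
}

# 0-based bin indices of local maxima; plateaus count once (leftmost bin).
histogram_peaks <- function(h) {
  r <- rle(h)
  vals <- r$values
  k <- length(vals)
  left <- c(-Inf, vals[-k])
  right <- c(vals[-1L], -Inf)
  runs <- which(vals > left & vals > right)
  starts <- cumsum(r$lengths) - r$lengths + 1L
  starts[runs] - 1L
}
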