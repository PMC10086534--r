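# Independent reference implementations used as oracles. These deliberately
# trade speed for obviousness and share no code with the package internals.

# scalar hue-class reference: integer hue + brightness -> class name or NA
ref_classify_pixel <- function(hue, brightness) {
  if (brightness < 35 || brightness > 255) return(NA_character_)
  if (hue >= 52 && hue <= 128) return("green")
  if (hue >= 39 && hue <= 51) return("yellow")
  if (hue >= 10 && hue <= 38) return("orange")
  if ((hue >= 0 && hue <= 9) || (hue >= 230 && hue <= 255)) return("red")
  "unclassified"
}

# trapezoid rule written out longhand
ref_trapezoid <- function(x, y) {
  o <- order(x)
  x <- x[o]; y <- y[o]
  total <- 0
  for (i in seq_len(length(x) - 1))
    total <- total + (x[i + 1] - x[i]) * (y[i] + y[i + 1]) / 2
  total
}

# build a constant-intensity raster quickly
const_image <- function(value, nr = 8, nc = 8)
  raster_image(matrix(value, nr, nc))

# random simple (convex) polygon: vertices on a jittered circle, sorted by angle
random_convex_polygon <- function(center, radius, n = 12) {
  ang <- sort(runif(n, 0, 2 * pi))
  rad <- runif(n, 0.6 * radius, radius)
  polygon_roi(cbind(center[1] + rad * sin(ang), center[2] + rad * cos(ang)))
}

# random logical mask with roughly `p` coverage
random_mask <- function(nr, nc, p) matrix(runif(nr * nc) < p, nr, nc)

# single-animal von Frey trial table from per-filament positive counts
vf_table <- function(positives, filaments = vonfrey_filaments(), trials = 5L) {
  stopifnot(length(positives) == length(filaments))
  do.call(rbind, lapply(seq_along(filaments), function(i) {
    data.frame(animal = "A1", filament_g = filaments[i], trial = seq_len(trials),
               response = as.integer(seq_len(trials) <= positives[i]))
  }))
}
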