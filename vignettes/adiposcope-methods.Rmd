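---
title: "Methods: quantitative histology and physiology with adiposcope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative histology and physiology with adiposcope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adiposcope)
```

# Scope

adiposcope implements the image-analysis and physiology readouts used to
phenotype peripheral neuropathy and adipose-tissue remodeling across aging:
picrosirius-red (PSR) collagen scoring, whole-depot neurovascular
quantification, intraepidermal nerve-fiber (IENF) density, neuromuscular
junction (NMJ) occupancy and adipocyte morphometry, von Frey sensitivity
curves, and wire-myography dose-response fitting. Each analysis is paired
with a seeded synthetic-data generator that emits machine-readable ground
truth, so the whole chain is testable without any raw micrographs.

# Image substrate and conventions

All images live on the 0--255 intensity scale as numeric matrices
(`raster_image`, `rgb_image`, `channel_stack`), with a physical pixel size in
micrometers. Conventions, fixed so results are bit-reproducible:

* Pixel coordinates are 0-based and row-major; pixel $(r, c)$ covers the unit
  square $[r, r+1) \times [c, c+1)$ with its center at $(r+0.5, c+0.5)$.
* Polygon ROIs are vertex lists in (row, col) pixel units, implicitly closed,
  rasterized by even--odd scanline fill over pixel centers. An axis-aligned
  square from $(0,0)$ to $(10,10)$ therefore encloses exactly 100 pixels,
  matching its shoelace area.
* Intensity gates quoted as "35--255" are closed intervals: a pixel at
  exactly 35 passes.
* Hue is carried on a 0--255 wraparound scale (degrees $\times 255/360$);
  brightness is $\max(R,G,B)$. Pure green maps to hue 85.

# Picrosirius-red collagen

Under circularly polarized light, PSR-stained collagen is birefringent, and
the hue of the birefringence tracks fiber thickness: green/yellow for thin
fibrils, orange/red for thick fibers. Two readouts are computed per field:

* **Total-collagen ratio** = birefringent area (polarized image) / total
  stained area (bright-field image). As a within-section ratio of areas it is
  insensitive to uniform changes in adipocyte size or number, which the
  package verifies literally: duplicating every pixel 2x leaves the ratio
  unchanged to float precision.
* **Thin/thick fractions** from hue-binned birefringent pixels. Classes
  (inclusive, 0--255 hue): green 52--128, yellow 39--51, orange 10--38, red
  0--9 and 230--255. A brightness gate of 35--255 is applied first to keep
  camera noise out of pixel counts; saturation is deliberately ignored.
  Gate-passing hues 129--229 (blue/violet band) belong to no class: they are
  excluded from birefringent area but reported as `unclassified_bright` for
  QC.

Design choices that were genuinely open:

* The ratio's orientation is birefringent/total-PSR -- the bounded
  fraction-of-stain-that-is-fibrillar reading -- with an `invert` flag for
  the reciprocal.
* Thick fibers = orange + red. (A variant grouping of orange + yellow
  circulates in figure captions of the literature this implements; it is
  physically inconsistent with the hue ladder and is treated as a
  transcription error, but the class split is an argument of
  `fiber_thickness_fractions()`.)
* Bright-field stain segmentation has no canonical recipe; the default gate
  (hue in 0--38 or 230--255, saturation >= 60) is package configuration, not
  a biological claim, and every threshold is exposed.
* Classification rounds hue to the nearest integer bin, matching tools that
  classify on 8-bit hue; the four class intervals plus the 129--229 gap then
  partition the integer hue axis exactly (tested by enumeration).

Five fields per tissue are the conventional design; `analyze_psr_tissue()`
averages fields arithmetically and excludes degenerate fields (zero stain or
zero birefringence) with a warning rather than propagating NaN.

# Neurovascular masks and overlap

High-magnification two-channel stacks (sympathetic nerves via tyrosine
hydroxylase, vasculature via isolectin IB4) are flattened and masked with a
fixed filter chain:

* **Nerve**: Z-max projection -> subtract a sigma = 80 px Gaussian blur
  (background estimate) -> gate 100--255.
* **Vessel**: Z-max projection -> background subtraction -> unsharp mask
  (radius 1, weight 0.60) -> gate 15--255 -> one 3x3 binary dilation ->
  hole filling -> 3x3 median.

Numerical conventions the chain depends on:

* The unsharp formula is $(I - w\,G_\sigma(I))/(1-w)$ clamped to [0, 255] --
  the convention under which a fractional mask weight is meaningful and
  constants are fixed points.
* Gaussian blurs use a separable kernel truncated at $3\sigma$ and
  renormalized, with replicate boundaries, so constant images are exact
  fixed points (hence background subtraction of a flat field is exactly
  zero).
* Dilation uses a full 3x3 structuring element, once; the radius-1 median is
  a 3x3 majority vote with out-of-bounds cells counted as background; hole
  filling floods 4-connected background from the image border.
* The morphology order is threshold -> dilate -> fill -> median, as the
  chain is conventionally stated. Note one consequence: a single-pixel noise
  speck that survives thresholding is first dilated to a 3x3 block, which
  the median then largely keeps; the median's speck-removal behavior is
  therefore a property of the operator in isolation, not of the full chain.

Overlap between the nerve and vessel masks is summarized by Mander's
coefficients: $M_1 = |A \cap B|/|A|$, $M_2 = |A \cap B|/|B|$, and the
symmetric $\mathrm{MOC} = |A \cap B|/\sqrt{|A||B|}$. All three are always
reported; the headline is $M_1$ with A = nerve, B = vessel (the fraction of
nerve signal lying on vessels), because that is the biological question the
overlap answers. Per-tissue overlap is the mean of per-field $M_1$ over the
five fields.

Whole-depot densities use projected mosaics without background subtraction:
nerve gate 35--255 and vessel gate 45--255 inside a polygon tissue ROI,
reported as labeled area / tissue area, plus the nerve/vessel area ratio.
Whether to threshold tiles before or after projection is unresolved in the
field; the package thresholds the projected mosaic (max-projection first),
and the mosaic/stack plumbing makes the other order a two-line variant.
Neuro-adipose nexus (NAN) annotations are visual identifications; the
package only tallies annotation points and their neighbor counts within a
radius (for density color coding), never detects them.

# IENF density

Skin autofluorescence forms one intensity mode and pan-neuronal label a
second; the intermodes threshold separates them per image. The algorithm:
iteratively smooth the 256-bin histogram with a 3-bin moving mean
(edge-replicated) until exactly two local maxima remain, then take the
integer midpoint of the two peak bins. Details pinned here because the name
alone underdetermines them: plateau maxima count once at their leftmost bin;
the iteration cap is 10,000 passes; a histogram that is (or becomes)
unimodal raises an error that points to the manual `threshold` override
rather than guessing. The histogram is computed over the epidermal ROI by
default (`whole_image_hist = TRUE` gives the whole-section variant), the
upper gate is fixed at 255, and density = thresholded area / ROI area.
Multiple sections per tissue are averaged.

# NMJ occupancy and adipocyte morphometry

Junctions are scored into occupied / altered / unoccupied;
`fraction_occupied` counts only fully occupied junctions (altered counts as
not occupied, per the binary "fully occupied or not" convention). Fifty
junctions per tissue is the expected design; other counts warn but do not
error. Terminal-Schwann-cell means include every record carrying a count,
whatever its status. `occupancy_score()` is explicitly advisory plumbing for
annotation assistance -- scoring in the underlying protocol is manual.

Adipocyte metrics consume label masks (instance segmentation is out of
scope): area is an exact pixel count times squared pixel size; perimeter is
outer pixel-edge tracing -- exact for axis-aligned shapes (10x10 px at
1 um/px gives 100 um^2 and 40 um) and deliberately simple so results are
reproducible bit-exactly.

# Von Frey and myography

Response curves are per-filament positive-response fractions over the
standard 4.00/2.00/1.00/0.40/0.02 g set, five trials each. AUC is the
trapezoidal integral of fraction against filament strength on a **linear
gram axis**, ascending -- so a fully sensitive animal scores 3.98
gram-fraction units; a log-axis option exists but is not default, since the
convention is unstated in the underlying protocol.

Myography traces are normalized before fitting: contraction as % of maximal
KCl contraction, relaxation as % of pre-contraction tone. EC50 comes from a
four-parameter logistic fit on log-dose,
$y = b + (t-b)/(1 + (\mathrm{EC50}/d)^{h})$, with deterministic
initialization (extrema for $b, t$; the dose nearest half-range for EC50;
Hill slope +/-1 by trend) and EC50 bounded within [min dose/10, max dose x
10]. Fits are canonicalized to $b \le t$ (flipping the Hill sign, which
leaves the curve unchanged), must beat the flat-mean model in RSS, and error
out on flat data. A known identifiability limit, measured by the acceptance
suite: with the conventional 2 nM--10 uM ladder and an EC50 near 1 uM, the
upper plateau is barely sampled, so the EC50's sampling variability under
noise is several-fold larger than for a centered EC50 -- a property of the
experimental design, not of the optimizer (the package fit matches an
independent grid-profile oracle's optimum).

# Synthetic data: what it emulates, and what a green test proves

All generators are pure functions of a scene specification plus a seed
(bit-identical reruns, global RNG untouched) and emit ground truth that is
self-consistent with the emitted pixels by construction.

* **PSR pairs**: random-walk fibers thickened to tubes; fiber pixels
  partitioned across hue classes in *exactly* the programmed fractions
  (largest-remainder apportionment) and painted at full saturation with
  integer hues inside each class interval; bright-field stain = fibers plus
  diffuse blobs trimmed to exactly the programmed stained fraction. Defaults
  (512 px, 30% stain, thin:thick 65:35) describe a plausible young-adult
  subcutaneous field.
* **Depot scenes**: a vessel tree of thickened random walks; nerve signal as
  point varicosities, a programmed fraction p of them sampled on vessel
  pixels and the rest at Chebyshev distance > 4 from any vessel so the
  mask chain's single dilation cannot absorb them.
* **IENF sections**: a rectangular epidermal-band ROI, background
  autofluorescence at one mode, fibers crossing the band at a second mode,
  fiber count trimmed to exactly the programmed ROI fraction.
* **Tables**: NMJ statuses multinomial; von Frey trials Bernoulli under a
  logistic psychometric function of log filament strength (threshold 0.4 g,
  slope 2 by default -- the protocol states the filament set and trial
  count, not a response model); dose-response from a 4PL on a default
  10-dose log-spaced ladder spanning 2 nM--10 uM (the protocol states the
  range; 2--3 doses per decade is standard practice).

Noise is additive Gaussian clamped to [0, 255]. For RGB scenes one draw per
pixel is added to all three channels (luminance speckle): equal shifts
preserve channel differences, so noise perturbs the brightness gate without
scrambling hue, which is how detector noise behaves and keeps the
noise-robustness tests about gating rather than about hue quantization
artifacts. The default sd is 10 for bright-field/polarized scenes; depot
scenes default to sd 2 because confocal fluorescence background is
photon-limited and dark, and the 15-intensity vessel gate sits below the
2.5x noise gain of the unsharp step -- the generators guarantee that
background does not pass the relevant gates, so pipeline test failures
indicate pipeline bugs, not fixture bugs.

What a green test does **not** establish: the generators draw idealized
structures (no point-spread function, no depth attenuation, no chromatic
aberration, no tissue autofluorescence gradients, no stain variability), so
green recovery tests validate the *arithmetic and logic* of the pipelines --
gates, partitions, morphology, ratios, fits -- not their robustness to real
histological artifacts. Threshold defaults transfer to real data only to the
extent the acquisition matches the conventions above (8-bit scale, same
objective/zoom scale for the sigma-80 background model).

# Degenerate inputs and tie-breaks

Zero-stain or zero-birefringence fields are excluded from tissue means with
a warning; all-degenerate tissues error. Empty masks make Mander's
coefficients undefined and error naming the offending mask. Flat
dose-response data and unimodal histograms error rather than return a
number. Achromatic pixels take hue 0 by convention. `total_collagen_ratio`
with zero stained area errors (the field is meaningless, not zero).

# Limitations

TIFF I/O is not available in the supported runtime; images travel as
plain-text TSV matrices (CSV for ROIs and tables, JSON for configs), and a
TIFF front-end would be a thin addition. NAN detection, adipocyte instance
segmentation, vessel tracing, registration/stitching with overlap blending,
collagen type (I vs III) inference, and group statistics are all explicit
non-goals: the package produces per-field/per-tissue/per-animal tables
(hierarchically averaged in that order) designed for export to any
statistics environment.
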