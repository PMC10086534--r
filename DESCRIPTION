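Package: adiposcope
Title: Quantitative Histology and Physiology of Adipose Innervation and Aging
Version: 0.1.0
Authors@R:
    person("Adiposcope", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reusable, tested implementations of quantitative histology and
    physiology readouts used in peripheral-neuropathy and adipose-aging
    studies: picrosirius-red collagen birefringence scoring with hue-based
    thin/thick fiber classification, whole-depot neurovascular density and
    Mander's nerve-vessel overlap from engineered fluorescence masks,
    intermodes-thresholded intraepidermal nerve fiber density, neuromuscular
    junction occupancy and adipocyte morphometry, von Frey sensitivity curves
    with area under the curve, and wire-myography normalization with
    four-parameter logistic EC50 fitting. Ships seeded synthetic-data
    generators with machine-readable ground truth so every pipeline stage is
    verifiable without access to raw micrographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    optparse,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
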