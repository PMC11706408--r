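Package: spindlescreen
Title: Spindle-Pole-Tracking Analysis of Germline Stem Cell Mitosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying mitosis in C. elegans germline stem and
    progenitor cells (GSPCs) from in situ live-cell imaging. Reads spindle
    pole tracking exports (TrackMate-style spot tables), scores mitotic
    landmarks (nuclear envelope breakdown, mitosis start, anaphase onset)
    from spindle-length time series or from chromatin intensity-variance
    traces, extracts nine spindle features describing spindle size and
    dynamics, and runs the cohort statistics used in candidate screens:
    per-genotype outlier removal, control-normalized heatmaps, duration
    correlations, principal component analysis and delayed-cell
    classification. Also provides image-derived quantifications
    (nuclear-to-cytoplasmic fluorescence ratio, proliferative-zone nucleus
    counting by Difference-of-Gaussians detection and track linking, mitotic
    index, depletion fluorescence, assay ratios) and a synthetic-data
    generator with known ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
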