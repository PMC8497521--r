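Package: plasmidQuant
Title: Quantifying Spatial Plasmid Loss in Biofilm Confocal Stacks and
    Flow Cytometry Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying segregational plasmid loss in spatially
    structured bacterial communities carrying a dual-label reporter
    (plasmid-encoded mCherry, chromosomal GFP de-repressed on plasmid loss).
    Provides 3D image primitives (3x3x3 median smoothing, Otsu/Yen/Moments
    auto-thresholding, 26-connected component labeling), depth-resolved
    loss profiles for flow-cell biofilm z-stacks with biomass-weighted
    LOESS curves and top/bottom stratification, aggregate detection and
    size-distance modeling for alginate-bead microcolonies, gating and
    loss-trajectory statistics for flow-cytometry event tables, and a
    synthetic-data generator with known ground truth for end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    tiff,
    yaml,
    jsonlite,
    lme4,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    emmeans,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
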