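Package: roiconn
Title: ROI-Level Functional Connectomics and Morphometry for Small-Animal MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for region-of-interest (ROI) level
    analysis of small-animal MRI studies: synthetic cohort generation with
    planted modular covariance, BOLD time-series cleaning (motion-spike
    censoring, detrending, band-pass filtering, nuisance regression, L2
    normalization), Fisher-z functional connectivity matrices with bootstrap
    significance, weighted graph-theory metrics with multi-threshold
    area-under-curve summaries, consensus Louvain modularity and
    degree-preserving null models, and ROI volumetry/diffusion group
    statistics with a rank-based false-discovery filter.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    yaml,
    jsonlite,
    RNifti,
    car,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
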