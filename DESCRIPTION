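Package: atypia3d
Title: Quantification of Keratinocyte Nuclear Atypia from 3D Nucleus Segmentations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-segmentation analysis of 3D keratinocyte nucleus instance
    segmentations of the skin epidermis, as produced by star-convex
    polyhedron detectors on line-field confocal optical coherence tomography
    (LC-OCT) volumes. Builds Delaunay-derived neighbor graphs, computes 13
    cell-level morphometric features (volume, compactness, neighborhood
    distances and ratios) and image-level aggregates, scores per-nucleus
    atypia with a rule-based definition, an isolation forest, a
    weakly-supervised logistic regression and gradient-boosted trees under
    image-level stratified cross-validation, and evaluates image scores
    against diagnosis labels (AUC, Pearson correlations, t-tests, reader
    consensus). Includes a seeded synthetic 3D-tissue generator emulating
    healthy and pathological nuclei populations so the full pipeline can be
    exercised without clinical images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
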