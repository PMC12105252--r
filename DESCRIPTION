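Package: circuitsdm
Title: Ensemble Species Distribution Models and Circuit-Theory Landscape
    Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline for habitat-suitability and landscape
    connectivity analysis of range-restricted species: ensemble ecological
    niche models with surface-range-envelope pseudo-absences and spatially
    blocked (checkerboard) cross-validation, continuous Boyce and TSS
    evaluation, multi-scenario climate projection with MESS extrapolation
    diagnostics and dissimilarity-weighted model averaging, fine-scale
    weighted-overlay suitability, negative-exponential resistance surfaces,
    pairwise current-flow connectivity on raster graph Laplacians, and
    change and hybridization-zone indices. Ships a synthetic-landscape
    generator (Gaussian random fields, DEM-derived hydrology with Strahler
    orders, barriers, virtual species) so the whole pipeline is testable
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    randomForest,
    xgboost,
    jsonlite,
    minpack.lm,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
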