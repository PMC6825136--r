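Package: paleotf
Title: Pollen-Climate Transfer Functions with Variable-Radius h-Block
    Cross-Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibration and cross-validation toolkit for quantitative
    palaeoclimate reconstruction from fossil pollen. Implements eight
    calibration methods (modern analogue technique, weighted averaging,
    weighted averaging partial least squares, random forests, extremely
    randomized trees, boosted regression trees, and two single-hidden-layer
    neural network variants) behind a single fit/predict contract, a
    variable-radius h-block spatial cross-validation engine with RMSEP,
    maximum-bias and analogue-quality diagnostics, variogram-based selection
    of the exclusion radius h, correlation screening and ensemble ranking of
    candidate climate variables, fossil palaeoclimate reconstruction, and
    SiZer maps of significant trends. A synthetic-data generator with
    spatially autocorrelated climate surfaces and unimodal taxon responses
    makes every stage testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    nnet,
    randomForest,
    ranger,
    xgboost
Suggests:
    geosphere,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
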