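Package: geofav
Title: Favourability-Based Species Distribution Models with a Geographic
    Trend-Surface Predictor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling gridded species presence/absence data with
    prevalence-corrected favourability models. Implements self-contained
    logistic-regression machinery (iteratively reweighted least squares,
    likelihood-ratio tests, forward-backward stepwise selection,
    Benjamini-Hochberg false-discovery-rate screening, variance inflation
    factors), a trend-surface geographic predictor built from polynomial terms
    of cell-centroid coordinates, the favourability transformation and its
    inverse, variation partitioning of explained deviance across predictor
    sets by inclusion-exclusion, discrimination metrics (sensitivity,
    specificity, correct classification rate, AUC), and projection of fitted
    models onto future climate scenarios. A seeded synthetic-landscape
    generator produces spatially autocorrelated covariates and logistic
    occurrence processes so the whole workflow can be exercised and tested
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
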