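Package: pestRisk
Title: Climate Suitability and Municipal Economic Risk Assessment for
    Forest Pest Invasions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: An end-to-end, fully offline pipeline for assessing the
    invasion risk that a forest pest poses to plantation forestry. It
    provides spatial thinning of occurrence records and climate-zone
    background delimitation, iterative VIF predictor filtering, a
    self-contained minimal MaxEnt (L1-regularised Gibbs model over
    background cells with linear/quadratic/hinge/product features),
    AICc-based tuning over a regularisation-by-feature-class grid,
    evaluation by AUC, a randomised null-model significance test and the
    Continuous Boyce Index, exact Fisher-Jenks natural-breaks
    classification, combination of suitability with an
    introduction-likelihood surface, municipality-level zonal statistics,
    and a two-dimensional economic risk matrix built from the normalized
    Concentration Index (location quotient, Hirschman-Herfindahl and
    relative participation, PCA-weighted). A synthetic-world module
    generates every input with known ground truth so the whole pipeline is
    testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    geosphere,
    mgcv,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
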