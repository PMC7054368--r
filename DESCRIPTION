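Package: twincycle
Title: Path-Analysis Structural Equation Models for the Twin-Cycle
    Hypothesis of Glycaemic Control
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Maximum-likelihood path analysis (manifest-variable structural
    equation modelling on covariance matrices) for testing the twin-cycle
    model of glycaemic control and its extension with physical activity.
    Provides stratified rank-inverse-normal transformation and two-step
    residual regression preprocessing, ML estimation of possibly cyclic
    (non-recursive) path models with Wald tests and standardized solutions,
    CFI/TLI/RMSEA fit indices, a variable-randomised null-distribution test
    of model fit, coefficient-product (mediation) pathway effects with
    delta-method standard errors, and a synthetic cohort generator that
    emulates the statistical structure of the multicentre metabolic cohorts
    the models were designed for.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    MASS,
    ggplot2
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
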