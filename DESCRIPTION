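Package: rnevo
Title: Selection on and Predicted Evolution of Phenological Reaction Norms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying selection on, genetic variation in, and
    predicted micro-evolution of linear reaction norms of seasonal timing
    traits (such as avian egg-laying date) against a spring temperature cue.
    Provides a synthetic-data generator for pedigreed wild-population
    breeding records; estimation of the optimal reaction norm from resource
    phenology with bias-corrected and accelerated (BCa) bootstrap intervals;
    a simplified sliding-window search for the best temperature cue window;
    Gibbs samplers for random-regression (animal) models with heterogeneous
    residual variance, including a bivariate laying-date/fitness model;
    annual fitness-surface fitting and Lande-Arnold selection gradients with
    parametric-bootstrap standard errors; a reaction-norm breeder's equation
    with first-order error propagation; and a simulation study of how
    residual-structure misspecification inflates slope-variance estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    mgcv,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
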