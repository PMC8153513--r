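Package: vfbayes
Title: Bayesian Estimation of Vocal Fold Material Properties from Glottal
    Area Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Subject-specific vocal fold modeling by Bayesian inverse
    analysis.  Provides a two-dimensional three-layer viscoelastic finite
    element model of the vocal folds (body, ligament and cover layers over
    an M5-style cross section) driven by a quasi-one-dimensional Bernoulli
    flow model with flow separation and midline collision, and an
    importance-sampling estimator that infers layer Young's moduli,
    density, viscosity, subglottal pressure and medial-compression offset
    from a measured glottal area waveform.  Includes a synthetic-data
    generator with known ground truth, waveform metrics (fundamental
    frequency, open and speed quotients), posterior summaries with
    uncertainty, sensitivity sweeps over ensemble size, time step and mesh
    density, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    parallel,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
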