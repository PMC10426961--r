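Package: confcat
Title: Confidence Models for Two-Alternative Categorisation Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Signal-detection-theory models of category choice and confidence for
    two-alternative forced-choice categorisation tasks with 4-point confidence
    ratings. Implements three model classes (unscaled evidence strength, scaled
    evidence strength with linear, quadratic or free-exponent boundary scaling,
    and Bayesian log-posterior-probability-ratio observers, with optional
    orientation-dependent noise, decision noise and free category-distribution
    beliefs), exact interval-mass likelihoods, maximum-likelihood fitting with
    ordered-boundary constraints, AIC/BIC model comparison, cross-modal joint
    fits with graded parameter sharing, a synthetic-session generator emulating
    a balanced category-by-intensity design, and model- and parameter-recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite,
    yaml
Config/testthat/edition: 3
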