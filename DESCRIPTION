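Package: buvspatial
Title: Bayesian Spatial Presence-Absence Models for Baited Underwater Video Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Fits Bayesian logistic regressions, with and without a
    Gaussian-process spatial random effect under an exponential covariance,
    to presence-absence records from baited underwater video (BUV) surveys.
    Inference uses Polya-Gamma data augmentation Gibbs sampling with a
    random-walk Metropolis step on the spatial decay parameter. Includes a
    synthetic survey generator emulating clustered coastal BUV designs,
    location-blocked k-fold cross-validation with conditional (kriged)
    sampling of the random effect at held-out sites, posterior model
    comparison by log-likelihood, mean squared error and ROC AUC, and
    reporting of odds ratios, highest-posterior-density intervals, the
    effective spatial range and gridded random-effect surfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
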