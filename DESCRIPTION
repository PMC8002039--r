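Package: fesdcm
Title: Dynamic Causal Modeling and Empirical Bayes Group Inference for a
    Four-Region Motor Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and variational-Laplace inversion of bilinear dynamic
    causal models (DCM) of BOLD time series for a four-region motor network
    (M1, S1, SMA, AG) under a 2x2 volitional-by-FES block paradigm, with
    hierarchical group inference by parametric empirical Bayes (PEB),
    Bayesian model reduction and averaging, and a six-step model-structure
    identification pipeline (controls C, A, B then patients C, A, B).
    Includes a synthetic-cohort generator with planted carryover, time and
    capacity-score effects, and an ROI-summarization stage (Gaussian
    smoothing, masked maxima selection with a minimum-separation rule,
    first-eigenvariate extraction of spherical regions).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
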