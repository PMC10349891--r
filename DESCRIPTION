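Package: higgsr
Title: Hidden Gaussian Graphical Spectral Models for Oscillatory Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Identification of frequency-specific oscillatory networks from
    M/EEG-like spectral data. Implements the Hermitian graphical LASSO
    (hgLASSO) precision-matrix estimator for complex-valued cross-spectra via
    local quadratic approximation, desparsified (debiased) estimates with
    Rayleigh-calibrated edge selection, a one-step expectation-maximization
    inverse solution (HIGGS) that estimates source connectivity directly from
    sensor cross-spectra given a lead field, multistep two-step baselines
    (eLORETA and LCMV first steps followed by graphical estimation), a
    Xi-Alpha oscillatory-network simulator with a planar forward model, and
    evaluation metrics (ROC support recovery, Kullback-Leibler, Riemannian
    and log-Euclidean divergences between precision matrices).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    pROC
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
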