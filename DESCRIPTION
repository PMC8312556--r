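Package: qmrieff
Title: Efficiency Analysis and Sequence Design for Quantitative MRI Relaxometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify, optimize and compare the intrinsic efficiency of
    quantitative MRI relaxometry methods for joint T1/T2 mapping. Provides
    steady-state (SPGR, bSSFP, DESS, TESS) and transient (fingerprinting)
    gradient-echo signal models backed by extended-phase-graph and Bloch
    simulation kernels, Cramer-Rao lower bound machinery for the efficiency
    metric eta (parameter-to-noise ratio per unit maximum SNR and square root of
    acquisition time), multi-start constrained optimization of acquisition
    settings, a Monte-Carlo model of efficiency loss under k-space undersampling
    with zero-filled reconstruction (the dynamics-factor), and an in-silico
    repeat-experiment harness that validates predicted efficiencies against
    empirical ones for DESPOT1-style T1 mapping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
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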