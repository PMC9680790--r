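Package: cftrgate
Title: Hidden-State Inference for CFTR Single-Channel Gating
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of single-channel patch-clamp recordings
    of the CFTR chloride channel under a seven-state aggregated hidden Markov
    model of the gating cycle. Builds continuous-time kinetic rate matrices
    with ATP-dependent binding and discretizes them to transition probability
    matrices; simulates ground-truth state sequences and noisy current traces;
    computes exact posterior state marginals by the scaled forward-backward
    (sum-product) algorithm; estimates the transition matrix, noise variance
    and current amplitude by expectation-maximization under a hard
    scheme-topology constraint; and classifies channel closings as permissive
    or nonpermissive (ADP-releasing) with false-alarm and missed-detection
    scoring against ground truth. Includes block-averaging decimation for raw
    recordings and scripted parameter sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
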