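Package: oscbind
Title: Time-Based Binding Simulation and Oscillatory Neural Signal Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates time-based binding of hierarchical linguistic structure
    (phrase versus sentence) in a layered node network and analyses oscillatory
    multichannel time-series with the standard toolbox of cognitive
    electrophysiology: Morlet wavelet time-frequency decomposition, intertrial
    phase coherence, induced power with decibel baselining, intersite phase
    clustering and rank-correlation power connectivity with graph thresholding
    into degree maps, phase-amplitude coupling with permutation z-normalisation,
    spectrotemporal response functions estimated by ridge regression with
    leave-one-out cross-validation, nonparametric cluster-based permutation
    inference, and stimulus acoustics (envelope extraction, RMS normalisation,
    cosine-similarity permutation tests, Bayesian ROPE spectrum comparison).
    A synthetic-data module plants parameterised ground-truth effects so every
    analysis stage can be validated against a known answer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
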