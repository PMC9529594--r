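Package: earpipe
Title: Ear-EEG/EMG Signal Analysis for Wearable Bruxism Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for around-the-ear electrophysiological
    recordings (cEEGrid-style electrode arrays driven by OpenBCI-class
    amplifiers): reading OpenBCI GUI exports, adaptive reference-channel
    line-noise removal with a normalized least-mean-squares (NLMS) filter,
    Welch power spectral density estimation, epoch-level labeling of facial
    activity events, a seven-feature per-channel time-domain feature set
    (Hjorth parameters, amplitude statistics, Higuchi and Petrosian fractal
    dimensions), and imbalance-aware cross-session classification of jaw
    clenching (bruxism) events with SMOTE oversampling and a boosted-stump
    ensemble. Includes a fully synthetic session generator emulating a
    28-activity posed facial-activity protocol so the whole chain is testable
    without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    signal,
    rpart,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    withr,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
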