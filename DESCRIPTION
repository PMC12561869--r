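Package: sleepnet
Title: Multimodal Multi-Scale Attention Network for Automatic Sleep Staging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end automatic sleep staging from multi-channel
    polysomnography (two EEG derivations, EOG, submental EMG). Implements a
    neural classifier that combines per-modality dual-branch multi-scale 1D
    convolution, squeeze-and-excitation channel attention, a bidirectional
    LSTM temporal encoder with attention pooling, and a softmax classifier,
    together with EDF/EDF+ reading and writing, 30-second epoching with
    AASM five-class label mapping and wake trimming, subject-disjoint
    cross-validation training with early stopping, a full evaluation suite
    (accuracy, macro-F1, Cohen's kappa, per-class sensitivity, specificity
    and precision), ablation variants of the architecture, and a synthetic
    polysomnography generator so the whole pipeline is testable without
    benchmark downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    nnet,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp,
    RcppArmadillo
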