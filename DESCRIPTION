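Package: emorhythm
Title: Cross-Subject EEG Emotion Recognition from Rhythm-Resolved Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for cross-subject emotion recognition from
    multi-channel EEG. Decomposes trials into theta/alpha/beta/gamma rhythms
    with linear-phase FIR filters, extracts nine time-frequency descriptors
    and nine nonlinear dynamical-system descriptors (approximate entropy, C0
    complexity, correlation dimension, Kolmogorov K2 entropy, largest Lyapunov
    exponent, permutation entropy, singular-spectrum entropy, Shannon entropy,
    spectral entropy) over sliding windows, ranks features by five selection
    strategies (chi-squared, mutual information, ANOVA F, SVM recursive
    feature elimination, L1-penalized linear SVM), evaluates them with a
    leave-one-subject-out linear-SVM harness (accuracy, ROC, AUC, searchlight
    reports by channel, region, rhythm and feature), and analyses thresholded
    channel-correlation networks via clustering coefficients. Ships a
    synthetic multi-subject EEG generator emulating the structure of affective
    EEG experiments for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    e1071,
    pROC,
    igraph,
    deSolve,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
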