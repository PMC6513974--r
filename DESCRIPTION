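Package: painfeat
Title: Physiological Feature Extraction, Selection, and Topological
    Charting for Heat-Pain Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reusable pipeline for pain-level recognition from peripheral
    physiological signals (facial and trapezius surface EMG, skin conductance,
    ECG). Provides a synthetic multimodal trial generator emulating a
    calibrated heat-pain protocol, signal preprocessing (zero-phase Butterworth
    filtering, empirical-mode-decomposition power-line removal, Hilbert
    spectra), a bank of 155 named time- and frequency-domain features, a
    repeated-epoch feature-selection protocol (univariate ANOVA-F ranking and
    sequential forward selection with a Naive Bayes wrapper and majority
    voting) with linear-SVM accuracy curves, a Mapper-based topological
    feature chart, and a baseline-versus-tolerance effect-size interaction
    analysis.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    e1071,
    igraph,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
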