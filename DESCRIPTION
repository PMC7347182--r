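Package: semgpain
Title: Pain Intensity Analysis from Facial Surface Electromyography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for studying pain intensity with facial
    surface electromyography (sEMG). Includes a calibrated synthetic cohort
    generator (amplitude-modulated Gaussian muscle activity with talking,
    power-line, pulse-train, spike and drift artifacts), the standard sEMG
    preprocessing chain (zero-phase Butterworth high-pass, reference-channel
    adaptive noise cancellation, 1-Hz root-mean-square and waveform-length
    features, Hampel outlier filtering, per-test z-scoring), self-report
    anchored period labelling, nonparametric statistics (Wilcoxon signed-rank,
    Spearman correlation screening), and an ordinal k-nearest-neighbour
    prediction model evaluated with the concordance index under nested
    leave-subject-out cross-validation and a permutation significance test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    dplyr,
    tidyr,
    tibble,
    ggplot2,
    rlang,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
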