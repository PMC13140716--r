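Package: thermoeeg
Title: Spatiotemporal EEG Analysis of Staged Cold Exposure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multichannel EEG recorded across staged
    whole-body cold exposure (thermoneutral baseline, cold exposure, cold-wind
    stimulation, habituation and recovery). Provides a synthetic cohort
    generator with closed-form spectral ground truth, EDF input/output and
    zero-phase bandpass preprocessing, per-window features (mean amplitude,
    absolute and relative band power, Hjorth parameters, weighted average
    skin temperature), a stage-wise statistical battery (Welch and
    repeated-measures ANOVA, Benjamini-Hochberg correction, effect sizes and
    a priori sample-size computation), classifier plus Shapley-value channel
    specificity analysis, and two response-latency estimators based on
    short-time Fourier band-power deviation and autoencoder reconstruction
    error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    car,
    e1071,
    nnet,
    randomForest,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
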