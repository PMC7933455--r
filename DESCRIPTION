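Package: pafc
Title: Sinus-Rhythm ECG Complexity Scoring for Paroxysmal Atrial
    Fibrillation Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Computes Lempel-Ziv (1976) complexity of short single-lead
    sinus-rhythm ECG recordings under two symbolizations (threshold
    crossing of the whole waveform against its median, and R-wave beat
    detection via a smoothed-derivative QRS detector), aggregates
    per-strip complexity scores into per-patient day-to-day variability
    scores, and combines them into an ellipse-calibrated composite
    h-score for paroxysmal atrial fibrillation risk screening.  Includes
    cohort-level evaluation (Mann-Whitney rank tests, empirical ROC
    curves with Hanley-McNeil confidence intervals and DeLong AUC
    comparison, Youden operating points, threshold perturbation and
    additive-noise robustness analyses) and a seeded synthetic ECG
    cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
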