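Package: epiage
Title: DNA Methylation Age Estimation with a Tunable Log/Linear Age
    Transformation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Chronological age estimation from CpG methylation
    proportions, as used in forensic epigenetics. Implements the
    piecewise logarithmic/linear transformation linking chronological
    and epigenetic age with the adult cut-off treated as a tunable
    hyperparameter, selected by repeated k-fold cross-validation
    (unisex and sex-specific); ordinary-least-squares age models on the
    transformed scale with backtransformed point predictions and
    prediction intervals; a published seven-CpG buccal-swab model as a
    built-in fixture; evaluation tools (MAD, RMSE, R-squared,
    Bland-Altman agreement, age-binned accuracy tables, per-CpG
    correlation screening); minisequencing peak-height quantification;
    and a seeded synthetic-data generator emulating the study design so
    the whole pipeline is testable without access to the original
    cohort.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
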