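Package: cardioscreen
Title: ECG/HRV Feature Extraction, Norm-Anchored Scoring and Nested
    Feature Selection for Psychophysiological Screening
Version: 0.1.0
Authors@R:
    person("cardioscreen", "developers", email = "dev@cardioscreen.invalid",
           role = c("aut", "cre"))
Description: Tools for linking subtle electrocardiographic and heart rate
    variability features to psychological assessment scores in small
    cohorts. Provides a synthetic six-lead ECG and cohort generator with
    analytic ground truth, extraction of amplitude-time, area, ratio and
    HRV features (time domain, Welch spectra, detrended fluctuation
    analysis, Baevsky stress index and related psycho-emotional indices),
    a hierarchical norm-anchored 0-100 point scoring system with
    robustness and homogeneity diagnostics, Pearson/Spearman correlation
    screening with tiered significance summaries, and a leakage-safe
    forward sequential feature-selection pipeline (train/test split,
    training-only outlier removal via isolation forest, median
    imputation, collinearity filtering, transformer search and five-fold
    cross-validated linear regression) with held-out evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
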