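Package: lfpdecode
Title: Decoding Whisker Stimuli from Laminar Local Field Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking lightweight classifiers, including a
    from-scratch spiking Liquid State Machine, on the task of decoding
    whisker stimulation and behavioral responses from laminar local field
    potential (LFP) recordings of mouse barrel cortex. Provides a synthetic
    cohort generator emulating laminar evoked responses and go/no-go
    behavior, trial quality control, causal Butterworth filtering, current
    source density based layer assignment, RAW and FFT feature extraction
    with train-anchored Min-Max scaling, leave-one-mouse-out bootstrap
    validation with grid search and class balancing, ROC/PR/Brier
    evaluation, Platt calibration, and nonparametric significance tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    withr,
    generics,
    signal,
    glmnet,
    rpart,
    ranger,
    xgboost,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
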