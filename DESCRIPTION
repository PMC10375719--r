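Package: osadetect
Title: Obstructive Sleep Apnea Event Detection from Portable-Monitor Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects obstructive sleep apnea (OSA) events and estimates the
    apnea-hypopnea index (AHI) from four 1-Hz physiological channels (SpO2,
    heart rate, thoracic and abdominal respiratory effort). Provides a
    synthetic cohort generator with planted apnea/hypopnea physiology, EDF and
    NSRR-style XML readers, artifact interpolation and per-window
    standardization, a 1D convolutional network window classifier with
    batch-normalized blocks, a global-average-pooling sigmoid head and Adam
    training with early stopping, a successive-halving hyperparameter search,
    patient-grouped incremental cross-validation, Grad-CAM temporal relevance
    maps validated against an occlusion oracle, and AHI/severity agreement
    reporting (R-squared, weighted Cohen's kappa, screening metrics).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
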