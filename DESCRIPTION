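Package: actionability
Title: Entropy-Based Actionability Metrics for Multiclass Clinical Prediction Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the "actionability" of multiclass clinical prediction
    models as their tendency to reduce uncertainty in medical decision-making
    relative to a reference (typically clinician judgment alone). Implements
    the diagnosis-phase metric (mean Shannon-entropy reduction of per-patient
    diagnostic belief distributions) and the action-phase metric
    (entropy reduction of policy-induced future-state distributions in a
    partially observable Markov decision process framing), together with a
    seeded synthetic clinical-scenario generator, stratified diagnostics that
    expose confidently-wrong models, and a standard net-benefit
    (decision-curve) companion for triaging candidate models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
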