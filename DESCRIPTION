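Package: fusesurv
Title: Multimodal Cross-Attention Fusion Models for Survival Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits hierarchical multimodal fusion survival models that combine
    pathology, ultrasound and structured clinical feature streams through
    intramodality and intermodality cross-attention with a clinical residual
    stage, trained end-to-end with the Cox partial-likelihood loss. Includes a
    learnable compensation mechanism for missing modalities, a synthetic
    multimodal-cohort simulator with planted proportional-hazards risk, a full
    survival evaluation suite (Harrell's C-index, time-dependent AUC, IPCW
    Brier score and calibration, Kaplan-Meier and log-rank stratification,
    hazard ratios, bootstrap confidence intervals, decision-curve analysis),
    stratified cross-validation and an ablation-grid harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
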