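Package: phenoconn
Title: Classifier-Derived Language Phenotype Scores and Whole-Brain
    Connectedness Compensation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for testing neural compensation in two-group
    neuroimaging conversation studies.  Builds a participant-level
    "classifier score" of typical language behavior from per-conversation
    linguistic feature tables (z-scoring, leave-one-out linear support
    vector classification, Platt posterior calibration, composite scoring,
    participant-level permutation testing, ROC and severity validation);
    computes per-scan whole-brain connectedness maps from parcellated
    time series; contrasts them between groups with node-wise linear
    mixed-effects models under permutation-calibrated cluster-extent
    thresholds and a multi-threshold robustness map; and tests, per
    selected region, whether connectedness relates to the classifier
    score differently by group, with seed-based follow-up contrasts and
    hemisphere counts.  Includes a synthetic-data generator that plants
    known group, severity and compensation structure for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lme4,
    lmerTest,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    e1071,
    igraph,
    optparse,
    pROC,
    RNifti,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
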