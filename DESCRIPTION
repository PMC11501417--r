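Package: episemio
Title: Structured Extraction and Classification of Seizure Semiology from
    Clinical Narratives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A lexicon-driven toolkit for turning free-text epilepsy
    histories into structured seizure records (time stamp, location,
    symptom, status, episode duration, frequency). Provides a bilingual
    semiology lexicon data model with synonym normalization, a rule-based
    extraction engine with negation and uncertainty scoping and temporal
    normalization, per-dimension precision/recall/F1 scoring against gold
    annotations, Fleiss's kappa for inter-annotator agreement, a binary
    symptom feature-matrix builder, stacked ensemble classification of
    generalized versus focal epilepsy with out-of-fold meta-features, and
    a synthetic-narrative generator with exact gold annotations for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    glmnet,
    ranger,
    rpart,
    xgboost,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
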