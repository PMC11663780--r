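Package: cognote
Title: Detecting Signs of Cognitive Decline in Clinical Note Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end pipeline for binary classification of clinical-note
    sections for signs of cognitive decline. Provides a calibrated synthetic
    note-corpus generator (lexicon-bearing positive cues, hard negatives, and
    neutral filler), an expert-keyword section filter, prompt assembly and
    response parsing for large-language-model classification with a
    deterministic scripted backend, four five-shot example-selection
    strategies, gradient-boosted-tree and attention-network baselines, a
    majority-vote ensemble, bootstrap confidence intervals with paired model
    comparison, mean-plus-two-standard-deviation keyword-importance
    extraction, and three-set error-overlap accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    Matrix,
    stats,
    tibble,
    utils,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
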