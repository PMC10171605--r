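Package: hitloop
Title: Human-in-the-Loop Active Learning for Coding Free-Text Clinical Notes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for coding free-text clinical records (death-certificate
    cause-of-death strings, aeromedical retrieval triage shorthand and similar
    short clinical notes) into researcher-defined categories with a
    label-train-evaluate active-learning loop. Provides sparse word n-gram and
    character n-gram featurization, gradient-boosted tree and maximum-entropy
    classifiers behind a common interface, pool-based sampling strategies
    (random, keyword search, confidence-sorted), a seeded two-expert consensus
    oracle for simulation studies, balanced test and validation set
    construction, confusion-matrix diagnostics (sensitivity, specificity,
    PPV, NPV), learning-curve assembly, and a seeded generator of synthetic
    clinical corpora with typos, abbreviations, rare classes and confusable
    category pairs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    glmnet,
    xgboost,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
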