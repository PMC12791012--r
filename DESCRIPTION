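Package: igpair
Title: Antibody Heavy-Light Chain Pairing Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for learning and scoring cognate antibody heavy-light
    (H-L) chain pairing from adaptive immune receptor repertoire (AIRR)
    data. Reads AIRR rearrangement tables, assembles per-cell H-L pairs,
    curates balanced positive/pseudo-negative training sets with
    clonotype-aware leakage control, trains desk-scale pairing
    classifiers (gene-usage linear and boosted-tree baselines, a
    two-stream CDR3 convolutional network), supports light-chain-type
    specific (kappa/lambda) model routing, and implements downstream
    procedures: maturation annotation with reshuffled-light controls,
    spatial candidate-pair ranking, cancer clone-table filtering, and
    germline CDRH3-grafting library screens. Includes a paired-repertoire
    simulator with a planted, tunable H-L compatibility rule and a
    kappa-first/lambda-rescue light-chain choice model so every pipeline
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    glmnet,
    jsonlite,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    xgboost,
    yaml
Suggests:
    Biostrings,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
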