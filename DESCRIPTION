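Package: trialselect
Title: Selective Classification for Clinical Trial Approval Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts clinical trial approval from drug structures, disease
    codes and eligibility-criteria text with a hierarchical interaction
    network -- a 13-node attentive graph neural network over drug, disease
    and protocol embeddings with ADMET and disease-risk auxiliary
    pretraining -- and wraps any probabilistic trial classifier in a
    distribution-free selective-classification layer that abstains on
    low-confidence trials while guaranteeing a user-specified selective
    accuracy via one-sided binomial (Clopper-Pearson) tail bounds.
    Includes a seeded synthetic-data generator with a planted outcome
    model, evaluation metrics (PR-AUC, ROC-AUC, F1, accuracy, retain
    rate), temporal splitting, paired-bootstrap significance testing and
    coverage-accuracy trade-off curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
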