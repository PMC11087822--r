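Package: vkradr
Title: Adverse Drug Reaction Profile Prediction via NMF and Kernel Ridge Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts adverse-drug-reaction (ADR) profiles for new (cold-start)
    drugs from binary drug features such as drug-gene interactions and chemical
    fingerprints. Implements the VKR predictor - non-negative matrix
    factorization of the known-drug ADR matrix followed by kernel ridge
    regression of the drug factor on an RBF drug-drug kernel - together with a
    naive prevalence baseline, plain kernel regression (KR), and multiple kernel
    regression (MKR). Provides micro-pooled AUPR/AUROC metrics, seeded k-fold
    and nested cross-validation with inner-loop grid search, hold-out
    evaluation, paired t-tests across folds, a seeded synthetic-data generator
    emulating sparse low-rank ADR matrices, and tab-separated file I/O for
    SIDER/DGIdb-style pair lists.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
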