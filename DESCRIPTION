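Package: pssmstack
Title: Protein Classification from PSSM Profiles with Stacked Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for predicting functional protein classes (e.g. vesicle
    transport proteins) from PSI-BLAST position-specific scoring matrices.
    Parses ASCII PSSM files, extracts reduced-alphabet RPSSM (110-d) and
    AADP-PSSM (420-d) evolutionary-information features, ranks features with a
    max-relevance-max-distance (MRMD) criterion, balances classes by random
    undersampling, and fits a two-layer stacked ensemble (gradient boosting,
    RBF support vector machine and extremely randomized trees feeding a
    logistic-regression meta-model via out-of-fold probabilities). Includes
    confusion-matrix metrics, ROC/AUC, cross-validated reporting, McNemar's
    paired test, and a synthetic PSSM generator for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    ranger,
    seqinr,
    stats,
    utils,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
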