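Package: odorcascade
Title: Odor Prediction from Olfactory Receptor Activation Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A biologically structured cascade for predicting the odor of
    small molecules from their interactions with a panel of olfactory
    receptors. Three models are chained: a classifier for whether a
    molecule binds each receptor, a regressor for the binding strength
    (log(EC50)) of predicted binders, and a bank of binary classifiers
    that read the assembled receptor activation profile and call the
    presence of odor communities. Odor communities are extracted from an
    odor-label co-annotation graph by greedy modularity maximization.
    Includes proteochemometric featurization (stereo-aware Morgan, RDKit
    and MACCS fingerprints and physicochemical descriptors for molecules;
    k-mer amino-acid frequency and alignment one-hot descriptors for
    receptors), k-means++ clustering undersampling for class imbalance,
    nested cross-validation over a configurable method panel, and a
    synthetic-study generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    jsonlite,
    glmnet,
    e1071,
    ranger
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    xgboost,
    kernlab,
    mixOmics,
    MASS,
    class,
    rpart,
    optparse
SystemRequirements: Python (>= 3.9) with rdkit, on PATH as 'python'
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
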