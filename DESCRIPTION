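Package: orgprobe
Title: Multilevel Prediction of Organelle-Targeted Fluorescent Probes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Curation, featurization and multilevel machine-learning
    classification of small-molecule fluorescent probes by subcellular
    target. Implements a four-level cascade (probe versus non-probe,
    mitochondria versus other organelles, six-organelle multiclass, and
    mitochondrial colocalization quality), MACCS/ECFP4 fingerprints and an
    open 2D descriptor set computed through OpenBabel, SMOTE class
    balancing, a ten-algorithm model comparison grid with stratified
    cross-validation, SHAP and gain-importance model interpretation with
    top-k consensus ranking, property-based candidate screening, and a
    seeded synthetic probe-library generator with planted, recoverable
    structure for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineOB,
    ChemmineR,
    igraph,
    xgboost,
    randomForest,
    ranger,
    rpart,
    glmnet,
    e1071,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
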