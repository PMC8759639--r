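Package: riemerp
Title: Riemannian Single-Trial Classification of Event-Related EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Single-trial classification of event-related EEG potentials
    using xDAWN spatial filtering, augmented-trial covariance matrices,
    tangent-space mapping on the manifold of symmetric positive-definite
    matrices, and regularized logistic regression.  Includes an sLORETA
    standardized distributed inverse for source-space classification on
    synthetic lead fields, a multi-subject synthetic visual-ERP generator,
    leave-one-subject-out and per-subject k-fold cross-validation
    harnesses, classification metrics (accuracy, MCC, ROC/AUC,
    precision-recall/AP), forward electrode selection, and pipeline
    comparison utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    glmnet,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
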