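Package: vestasym
Title: Vestibular Test Asymmetry Analysis and Affected-Side Prediction
Version: 0.3.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for lateralizing unilateral vestibular hypofunction from a
    standard laboratory test battery. Computes left-right asymmetry statistics
    from video head impulse test (vHIT) gains of the six semicircular canals
    (including a composite anterior-posterior measure based on gain products),
    cervical and ocular VEMP amplitude asymmetry ratios, the Jongkees canal
    paresis from four-condition caloric irrigation, and mean subjective visual
    vertical tilt. Provides a normative correction for the systematic
    left-right gain bias of monocular vHIT recordings, fold-aware
    preprocessing (1-nearest-neighbour imputation, winsorization, range
    normalization, standardization), descriptive side-correspondence
    summaries, and leave-one-out cross-validated side prediction with
    logistic regression, Gaussian naive Bayes and linear SVM, including ROC
    curves, bootstrap confidence intervals, Youden-optimal operating points,
    SVM-weight feature ranking, stepwise multivariate AUC traces and paired
    bootstrap AUC comparisons. A synthetic cohort generator with known ground
    truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
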