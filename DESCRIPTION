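Package: polyrisk
Title: Polytomous Risk Prediction Models for Ovarian Tumor Diagnosis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Development, validation and comparison of polytomous (four-class)
    risk prediction models for the preoperative diagnosis of ovarian tumors as
    benign, borderline, primary invasive or metastatic. Implements multinomial
    logistic regression, pairwise coupling of one-versus-one dichotomous
    models (logistic regression, Bayesian least squares support vector
    machines, kernel logistic regression), a nested sequential-dichotomy
    alternative, cross-validation and information-criterion based variable
    selection including fast forward selection with rank-one kernel updates
    and exact leave-one-out shortcuts, and an evaluation suite built around
    the polytomous c-index and loess calibration curves. A seeded synthetic
    generator emulates the class-conditional structure of a multi-center
    ovarian tumor cohort for testing and simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    glmnet
Config/testthat/edition: 3
RoxygenNote: 7.3.3
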