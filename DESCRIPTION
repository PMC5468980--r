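Package: incidenttriage
Title: Multiclass Triage of Patient Safety Incident Reports with Binary
    Classifier Ensembles
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for automated triage of free-text patient safety incident
    reports by incident type and severity level. Implements bag-of-words
    feature extraction (binary, term-frequency and tf-idf weighting),
    one-versus-one and one-versus-all binary classifier ensembles over
    regularized logistic regression and support vector machines (linear and
    radial-basis-function kernels, solved by a built-in SMO optimizer),
    voting and directed-acyclic-graph decision schemes, repeated random
    sub-sampling validation with a frozen test partition, micro- and
    macro-averaged precision/recall/F evaluation, and a synthetic
    incident-report generator that emulates the class compositions and
    report-length statistics of hospital incident reporting systems so the
    whole pipeline is testable without confidential data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    glmnet,
    jsonlite,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
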