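Package: nodalstaging
Title: Nodal Staging Scores for Occult Lymph Node Metastasis in Papillary
    Thyroid Carcinoma
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Beta-binomial modelling of positive lymph-node counts in
    papillary thyroid carcinoma, fitted by zero-truncated maximum
    likelihood on node-positive patients.  Provides the false-negative
    staging probability as a function of the number of nodes examined,
    prevalence correction for occult metastases, the Bayesian nodal
    staging score (the posterior probability that a pathologically
    node-negative patient is truly node-negative), inversion to the
    number of nodes that must be examined to reach a target negative
    predictive value, a synthetic SEER-like cohort generator with
    ground-truth occult-metastasis labels, and an overall-survival
    comparison across nodal-staging-score quartiles using directly
    implemented Kaplan-Meier and log-rank procedures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
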