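Package: rtkinetics
Title: Cell-Kinetics Modelling of Tumor Volume Response to Radiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Discrete-time cell-kinetics modelling of tumor volume time
    courses measured during fractionated radiotherapy. Tumor growth is
    described by cycling and quiescent compartments with delayed loss of
    killed cells through a three-stage dying pipeline; four treatment-efficacy
    model variants (uniform kill, compartment-specific kill, recruitment of
    quiescent cells, and radioresistant subpopulations) are fitted to
    log-volume data by constrained maximum likelihood with profile-likelihood
    confidence intervals, likelihood-ratio model selection, and a four-way
    response-type classification. Includes linear-quadratic fractionation
    utilities (BED, EQD2) and a seeded synthetic-data generator for
    conventional and hypofractionated treatment courses.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    lhs,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
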