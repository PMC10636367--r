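Package: emanet
Title: Personalized Emotion Networks from Ecological Momentary Assessment Data
Version: 0.1.0
Authors@R:
    person("EMA Networks", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Estimates per-participant directed (lag-1 vector autoregressive)
    and contemporaneous (residual partial-correlation) emotion networks from
    intensive longitudinal ecological momentary assessment (EMA) data,
    enumerates all k-node subnetworks of an item pool, computes signed-sum
    network connectivity, and relates connectivity to depression severity and
    week-to-week depression variability. Includes case-dropping bootstrap
    stability (CS coefficients), weekly lagged connectivity-depression models,
    and a synthetic-cohort generator with a between-person connectivity
    gradient for end-to-end testing without access to raw study data.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
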