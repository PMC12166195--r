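Package: ninflux
Title: Biphasic Michaelis-Menten Kinetics of Root Nitrogen Influx
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing short-term 15N tracer influx experiments in
    plant roots. Implements a two-stage (high-/low-affinity) Michaelis-Menten
    rate law with an activation threshold for the low-affinity phase, fitted
    by profiled nonlinear least squares with variable projection; AICc-based
    comparison against the single-phase model; stratified case-resampling
    bootstrap confidence intervals; simulators for influx assays and
    treatment x organ x analyte metabolite tables; and tidy analytics for
    amino-acid ratios, free-amino-acid totals and log2 fold-change matrices.
    All user-facing functions take data frames and return tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
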