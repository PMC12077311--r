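Package: telegraph
Title: Exact Solutions and Stochastic Simulation of the Two-State Model
    of Transcriptional Bursting
Version: 0.1.0
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.com>
Description: Tools for the two-state (ON/OFF) Markov model of gene
    expression: exact steady-state copy-number distributions via the
    confluent hypergeometric (Kummer M) solution of the chemical master
    equation, the negative-binomial bursting limit and its convergence
    diagnostics, exact stochastic (Gillespie) simulation of the two-state
    process and its M-state promoter ladder generalization, burst
    detection and burst-size/duration statistics with a summary-statistic
    parameter estimator, and a fluorescence time-rescaling diagnostic for
    log-linear decay. Includes TSV/CSV round-tripping of trajectories,
    distributions and traces, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
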