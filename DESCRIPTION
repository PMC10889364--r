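Package: sceptic
Title: Information-Compressing Reinforcement Learning for the Clock Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, fitting, and analysis tools for the SCEPTIC family of
    reinforcement-learning models of the continuous-time "clock" task, in which
    an agent learns when to respond within a trial interval under time-varying
    reward probability and magnitude. Implements the Gaussian radial-basis value
    representation with temporal-generalization eligibility, traditional
    (full-maintenance) and information-compressing (selective-maintenance)
    learning rules, a working-memory comparator with a selection-history buffer,
    value-entropy dynamics, a softmax choice policy, and empirical-Bayes
    hierarchical parameter estimation with group-mean refits. Ships a synthetic
    task-environment generator (IEV/DEV/CEV/CEVR contingencies, original and
    reversal session designs, heterogeneous agent cohorts, synthetic
    trial-aligned neural series) and builders for analysis-ready datasets:
    response-time swings, Kullback-Leibler selection-history statistics,
    working-memory buffer regression tables, within-trial survival datasets with
    time-varying value, and model-based neural regressors (HRF convolution,
    peak-renormalized parametric regressors, high-pass filtering,
    feedback-aligned epoching, and AIC model-comparison tables).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    signal,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
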