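Package: pursuitbayes
Title: Bayesian Observer Analysis of Smooth-Pursuit Initiation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation and analysis of open-loop smooth pursuit eye movements
    under switching direction priors. Generates synthetic 1-kHz eye traces for a
    two-block (narrow/wide prior) random-dot pursuit task, preprocesses them
    (zero-phase Butterworth filtering, differentiation, saccade-window trial
    exclusion), decomposes single trials into direction, gain and latency by
    template fitting, computes session-level bias and precision statistics,
    fits an eight-parameter Gaussian Bayesian observer model to condition
    summaries, and runs time-resolved cluster-based permutation comparisons
    across prior conditions.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    signal,
    lhs,
    withr,
    jsonlite,
    readr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    arrow,
    optparse
Config/testthat/edition: 3
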