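Package: itsprev
Title: Multi-Intervention Interrupted Time Series Analysis of Weekly
    Prevalence Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-intervention interrupted time series (ITS)
    analysis of weekly prevalence series derived from survey microdata.
    Derives a binary mental-health outcome from a days-based survey item,
    aggregates it to survey-weighted weekly prevalence (overall and by
    stratum), encodes a calendar of dated interruptions as lagged binary
    indicators with segment persistence for phased rollouts, and estimates
    intervention effects by regression with ARIMA errors, reporting 95%
    confidence intervals, BIC, Ljung-Box and Stationary R-squared
    diagnostics.  Also provides a long short-term memory (LSTM) network with
    mean and variance output heads trained by Gaussian negative
    log-likelihood for distributional ITS forecasting, a seeded synthetic
    data generator emulating the assumed data-generating process, and a
    Monte-Carlo harness for parameter recovery, confidence-interval coverage
    and type-I-error studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
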