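Package: faersignal
Title: Disproportionality Signal Detection and Time-to-Onset Analysis for
    Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for post-marketing pharmacovigilance
    on FAERS-style spontaneous-report data: reading and deduplicating
    quarterly ASCII tables, extracting primary-suspect cases for a target
    drug, rolling MedDRA preferred terms up to system organ classes, building
    2x2 contingency tables and screening them with four disproportionality
    algorithms (reporting odds ratio, proportional reporting ratio with
    chi-squared, Bayesian information component, empirical Bayes geometric
    mean) under a joint signal rule, summarising cohort characteristics, and
    fitting Weibull time-to-onset models with failure-type classification.
    Includes a self-auditing synthetic-report generator with known ground
    truth so the full pipeline is testable without access to the live corpus.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    utils
Suggests:
    fitdistrplus,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
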