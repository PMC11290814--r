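Package: faersignal
Title: Disproportionality Signal Detection for FAERS Spontaneous Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for pharmacovigilance disproportionality
    analysis of FDA Adverse Event Reporting System (FAERS) quarterly data.
    Parses the $-delimited ASCII distribution (DEMO, DRUG, REAC, OUTC),
    deduplicates versioned case reports, normalizes drug names against a
    synonym dictionary, aggregates MedDRA preferred terms to System Organ
    Classes, builds 2x2 contingency tables for drug-event pairs, and
    computes four disproportionality statistics with 95% confidence
    intervals and positivity criteria: the reporting odds ratio (ROR), the
    proportional reporting ratio (PRR) with its chi-square statistic, the
    information component (IC) of the Bayesian confidence propagation
    neural network, and the relative-reporting-ratio form of the empirical
    Bayes geometric mean (EBGM). Includes demographic and serious-outcome
    descriptive summaries, a synthetic FAERS generator with known ground
    truth for end-to-end testing, and a single-command pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
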