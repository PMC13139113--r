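Package: srsignal
Title: Disproportionality Signal Detection for Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A multi-database pharmacovigilance pipeline for spontaneous
    reporting systems: ingestion of FAERS-style relational extracts and flat
    single-table extracts into a common report schema, key-based
    deduplication, healthcare-professional and primary-suspect inclusion
    filters, preferred-term (PT) case classification, case-noncase 2x2
    contingency tables, four disproportionality statistics (reporting odds
    ratio, proportional reporting ratio with chi-square, Bayesian information
    component, and the DuMouchel gamma-Poisson shrinker EBGM with its lower
    posterior percentile), a combined four-algorithm positivity rule,
    co-medication sensitivity reruns, cross-database replication scoring,
    time-to-onset and annual-trend summaries, labeling-gap classification,
    and a seeded synthetic report generator with analytic expected cell
    counts so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
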