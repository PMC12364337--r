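Package: faersignal
Title: Disproportionality Signal Detection for FAERS-Style Spontaneous
    Adverse Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for pharmacovigilance disproportionality analysis of
    spontaneous adverse-event reports in the FDA Adverse Event Reporting
    System (FAERS) quarterly ASCII dialect. Parses and writes
    dollar-delimited DEMO/DRUG/REAC files, applies the standard cleaning
    steps (case deduplication keeping the latest version, drug-name
    standardization with synonym maps, primary-suspect restriction,
    receipt-date windowing) with full provenance counts, builds 2x2
    contingency tables of report counts against the all-other-drugs
    background, and estimates reporting odds ratios with Woolf 95%
    confidence intervals, Haldane-Anscombe zero-cell correction, and
    threshold-based signal classification. A synthetic spontaneous-report
    generator with injected drug-event associations at known odds ratios
    makes the full pipeline testable without a FAERS download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
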