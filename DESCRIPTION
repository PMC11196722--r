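Package: pvsignal
Title: Disproportionality Signal Detection for Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A pipeline for pharmacovigilance signal detection in
    FAERS-style spontaneous adverse-event report collections: parsing and
    deduplication of case reports, reporting odds ratio (ROR), proportional
    reporting ratio (PRR), chi-square and Bayesian Confidence Propagation
    Neural Network (BCPNN) information component statistics with Wald
    intervals and configurable screening thresholds, MedDRA-style
    LLT/PT/SOC hierarchy rollups, age-stratified signal tables,
    drug-leaflet comparison of positive signals, and a synthetic report
    generator with analytic ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
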