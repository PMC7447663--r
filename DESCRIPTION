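Package: pvsignal
Title: Disproportionality Signal Detection for Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Case/non-case disproportionality analysis for spontaneous
    adverse-drug-reaction reporting databases, built around the Bayesian
    information component (IC) of the BCPNN framework and the reporting odds
    ratio (ROR) with Woolf confidence intervals. Provides a data model for
    individual case safety reports (ICSRs) with de-duplication and exposure
    classification for immune checkpoint inhibitor therapies, a miniature
    catalog of endocrine adverse-event preferred terms with group queries,
    spectrum screening with IC-based signal-strength categories, subgroup
    ROR comparison, time-to-onset summaries and log-scale tests, descriptive
    reporting, and a seeded synthetic ICSR database generator with planted
    disproportionality signals for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
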