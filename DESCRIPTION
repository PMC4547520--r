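Package: mininart
Title: Mokken Scale Analysis and Premorbid IQ Estimation for the
    National Adult Reading Test
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Nonparametric item response theory (Mokken scaling) for
    dichotomous test data: Loevinger scalability coefficients (H, Hi,
    Hij), the automated item selection procedure (AISP), manifest
    monotonicity checks against rest-score groups, invariant item
    ordering (IIO) diagnostics with backward item elimination and the
    HT coefficient, and Molenaar-Sijtsma reliability. Ships the
    published item-difficulty and discrimination tables of the National
    Adult Reading Test (NART) and its 23-item hierarchical subset (the
    mini-NART), regression models converting scale scores to estimated
    premorbid IQ, an adaptive-administration engine for invariantly
    ordered scales, and a 2PL-based synthetic response generator for
    validating every stage of the workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
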