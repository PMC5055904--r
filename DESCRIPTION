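Package: uccea
Title: Markov Cohort Cost-Utility Model for Biologic Treatment of
    Ulcerative Colitis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-period Markov cohort model comparing adalimumab plus
    standard care against standard care alone for moderate-to-severe
    ulcerative colitis, from the public-payer and societal perspectives.
    Implements health-state transition dynamics with weekly induction and
    8-week maintenance cycles, background mortality from a life table,
    discounted cost and QALY accumulation with incremental cost-utility
    ratios, one-way and probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves, and a synthetic Gompertz
    life-table generator for fully reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
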