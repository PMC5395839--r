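Package: albuscreen
Title: Validity and Cost-Effectiveness of Persistent Albuminuria Screening Strategies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating screening strategies for persistent albuminuria
    in populations at high risk of chronic kidney disease. Implements the
    diagnostic-validity workflow (gold-standard classification from repeated
    urine albumin-to-creatinine-ratio measurements, confusion tables, exact
    Clopper-Pearson confidence intervals), a calibrated synthetic-cohort
    generator with multi-level lognormal biomarker variability, a hybrid
    decision-tree/Markov cohort model of screening, treatment and disease
    progression over a 30-year horizon, incremental cost-effectiveness and
    dominance analysis, and one-way (tornado) and probabilistic sensitivity
    analysis with cost-effectiveness acceptability curves.
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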