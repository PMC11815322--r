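Package: flcea
Title: Cost-Utility Markov Model for Front-Line Therapy in Early-Stage
    Follicular Lymphoma
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A five-state Markov cohort model comparing involved-field
    radiotherapy (RT) alone, RT plus CVP chemotherapy, and RT plus
    rituximab-CVP immunochemotherapy as front-line treatment of
    early-stage follicular lymphoma, from an Australian payer
    perspective. Computes discounted lifetime costs and
    quality-adjusted life-years with half-cycle correction, incremental
    cost-effectiveness ratios with dominance classification, one-way
    (tornado) sensitivity analyses, probabilistic sensitivity analysis
    with gamma and beta parameter distributions, and cost-effectiveness
    acceptability curves. Includes a synthetic-trial generator with
    competing exponential event processes and an individual-level
    microsimulation used as an independent validation oracle for the
    cohort engine.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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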