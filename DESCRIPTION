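Package: pade
Title: Sequential Bayesian Predictive Intervals for Differential Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies differentially expressed genes between a treatment and
    a control condition by sequentially comparing each gene's mean treatment
    effect against a credibility interval built from the Student-t predictive
    density of the remaining effects, under a conjugate normal-inverse-gamma
    model. Also provides the Welch two-sample t-test, the Cyber-t test and a
    Bayesian t-test as per-gene baselines, a two-condition Gaussian simulator
    with ground-truth labels, and a Monte-Carlo benchmarking harness that
    aggregates true-positive, false-positive and true-discovery rates over
    replicated datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
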