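Package: survmediate
Title: Natural Direct and Indirect Effects for Survival Outcomes via
    Weighted Cox Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Causal mediation analysis for right-censored survival outcomes
    with one or two binary mediators. Decomposes a total exposure hazard
    ratio into a natural direct effect and mediator-specific natural
    indirect effects using counterfactual data expansion, mediator-model
    weights, and weighted Cox proportional hazards regression, with
    cluster-bootstrap percentile confidence intervals. Includes a clustered
    synthetic-cohort generator with a brute-force counterfactual oracle,
    Kaplan-Meier and cluster-robust descriptive models, and a reporting
    pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    sandwich,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
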