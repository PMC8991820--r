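Package: ceamiss
Title: Missing-Data Strategies for Trial-Based Cost-Effectiveness Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for handling missing cost and quality-of-life data in
    within-trial cost-effectiveness analysis with staggered recruitment and a
    fixed study end. Implements complete-case analysis, multiple imputation by
    chained equations with linear-regression and predictive-mean-matching
    imputers pooled by Rubin's rules, repeated-measures mixed and fixed-effects
    panel estimators with cluster bootstrap, and a Bayesian selection model in
    which missing patient-level totals are treated as parameters. Includes a
    synthetic-trial generator that emulates design-driven (administrative
    censoring, single late telephone follow-up) and covariate/time-dependent
    missing-at-random item missingness, so estimator bias and coverage are
    testable against known truth. Reports incremental costs and QALYs,
    ICERs with dominance handling, and parametric or bootstrap
    cost-effectiveness acceptability curves.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    sandwich,
    rjags,
    coda
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
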