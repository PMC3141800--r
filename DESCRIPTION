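Package: recgap
Title: Multiplicative and Additive Hazards Models for Recurrent Event Gap Times
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits the two principal semiparametric regression frameworks for
    recurrent event gap times: the stratified multiplicative (conditional
    gap-time) proportional hazards model with Breslow baselines and a robust
    sandwich variance built from per-subject aggregated score residuals, and
    the Lin-Ying semiparametric additive hazards model with its closed-form
    estimator and A^-1 V A^-1 sandwich variance. Includes stratum-specific
    cumulative baseline hazard and survival estimation, martingale and
    deviance residuals with Arjas-style observed-versus-expected diagnostics,
    long-format counting-process data construction with order-specific
    covariate expansion, and a gamma-frailty event-history simulator that
    reproduces within-subject correlation and induced dependent censoring.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    survival,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
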