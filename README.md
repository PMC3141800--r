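# recgap

Recurrent event durations — the gap times between a subject's successive
events, such as repeat emergency-department visits after an injury — cannot
be analysed with ordinary single-event hazard regression: a subject's gaps
are positively correlated, and independent censoring of total follow-up
still censors the *later* gaps dependently on the earlier history. recgap
implements, for analysts of such data, the two principal semiparametric
frameworks on the gap-time scale, each stratified by event order `k` so
every recurrence keeps its own unspecified baseline hazard
$\lambda_{0k}(t)$:

* the **multiplicative (conditional gap-time) model**
  $\lambda_{ik}(t) = \lambda_{0k}(t)\,e^{\beta' Z_{ik}}$, fitted by
  Newton–Raphson on the stratified partial likelihood with Breslow ties,
  Breslow baseline estimation, and a robust sandwich variance
  $I^{-1}(\hat D'\hat D)I^{-1}$ built from per-subject aggregated score
  residuals;
* the **Lin–Ying additive hazards model**
  $\lambda_{ik}(t) = \lambda_{0k}(t) + \beta' Z_{ik}$, with its closed-form
  estimator
  $\hat\beta = [\sum_{ik}\int Y_{ik}\{Z_{ik}-\bar Z_k(t)\}^{\otimes 2}dt]^{-1}
  \sum_{ik}\int\{Z_{ik}-\bar Z_k(t)\}dN_{ik}(t)$
  (all integrals evaluated exactly over the observed gap grid) and the
  $A^{-1}VA^{-1}$ sandwich variance.

Both models support one shared coefficient vector across orders or
order-specific coefficients via covariate-by-order expansion. Around the
fits: long-format counting-process data construction, per-stratum
cumulative baseline hazards and survival prediction, martingale/deviance
residuals with Arjas-style observed-versus-expected diagnostics, and a
gamma-frailty cohort simulator reproducing within-subject correlation and
induced dependent censoring. Wald tables report estimate, naive SE,
sandwich SE, $\chi^2 = (\text{estimate}/\text{sandwich SE})^2$ and its
upper-tail 1-df p-value.

## Worked example

```r
library(recgap)

cfg    <- sim_config(n_subjects = 500, seed = 20)   # ED-revisit-like cohort
cohort <- simulate_cohort(cfg)
rec    <- build_gap_records(cohort, k_max = 4)

spec <- design_spec(c("sex", "race", "age", "parent"),
                    effects = "common", k_max = 4)
(fit <- fit_cox_gap(rec, spec))
#> Stratified multiplicative gap-time hazards model (common effects)
#>   500 subjects, 1001 records, 555 events in 4 strata
#>   log partial likelihood: -2708 (4 iterations, max |score| = 1.76e-10)
#>
#>  covariate estimate naive_se sandwich_se  chisq   p_value
#>        sex  -0.6366  0.10044     0.10436 37.207 1.062e-09
#>       race   0.3432  0.10424     0.10173 11.383 7.412e-04
#>        age   0.0500  0.01107     0.01162 18.505 1.694e-05
#>     parent   0.1151  0.08632     0.08830  1.701 1.922e-01

fit_additive_ly(rec, spec)
#> Lin-Ying additive gap-time hazards model (common effects)
#>   500 subjects, 1001 records, 555 events in 4 strata
#>
#>  covariate estimate naive_se sandwich_se  chisq   p_value
#>        sex -0.32379 0.062127    0.067658 22.904 1.703e-06
#>       race  0.12312 0.032152    0.031343 15.429 8.567e-05
#>        age  0.01981 0.004256    0.004528 19.150 1.208e-05
#>     parent  0.05073 0.032163    0.032672  2.411 1.205e-01
```

Read the two tables together: the multiplicative coefficients are log
hazard ratios (being male multiplies the revisit hazard by
$e^{-0.64}\approx 0.53$ at every order), the additive ones are rate
differences (being male lowers the revisit rate by 0.32 events per year at
every order). Both report the same directions and the same covariates as
significant; the sandwich SEs exceed the naive ones where within-subject
correlation matters. Survival prediction and diagnostics continue from the
same objects:

```r
bl <- breslow_baseline(fit, rec, order_k = 1)
predict_survival(fit, bl, c(sex = 1, race = 1, age = 15, parent = 1))
res <- martingale_residuals(fit, rec)
sum(res$cum_intensity)   # 555: expected events conserve the observed total
```

A command-line front end wraps the same functions
(`Rscript inst/cli/recgap.R <simulate|fit|predict|diagnose> ...`); see
`?recgap_cli`.

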