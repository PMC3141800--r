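---
title: "Multiplicative and additive hazards models for recurrent gap times"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiplicative and additive hazards models for recurrent gap times}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recgap)
```

## The data and the two models

Recurrent event data record repeated occurrences of the same event for each
subject — repeat emergency-department visits after an injury, tumour
recurrences, seizure episodes. Two features make them unlike ordinary
single-event survival data. First, a subject's successive durations are
positively correlated: subjects differ in unmeasured proneness, so a short
first gap predicts a short second gap. Second, even when the overall
follow-up time is censored independently, the *later* gap times are cut
short in a way that depends on the earlier event history (a subject whose
first two events came late has less room left for a third) — induced
dependent censoring.

recgap works on the **gap-time scale**: order the events within subject,
let $G_{ik} = X_{ik} - X_{i,k-1}$ be the duration between subject $i$'s
$(k-1)$-th and $k$-th events, and reset the clock to zero at each event.
Each (subject, order) pair is one record $(G_{ik}, \delta_{ik}, Z_{ik})$,
with $\delta_{ik}$ indicating an observed event and $Z_{ik}$ the baseline
covariates. Subjects censored before reaching order $k$ are simply absent
from stratum $k$; this is what makes the per-order risk sets shrink.

Two semiparametric regressions are fitted to those records, both stratified
by event order so each recurrence keeps its own unspecified baseline hazard
$\lambda_{0k}$:

* **Multiplicative (conditional gap-time) model**
  $\lambda_{ik}(t) = \lambda_{0k}(t)\, e^{\beta' Z_{ik}}$, estimated by
  maximising the stratified partial likelihood
  $\prod_{k}\prod_{i:\delta_{ik}=1}
  e^{\beta' Z_{ik}} / \sum_{j: G_{jk} \ge G_{ik}} e^{\beta' Z_{jk}}$.
  Coefficients are log hazard ratios.
* **Additive model (Lin–Ying)**
  $\lambda_{ik}(t) = \lambda_{0k}(t) + \beta' Z_{ik}$, estimated in closed
  form:
  $\hat\beta = \big[\sum_{ik}\int Y_{ik}(t)\{Z_{ik}-\bar Z_k(t)\}^{\otimes 2}
  dt\big]^{-1} \sum_{ik}\int \{Z_{ik}-\bar Z_k(t)\}\,dN_{ik}(t)$,
  where $\bar Z_k(t)$ is the risk-set mean covariate in stratum $k$.
  Coefficients are rate differences (events per unit time per unit of
  covariate), which many epidemiologists find the more natural scale.

Both models can share one coefficient vector across orders
(`effects = "common"`) or estimate one per order
(`effects = "order_specific"`, realised as covariate-by-order interaction
columns, so a single stratified fit still produces all of them).

The at-risk indicator is $Y_{jk}(t) = I(G_{jk} \ge t)$ — a record is in the
risk set at its own event time — for *both* models. (Printed conventions for
the additive model sometimes flip the inequality; the standard at-risk
meaning is the one implemented.)

## Variance estimation

Records from the same subject are correlated, so the usual model-based
variances are wrong. Both fits therefore report two matrices:

* a **naive** variance — the inverse observed information for the
  multiplicative model; for the additive model a working-independence
  analogue built from per-record scores — valid only if all records were
  independent;
* a **robust sandwich** variance, built from *per-subject aggregated*
  residual scores. For the multiplicative model,
  $I^{-1}(\hat D'\hat D) I^{-1}$ with $\hat D$ the matrix of per-subject
  summed score residuals; for the additive model $A^{-1} V A^{-1}$ with
  $V$ assembled from per-subject sums of
  $\int \{Z_{ik}-\bar Z_k(t)\}\,d\hat M_{ik}(t)$.

Wald inference in `fit_table()` uses the sandwich:
$\chi^2 = (\text{estimate}/\text{sandwich SE})^2$ on 1 df.

A normalisation detail the literature leaves implicit: recgap stores
$A$ = (integrated dispersion)/$n$ and $V$ = (sum of per-subject outer
products)/$n^2$, so that $A^{-1}VA^{-1}$ estimates
$\mathrm{var}(\hat\beta)$ *directly*, with no extra sample-size factor.
This convention is validated empirically by the coverage simulation in the
test suite (robust 95% intervals cover at about 0.95).

## Numerical choices

* **Ties.** Breslow's approximation in the partial likelihood and in the
  baseline estimator. Gap times from coarse clocks (days) tie often; Efron
  weighting is not implemented.
* **Optimisation.** Newton–Raphson from $\beta = 0$ with step-halving;
  convergence when $\max_j |U_j(\beta)| < 10^{-9}$ (50 iterations cap).
  Steps are only halved on a *material* decrease of the log partial
  likelihood (beyond rounding, $10^{-10}(|\ell|+1)$); rejecting
  rounding-level decreases stalls the quadratic score convergence near the
  optimum. The additive estimator is one linear solve and needs none of
  this.
* **Monotone likelihood.** If any coefficient passes 50 in magnitude during
  iteration the fit aborts with an explanatory error. With perfectly
  separating binary covariates the score can instead vanish in the limit,
  so a formally converged fit whose coefficients exceed 15 in magnitude
  draws a boundary warning rather than an error.
* **Additive integrals.** All time integrals are exact finite sums over the
  distinct observed gaps per stratum — the integrands are piecewise
  constant between them — so $\hat\beta$ solves the estimating equation to
  linear-algebra precision. Integration stops at the largest observed gap
  in each stratum (the risk set is empty beyond it), and baseline
  evaluation past that point is clamped with a warning rather than
  extrapolated.
* **Degenerate designs.** Constant or collinear covariate columns raise a
  singularity error naming the offending column before iteration starts.
* **Additive pathologies.** Nothing constrains the fitted additive hazard
  $\hat\lambda_{0k}(t) + \hat\beta' z$ to be nonnegative; preserving the
  closed form was judged worth the occasional negative fitted hazard.
  Consequently the additive baseline need not be monotone and the raw
  survival curve $\exp\{-\hat\Lambda_{0k}(t) - \hat\beta' z\, t\}$ can
  exceed 1 or rise. `predict_survival()` returns the raw curve alongside a
  monotone-corrected one (running minimum clipped to $[0,1]$) and warns
  when they differ; event records whose estimated cumulative intensity goes
  negative get an `NA` deviance residual with a warning.
* **Zero-length records.** A subject whose follow-up ends exactly at an
  event contributes no zero-gap censored record to the next stratum: such a
  record is at risk for no time and would only distort risk-set
  conventions.

## Diagnostics

`martingale_residuals()` returns per-record
$\hat M_{ik} = \delta_{ik} - \hat\Lambda_{ik}(G_{ik})$ with the cumulative
intensity taken from the fitted model (Breslow baseline times
$e^{\hat\beta' Z}$, or additive baseline plus $\hat\beta' Z\, G$), their
deviance transform
$d = \mathrm{sign}(\hat M)\sqrt{-2[\hat M + \delta\log(\delta-\hat M)]}$
(log term dropped when $\delta = 0$), and per-subject totals. Under the
multiplicative model with its Breslow baseline the estimated intensities
*exactly* conserve the observed event total — the identity that anchors the
Arjas diagnostic: `arjas_data()` orders records within covariate groups by
estimated cumulative intensity and accumulates observed versus expected
event totals; a well-fitting model tracks the diagonal. Grouping defaults
to a single group and accepts any covariate column; the ordering-by-
intensity convention is a documented package choice, since no standard
fixes it.

## What the simulator emulates — and what it does not

`simulate_cohort()` generates the structure the models are designed for,
at the scale of a pediatric firearm-injury ED revisit cohort of around 500
subjects followed for a median of about 3 years:

* covariates: binary male (0.85), black (0.70), parent-as-guardian (0.55)
  indicators and an integer age uniform on 5–18;
* true effects: by default the multiplicative truth uses log hazard ratios
  (sex $-0.654$, race $0.335$, age $0.043$/yr, guardian $0.152$) and the
  additive truth the corresponding rate differences (per-year scale),
  magnitudes typical of published common-effect estimates for such
  cohorts;
* baselines: constant per-order gap-time hazards
  $(0.25, 0.30, 0.35, 0.38)$ per year — the simplest family with an
  order-varying baseline. The values were calibrated once against the
  published event-count distribution of that cohort shape (about 48.5%
  with no revisit, tailing off to ~3% with six or more) and then frozen;
* dependence: a mean-1 gamma frailty $w_i$ (default variance
  $\sigma^2 = 0.25$) multiplying every hazard of subject $i$. For two gaps
  sharing a gamma frailty the implied Kendall rank correlation is
  $\sigma^2/(\sigma^2+2)$ (`frailty_kendall_tau()`), which the tests verify
  empirically;
* censoring: one $C_i \sim U(0, 6.4)$ years per subject applied on the
  *total-time* scale, so later gaps are censored dependently on the earlier
  history — exactly the induced dependent censoring the gap-time framework
  has to live with. Additive configurations are validated at construction
  so $\lambda_{0k} + \beta' z \ge 0$ over the whole covariate support.

RNG discipline: one seeded stream, subjects generated in a fixed order,
and a fixed-length latent gap sequence (100 orders) per subject with
censoring applied as a pure transform of it. The same seed and
configuration reproduce a cohort bitwise; tightening `censor_max` at a
fixed seed can only remove events. The latent gaps and frailty are kept on
each history for oracle checks.

What it does *not* emulate: informative censoring linked to the event
process (dropout caused by the events themselves), terminal events
competing with recurrence, time-varying covariates, or non-constant
baseline shapes. A passing test suite therefore says the estimators do
what their theory promises under frailty-type dependence and induced
dependent censoring — not that any real cohort satisfies those
assumptions.

## Marginal fits under frailty: a deliberate estimand gap

The fitted models are *marginal*: no frailty term is estimated. When data
are generated *with* a frailty, the marginal hazard ratio is attenuated
relative to the conditional one (high-frailty subjects fail early and
leave, diluting the contrast), so the common-effect fits converge to a
shrunken version of the generating coefficients — at the default study
conditions the measured attenuation factor is about 0.86 for both models,
and the package's recovery simulations report exactly that. With the
frailty switched off ($\sigma^2 = 0$) both fits recover the generating
coefficients within Monte-Carlo error, which the test suite checks. The
coverage study consequently centres its intervals on the marginal
(pseudo-true) parameter — estimated once from a large simulated cohort —
because its question is whether the *variance* estimators are honest:
robust 95% intervals cover at about 0.95 while the naive ones cover
strictly less. Frailty *estimation* is out of scope by design; the frailty
here is a data-generating device.

## Problem sizes used in the shipped checks

The test suite and the acceptance script keep simulations at desk scale,
chosen so Monte-Carlo error is small relative to the tolerances being
checked: 20 random single-order fixtures of $n = 200$ for the
reference-implementation comparison; 50 replicates of $n = 2000$ for the
recovery study; 200 replicates of $n = 300$ (with an $n = 60{,}000$
pseudo-truth cohort) for the coverage study; $n$ in the low thousands for
the Kendall-tau calibration. The acceptance script scales the replicate
counts down (25 and 100) and re-derives every number from scratch at run
time.

## Known limitations

* Breslow ties only; heavy tying with small risk sets will bias hazard
  ratios slightly toward zero, as it always does.
* The additive fit can produce negative fitted hazards and non-monotone
  baselines; both are reported, flagged, and left to the analyst.
* No left truncation within a stratum: every gap clock starts at zero.
* Fit objects do not serialise to a file format; the command-line
  `predict`/`diagnose` subcommands refit from the data table instead.
* Order-specific designs estimate $p \times k_{\max}$ parameters; with
  sharply shrinking risk sets the later-order estimates are noisy, and the
  package reproduces the expected growth of their standard errors with
  order rather than hiding it.
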