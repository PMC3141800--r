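test_that("fixture fit matches independent maximisation of the partial likelihood", {
  fit <- fit_cox_gap(fixture_f1(), design_spec("z", k_max = 1))
  b_star <- f1_cox_oracle_beta()
  expect_lt(abs(fit$coefficients[["z"]] - b_star), 1e-6)
  expect_equal(fit$loglik[["maximum"]],
               f1_cox_loglik(fit$coefficients[["z"]]), tolerance = 1e-12)
  # naive variance = inverse finite-difference information of the oracle
  expect_equal(fit$naive_covariance[1, 1],
               1 / f1_cox_oracle_information(b_star), tolerance = 1e-4)
})

test_that("symmetric tied data yield a zero coefficient under Breslow ties", {
  rec <- data.frame(id = c("a", "b"), order_k = 1, gap = c(1, 1),
                    status = c(1, 1), z = c(1, 0))
  fit <- fit_cox_gap(rec, design_spec("z", k_max = 1))
  expect_equal(unname(fit$coefficients), 0, tolerance = 1e-12)
})

test_that("degenerate designs raise singularity errors naming the column", {
  rec <- fixture_f1()
  rec$flat <- 1
  expect_error(fit_cox_gap(rec, design_spec(c("z", "flat"), k_max = 1)),
               "flat")
  rec$z2 <- 2 * rec$z
  expect_error(fit_cox_gap(rec, design_spec(c("z", "z2"), k_max = 1)),
               "z2")
})

test_that("monotone likelihood is detected or flagged", {
  # small-scale covariate: the score cannot reach tolerance before the
  # coefficient passes the bound
  rec <- data.frame(id = letters[1:4], order_k = 1, gap = c(1, 2, 3, 4),
                    status = c(1, 1, 0, 0), z = c(0.1, 0.1, 0, 0))
  expect_error(fit_cox_gap(rec, design_spec("z", k_max = 1)),
               "monotone likelihood")
  # binary covariate: the score vanishes in the limit, so the fit formally
  # converges but lands on an implausible boundary estimate
  rec$z <- c(1, 1, 0, 0)
  expect_warning(fit_cox_gap(rec, design_spec("z", k_max = 1)),
                 "boundary")
})

test_that("score residuals reproduce direct arithmetic and sum to the score", {
  rec <- fixture_f1()
  fit <- fit_cox_gap(rec, design_spec("z", k_max = 1))
  b <- fit$coefficients[["z"]]
  w <- exp(b * rec$z)
  # direct arithmetic: risk sums at the three event gaps
  S0 <- c(2 * exp(b) + 2, exp(b) + 2, exp(b) + 1)
  zbar <- c(2 * exp(b), exp(b), exp(b)) / S0
  dL <- 1 / S0                                  # Breslow increments
  H <- cumsum(dL)
  Q <- cumsum(zbar * dL)
  n_ev <- c(1, 2, 3, 3)                         # events with gap <= G_i
  expected <- rec$status * (rec$z - zbar[pmin(rec$gap, 3)]) -
    w * (rec$z * H[n_ev] - Q[n_ev])
  D <- score_residuals(fit, rec)
  expect_equal(unname(D[, 1]), expected, tolerance = 1e-10)
  expect_lt(abs(sum(D)), 1e-8)
  # robust covariance is the sandwich of the residual cross-product
  expect_equal(fit$robust_covariance[1, 1],
               fit$naive_covariance[1, 1]^2 * sum(expected^2),
               tolerance = 1e-10)
})

test_that("a single-subject fit has zero aggregated score residual", {
  rec <- data.frame(id = "solo", order_k = 1:2, gap = c(2, 3),
                    status = c(1, 1), z = c(1, 1))
  rec2 <- rbind(rec, data.frame(id = "other", order_k = 1:2, gap = c(1, 4),
                                status = c(1, 1), z = c(0, 0)))
  fit <- fit_cox_gap(rec2, design_spec("z", k_max = 2))
  D <- score_residuals(fit, rec2)
  # two subjects, one coefficient: rows are +/- the same value and sum to 0
  expect_lt(abs(sum(D)), 1e-8)
  expect_equal(nrow(D), 2L)
})

test_that("doubling the dataset doubles information and halves the naive variance", {
  rec <- fixture_f1()
  rec2 <- rec
  rec2$id <- paste0(rec2$id, "_dup")
  both <- rbind(rec, rec2)
  f1 <- fit_cox_gap(rec, design_spec("z", k_max = 1))
  f2 <- fit_cox_gap(both, design_spec("z", k_max = 1))
  expect_equal(f2$coefficients, f1$coefficients, tolerance = 1e-8)
  expect_equal(f2$information[1, 1], 2 * f1$information[1, 1],
               tolerance = 1e-7)
  expect_equal(f2$naive_covariance[1, 1], f1$naive_covariance[1, 1] / 2,
               tolerance = 1e-7)
})

test_that("Breslow baseline matches the plug-in closed form on the fixture", {
  rec <- fixture_f1()
  fit <- fit_cox_gap(rec, design_spec("z", k_max = 1))
  b <- fit$coefficients[["z"]]
  bl <- breslow_baseline(fit, rec, 1)
  expect_equal(bl$times, c(1, 2, 3))
  expect_equal(bl$increments,
               c(1 / (2 * exp(b) + 2), 1 / (exp(b) + 2), 1 / (exp(b) + 1)),
               tolerance = 1e-12)
  expect_equal(bl$cumhaz, cumsum(bl$increments))
  # forcing beta = 0 gives Nelson-Aalen increments 1/4, 1/3, 1/2
  bl0 <- breslow_baseline(fit, rec, 1, coefficients = 0)
  expect_equal(bl0$increments, c(1 / 4, 1 / 3, 1 / 2))
  # empty stratum warns and returns an empty baseline
  expect_warning(bl_e <- breslow_baseline(fit, rec, 3), "empty")
  expect_length(bl_e$times, 0)
  expect_equal(cumhaz_at(bl_e, c(0, 5)), c(0, 0))
})

test_that("survival predictions respect the proportional-hazards structure", {
  rec <- small_cohort_records(n = 120, seed = 9)
  spec <- design_spec(c("sex", "race", "age", "parent"), "common", 4)
  fit <- fit_cox_gap(rec, spec)
  bl <- breslow_baseline(fit, rec, 1)
  z0 <- c(sex = 0, race = 0, age = 0, parent = 0)
  s0 <- predict_survival(fit, bl, z0)
  expect_equal(s0$survival[s0$time == 0], 1)
  expect_equal(s0$survival, exp(-cumhaz_at(bl, s0$time)))
  expect_true(all(diff(s0$survival) <= 1e-12))
  # power relation at linear predictor log 2
  lp1 <- sum(fit$coefficients * c(1, 1, 15, 1))
  z_scaled <- c(sex = 1, race = 1, age = 15, parent = 1) * (log(2) / lp1)
  s2 <- predict_survival(fit, bl, z_scaled)
  expect_equal(s2$survival, s0$survival^2, tolerance = 1e-10)
  # ordering: higher risk, lower survival everywhere
  s_hi <- predict_survival(fit, bl, c(sex = 0, race = 1, age = 18, parent = 1))
  s_lo <- predict_survival(fit, bl, c(sex = 1, race = 0, age = 5, parent = 0))
  expect_true(all(s_hi$survival <= s_lo$survival + 1e-12))
})

test_that("converged fits satisfy the score equation and local-maximum property", {
  set.seed(31)
  for (seed in c(11, 12)) {
    rec <- small_cohort_records(n = 100, seed = seed)
    spec <- design_spec(c("sex", "race", "age", "parent"), "common", 4)
    fit <- fit_cox_gap(rec, spec)
    expect_lt(fit$score_norm, 1e-8)
    # random perturbations never beat the maximum
    des <- recgap:::build_design(rec, spec)
    sdat <- recgap:::split_strata(des$records, des$Z)
    ll_max <- recgap:::cox_lui(fit$coefficients, sdat)$ll
    expect_gte(ll_max, recgap:::cox_lui(numeric(4), sdat)$ll)
    for (r in 1:5) {
      eps <- rnorm(4) * 0.05
      expect_gte(ll_max, recgap:::cox_lui(fit$coefficients + eps, sdat)$ll)
    }
    # covariances symmetric positive semi-definite
    for (V in list(fit$naive_covariance, fit$robust_covariance)) {
      expect_equal(V, t(V))
      expect_true(all(eigen(V, symmetric = TRUE)$values > -1e-10))
    }
  }
})

test_that("order-specific fit on single-order data equals the common fit", {
  rec <- random_k1_records(80, seed = 5)
  common <- fit_cox_gap(rec, design_spec(c("z1", "z2"), "common", 1))
  os <- fit_cox_gap(rec, design_spec(c("z1", "z2"), "order_specific", 1))
  expect_equal(unname(os$coefficients), unname(common$coefficients),
               tolerance = 1e-12)
  expect_equal(unname(os$robust_covariance), unname(common$robust_covariance),
               tolerance = 1e-12)
})

test_that("single-order fits agree with the reference proportional-hazards implementation", {
  rec <- random_k1_records(150, seed = 17)
  fit <- fit_cox_gap(rec, design_spec(c("z1", "z2"), k_max = 1))
  cf <- suppressWarnings(
    survival::coxph(survival::Surv(gap, status) ~ z1 + z2, data = rec,
                    ties = "breslow", robust = TRUE,
                    control = survival::coxph.control(eps = 1e-12)))
  expect_equal(unname(fit$coefficients), unname(coef(cf)), tolerance = 1e-6)
  expect_equal(unname(fit$naive_covariance), unname(cf$naive.var),
               tolerance = 1e-8)
  expect_equal(unname(fit$robust_covariance), unname(cf$var),
               tolerance = 1e-8)
})

test_that("stratified multi-order fits agree with the reference implementation", {
  rec <- small_cohort_records(n = 200, seed = 23)
  spec <- design_spec(c("sex", "race", "age", "parent"), "common", 4)
  fit <- fit_cox_gap(rec, spec)
  cf <- suppressWarnings(survival::coxph(
    survival::Surv(gap, status) ~ sex + race + age + parent +
      survival::strata(order_k) + survival::cluster(id),
    data = rec, ties = "breslow",
    control = survival::coxph.control(eps = 1e-12)))
  expect_equal(unname(fit$coefficients), unname(coef(cf)), tolerance = 1e-7)
  expect_equal(unname(fit$robust_covariance), unname(cf$var),
               tolerance = 1e-8)
})
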