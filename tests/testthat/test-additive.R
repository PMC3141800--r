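test_that("closed-form estimator matches direct evaluation of the estimating sums", {
  fit <- fit_additive_ly(fixture_f1(), design_spec("z", k_max = 1))
  oracle <- f1_additive_oracle()
  expect_lt(abs(fit$coefficients[["z"]] - oracle$beta), 1e-10)
  # A is the integrated dispersion normalised by subjects (n = 4)
  expect_equal(fit$A_matrix[1, 1], oracle$A_raw / 4, tolerance = 1e-12)
  expect_equal(fit$A_raw[1, 1], oracle$A_raw, tolerance = 1e-12)
  # the estimating equation is solved to linear-algebra precision
  expect_lt(max(abs(fit$estimating_value)), 1e-10 * max(1, abs(oracle$b)))
})

test_that("sandwich pieces match termwise arithmetic on the fixture", {
  rec <- fixture_f1()
  fit <- fit_additive_ly(rec, design_spec("z", k_max = 1))
  b <- fit$coefficients[["z"]]
  z <- rec$z
  zbar <- c(1 / 2, 1 / 3, 1 / 2, 0)          # risk-set means on grid 1..4
  r_sz <- c(4, 3, 2, 1)
  d <- c(1, 1, 1, 0)
  # per-record integrated residual scores, assembled term by term:
  # event term - NA-jump term - drift-of-baseline term - own-drift term
  H <- cumsum(d / r_sz)
  QH <- cumsum(zbar * d / r_sz)
  CD <- 1:4
  CZD <- cumsum(zbar)
  CsD <- cumsum(-b * zbar)
  CZsD <- cumsum(-b * zbar^2)
  li <- rec$gap                                # grid index = gap here
  u <- rec$status * (z - zbar[li]) - (z * H[li] - QH[li]) -
    (z * CsD[li] - CZsD[li]) - (b * z) * (z * CD[li] - CZD[li])
  expect_equal(unname(fit$score_residuals[, 1]), u, tolerance = 1e-12)
  expect_equal(fit$V_matrix[1, 1], sum(u^2) / 16, tolerance = 1e-12)
  A_inv <- 1 / fit$A_raw[1, 1]
  expect_equal(fit$robust_covariance[1, 1], A_inv^2 * sum(u^2),
               tolerance = 1e-12)
  # A^-1 V A^-1 on the stored normalised matrices equals the sandwich
  expect_equal(solve(fit$A_matrix) %*% fit$V_matrix %*% solve(fit$A_matrix),
               fit$robust_covariance, tolerance = 1e-10)
  expect_lt(abs(sum(u)), 1e-12)
})

test_that("symmetric two-group data give a zero additive coefficient", {
  rec <- data.frame(id = c("a1", "a2", "b1", "b2"), order_k = 1,
                    gap = c(1, 2, 1, 2), status = c(1, 1, 1, 1),
                    z = c(0, 0, 1, 1))
  fit <- fit_additive_ly(rec, design_spec("z", k_max = 1))
  expect_equal(unname(fit$coefficients), 0, tolerance = 1e-12)
})

test_that("constant covariates are singular for the additive estimator", {
  rec <- fixture_f1()
  rec$flat <- 2
  expect_error(fit_additive_ly(rec, design_spec("flat", k_max = 1)),
               "singular")
})

test_that("location shifts of a covariate do not move the estimate", {
  rec <- small_cohort_records(n = 120, seed = 41)
  spec <- design_spec(c("sex", "race", "age", "parent"), "common", 4)
  f0 <- fit_additive_ly(rec, spec)
  rec_shift <- rec
  rec_shift$age <- rec_shift$age + 100
  f1 <- fit_additive_ly(rec_shift, spec)
  expect_equal(f1$coefficients, f0$coefficients, tolerance = 1e-9)
  expect_equal(f1$robust_covariance, f0$robust_covariance, tolerance = 1e-9)
})

test_that("rescaling time rescales additive coefficients inversely", {
  rec <- small_cohort_records(n = 100, seed = 43)
  spec <- design_spec(c("sex", "race", "age", "parent"), "common", 4)
  f0 <- fit_additive_ly(rec, spec)
  rec_c <- rec
  rec_c$gap <- rec_c$gap * 2.5
  f1 <- fit_additive_ly(rec_c, spec)
  expect_equal(f1$coefficients, f0$coefficients / 2.5, tolerance = 1e-9)
})

test_that("additive baseline is Nelson-Aalen at zero coefficients and matches the fixture arithmetic", {
  rec <- fixture_f1()
  fit <- fit_additive_ly(rec, design_spec("z", k_max = 1))
  # forced beta = 0: exact Nelson-Aalen on the stratum
  bl0 <- additive_baseline(fit, rec, 1, coefficients = 0)
  na <- nelson_aalen_direct(rec$gap, rec$status)
  expect_equal(cumhaz_at(bl0, na$times), na$cumhaz, tolerance = 1e-12)
  # fitted beta: jumps minus integrated drift, evaluated term by term
  b <- fit$coefficients[["z"]]
  zbar <- c(1 / 2, 1 / 3, 1 / 2, 0)
  jumps <- c(1 / 4, 1 / 3, 1 / 2, 0)
  drift <- cumsum(b * zbar)                    # unit spacing
  bl <- additive_baseline(fit, rec, 1)
  expect_equal(bl$cum_at_grid, cumsum(jumps) - drift, tolerance = 1e-12)
  # mid-interval evaluation interpolates the drift only
  expect_equal(cumhaz_at(bl, 1.5),
               (1 / 4 - b / 2) - b * (1 / 3) * 0.5, tolerance = 1e-12)
  # beyond the last gap: clamped with a warning
  expect_warning(v <- cumhaz_at(bl, 10), "clamped")
  expect_equal(v, bl$cum_at_grid[4], tolerance = 1e-12)
})

test_that("additive survival curves handle the negative-hazard pathology", {
  rec <- fixture_f1()
  fit <- fit_additive_ly(rec, design_spec("z", k_max = 1))
  bl <- additive_baseline(fit, rec, 1)
  s0 <- predict_survival(fit, bl, c(z = 0))
  expect_equal(s0$survival[s0$time == 0], 1)
  expect_equal(s0$survival_raw, exp(-cumhaz_at(bl, s0$time)))
  # a strongly protective covariate drives the raw curve above 1
  expect_warning(s_neg <- predict_survival(fit, bl, c(z = -10)),
                 "monotone|exceeds 1")
  expect_true(any(s_neg$survival_raw > 1))
  expect_true(all(s_neg$survival <= 1))
  expect_true(all(diff(s_neg$survival) <= 1e-12))
})

test_that("additive subject scores sum to zero and the sandwich is PSD", {
  rec <- small_cohort_records(n = 150, seed = 47)
  for (eff in c("common", "order_specific")) {
    spec <- design_spec(c("sex", "race", "age", "parent"), eff, 4)
    fit <- fit_additive_ly(rec, spec)
    expect_lt(max(abs(colSums(fit$score_residuals))), 1e-8)
    expect_lt(max(abs(fit$estimating_value)),
              1e-10 * max(1, max(abs(fit$A_raw))))
    for (V in list(fit$A_matrix, fit$robust_covariance,
                   fit$naive_covariance)) {
      expect_equal(V, t(V))
      expect_true(all(eigen(V, symmetric = TRUE)$values > -1e-10))
    }
  }
})

test_that("order-specific additive fit on single-order data equals the common fit", {
  rec <- random_k1_records(90, seed = 51)
  common <- fit_additive_ly(rec, design_spec(c("z1", "z2"), "common", 1))
  os <- fit_additive_ly(rec, design_spec(c("z1", "z2"), "order_specific", 1))
  expect_equal(unname(os$coefficients), unname(common$coefficients),
               tolerance = 1e-12)
})
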