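# Stratified multiplicative (conditional gap-time) hazards model.
#
# Each event order k is a stratum with its own unspecified baseline hazard on
# the gap-time scale; within stratum k the at-risk set at gap time t is
# {j : G_jk >= t} (a record is in the risk set at its own event time). The
# partial likelihood multiplies the usual Cox factors over strata, with the
# Breslow approximation for ties.

revcumsum <- function(x) {
  if (is.matrix(x)) {
    n <- nrow(x)
    if (n == 1L) return(x)
    apply(x[n:1, , drop = FALSE], 2, cumsum)[n:1, , drop = FALSE]
  } else rev(cumsum(rev(x)))
}

# Per-stratum sufficient statistics at the unique gap values, ascending.
# Risk-set sums are suffix sums: S0_u = sum of w over records with gap >= ug[u].
cox_stratum_stats <- function(gap, status, Z, eta) {
  w <- exp(eta)
  ug <- sort(unique(gap))
  nu <- length(ug)
  ri <- match(gap, ug)
  p <- ncol(Z)
  grp <- factor(ri, levels = seq_len(nu))
  w_u <- unname(rowsum(w, grp)[, 1L])
  S0 <- revcumsum(w_u)
  S1 <- unname(revcumsum(rowsum(Z * w, grp)))
  pair_i <- rep(seq_len(p), times = p)
  pair_j <- rep(seq_len(p), each = p)
  ZZw <- Z[, pair_i, drop = FALSE] * Z[, pair_j, drop = FALSE] * w
  S2 <- unname(revcumsum(rowsum(ZZw, grp)))      # nu x p^2
  d <- unname(rowsum(status, grp)[, 1L])
  Zev <- unname(rowsum(Z * status, grp))         # sum of Z over events at u
  eta_ev <- unname(rowsum(eta * status, grp)[, 1L])
  list(ug = ug, ri = ri, nu = nu, p = p, w = w, S0 = S0, S1 = S1, S2 = S2,
       d = d, Zev = Zev, eta_ev = eta_ev,
       pair_i = pair_i, pair_j = pair_j)
}

# log partial likelihood, score and information for one stratum
cox_stratum_lui <- function(st) {
  ev <- which(st$d > 0)
  p <- st$p
  if (!length(ev))
    return(list(ll = 0, U = numeric(p), I = matrix(0, p, p)))
  zbar <- st$S1 / st$S0
  ll <- sum(st$eta_ev[ev]) - sum(st$d[ev] * log(st$S0[ev]))
  U <- colSums(st$Zev[ev, , drop = FALSE]) -
    colSums(st$d[ev] * zbar[ev, , drop = FALSE])
  s2n <- st$S2[ev, , drop = FALSE] / st$S0[ev]
  zz <- zbar[ev, st$pair_i, drop = FALSE] * zbar[ev, st$pair_j, drop = FALSE]
  I <- matrix(colSums(st$d[ev] * (s2n - zz)), p, p)
  list(ll = ll, U = U, I = I)
}

cox_lui <- function(beta, strata_data) {
  p <- length(beta)
  ll <- 0; U <- numeric(p); I <- matrix(0, p, p)
  for (sd in strata_data) {
    st <- cox_stratum_stats(sd$gap, sd$status, sd$Z, drop(sd$Z %*% beta))
    comp <- cox_stratum_lui(st)
    ll <- ll + comp$ll; U <- U + comp$U; I <- I + comp$I
  }
  list(ll = ll, U = U, I = I)
}

#' Newton-Raphson control for the multiplicative gap-time fit
#'
#' @param tol convergence tolerance on the max absolute score component.
#' @param max_iter maximum Newton iterations.
#' @param beta_bound declare monotone-likelihood non-convergence when any
#'   coefficient exceeds this magnitude during iteration.
#' @param warn_bound warn when a fit formally converges (the score can vanish
#'   in the limit under perfect separation) but a coefficient magnitude
#'   exceeds this value, implausible for covariates on ordinary scales.
#' @return A list of class `"cox_gap_control"`.
#' @export
cox_gap_control <- function(tol = 1e-9, max_iter = 50L, beta_bound = 50,
                            warn_bound = 15) {
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 beta_bound = beta_bound, warn_bound = warn_bound),
            class = "cox_gap_control")
}

check_design_rank <- function(Z, covariates) {
  const <- vapply(seq_len(ncol(Z)), function(j) {
    v <- Z[, j]; all(v == v[1L])
  }, logical(1))
  if (any(const))
    stop("singular design: covariate '", covariates[which(const)[1L]],
         "' is constant")
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) {
    bad <- covariates[qz$pivot[(qz$rank + 1L):ncol(Z)]]
    stop("singular design: column(s) ", paste(bad, collapse = ", "),
         " linearly dependent on the others")
  }
  invisible(TRUE)
}

split_strata <- function(records, Z) {
  ks <- sort(unique(records$order_k))
  lapply(ks, function(k) {
    i <- which(records$order_k == k)
    list(order_k = k, gap = records$gap[i], status = records$status[i],
         Z = Z[i, , drop = FALSE], id = records$id[i])
  })
}

#' Fit the stratified multiplicative gap-time model
#'
#' Maximises the stratified partial likelihood of the conditional gap-time
#' model \eqn{\lambda_{ik}(t) = \lambda_{0k}(t) \exp(\beta' Z_{ik})} by
#' Newton-Raphson with step-halving, starting from \eqn{\beta = 0}, with
#' Breslow handling of tied gap times. Stratification is by event order
#' `order_k`, so each recurrence has its own baseline hazard and risk set on
#' the gap-time scale. With `effects = "common"` one coefficient vector is
#' shared across strata; with `effects = "order_specific"` the design is
#' expanded so each order gets its own coefficients (see
#' [expand_order_specific()]).
#'
#' Two variance estimates are returned: the naive inverse observed
#' information, valid only when all records are independent, and the robust
#' sandwich estimate \eqn{I^{-1}(\hat D' \hat D) I^{-1}}, where the rows of
#' \eqn{\hat D} are per-subject sums of score residuals across that subject's
#' records in all strata. The sandwich form remains valid under within-subject
#' correlation of gap times and is the one used for Wald inference in
#' [fit_table()].
#'
#' @param records gap-record data frame (see [build_gap_records()] /
#'   [read_gap_table()]).
#' @param spec a [design_spec()].
#' @param control a [cox_gap_control()].
#' @return An object of class `"cox_gap_fit"` with elements `coefficients`,
#'   `loglik` (at 0 and at the maximum), `information`, `naive_covariance`,
#'   `robust_covariance`, `score_residuals` (per-subject rows),
#'   `covariate_names`, `design`, `iterations`, `score_norm`, and per-stratum
#'   bookkeeping `strata` (records, events, risk-set size at time 0).
#' @examples
#' rec <- data.frame(id = letters[1:4], order_k = 1, gap = 1:4,
#'                   status = c(1, 1, 1, 0), z = c(1, 0, 1, 0))
#' fit <- fit_cox_gap(rec, design_spec("z", k_max = 1))
#' fit_table(fit)
#' @export
fit_cox_gap <- function(records, spec, control = cox_gap_control()) {
  des <- build_design(records, spec)
  Z <- des$Z
  covs <- des$covariates
  if (sum(des$records$status) < 1) stop("no events in the data")
  check_design_rank(Z, covs)
  strata_data <- split_strata(des$records, Z)
  p <- length(covs)

  beta <- numeric(p)
  cur <- cox_lui(beta, strata_data)
  ll0 <- cur$ll
  iter <- 0L
  repeat {
    if (max(abs(cur$U)) < control$tol) break
    if (iter >= control$max_iter)
      stop("Newton-Raphson did not converge in ", control$max_iter,
           " iterations (max |score| = ", format(max(abs(cur$U))), ")")
    step <- tryCatch(solve(cur$I, cur$U), error = function(e) {
      qi <- qr(cur$I)
      bad <- covs[qi$pivot[min(qi$rank + 1L, p)]]
      stop("singular information matrix (check covariate '", bad, "')",
           call. = FALSE)
    })
    new_beta <- beta + step
    new <- cox_lui(new_beta, strata_data)
    # halve only on a material decrease: near the optimum the log partial
    # likelihood is flat to rounding error and rejecting such steps stalls
    # the quadratic convergence of the score
    ll_slack <- 1e-10 * (abs(cur$ll) + 1)
    halvings <- 0L
    while ((!is.finite(new$ll) || new$ll < cur$ll - ll_slack) &&
           halvings < 30L) {
      step <- step / 2
      new_beta <- beta + step
      new <- cox_lui(new_beta, strata_data)
      halvings <- halvings + 1L
    }
    beta <- new_beta
    cur <- new
    iter <- iter + 1L
    # monotone-likelihood guard: past this magnitude the score equation has
    # no finite root worth reporting (perfect separation drives the score to
    # zero only as |beta| -> infinity)
    if (max(abs(beta)) > control$beta_bound)
      stop("monotone likelihood suspected: |beta| exceeded ",
           control$beta_bound,
           " (a covariate may perfectly separate events from censorings)")
  }

  if (max(abs(beta)) > control$warn_bound)
    warning("estimate on the boundary (|beta| > ", control$warn_bound,
            "): the partial likelihood may be monotone ",
            "(perfect separation); interpret with care")

  naive <- tryCatch(solve(cur$I), error = function(e)
    stop("information matrix not invertible at the optimum", call. = FALSE))
  naive <- (naive + t(naive)) / 2
  dimnames(naive) <- list(covs, covs)

  D <- cox_score_residual_matrix(beta, strata_data, des$records$id, p)
  colnames(D) <- covs
  robust <- naive %*% crossprod(D) %*% naive
  robust <- (robust + t(robust)) / 2

  strata_tab <- data.frame(
    order_k = vapply(strata_data, `[[`, numeric(1), "order_k"),
    n_records = vapply(strata_data, function(s) length(s$gap), numeric(1)),
    n_events = vapply(strata_data, function(s) sum(s$status), numeric(1))
  )

  structure(list(
    coefficients = setNames(beta, covs),
    loglik = c(null = ll0, maximum = cur$ll),
    information = structure(cur$I, dimnames = list(covs, covs)),
    naive_covariance = naive,
    robust_covariance = robust,
    score_residuals = D,
    covariate_names = covs,
    design = spec,
    iterations = iter,
    score_norm = max(abs(cur$U)),
    strata = strata_tab,
    n_subjects = length(unique(des$records$id)),
    n_records = nrow(des$records),
    n_events = sum(des$records$status)
  ), class = "cox_gap_fit")
}

# per-subject aggregated score residual matrix at beta
cox_score_residual_matrix <- function(beta, strata_data, ids, p) {
  uid <- unique(ids)
  D <- matrix(0, length(uid), p, dimnames = list(as.character(uid), NULL))
  for (sd in strata_data) {
    st <- cox_stratum_stats(sd$gap, sd$status, sd$Z, drop(sd$Z %*% beta))
    dS0 <- ifelse(st$d > 0, st$d / st$S0, 0)
    H <- cumsum(dS0)                               # Breslow cum. hazard at ug
    Q <- apply(st$S1 * (dS0 / st$S0), 2, cumsum)   # cum. of zbar * dLambda0
    Q <- matrix(Q, ncol = p)
    zbar <- st$S1 / st$S0
    li <- st$ri                                    # each record's grid index
    resid <- sd$status * (sd$Z - zbar[li, , drop = FALSE]) -
      st$w * (sd$Z * H[li] - Q[li, , drop = FALSE])
    agg <- rowsum(resid, factor(as.character(sd$id), levels = rownames(D)))
    D[rownames(agg), ] <- D[rownames(agg), , drop = FALSE] + agg
  }
  D
}

#' Per-subject score residuals of a fitted model
#'
#' For the multiplicative model these are the rows of the matrix \eqn{\hat D}
#' whose cross-product forms the middle of the sandwich variance: each
#' record's martingale-transform score residual
#' \eqn{\delta_{ik}\{Z_{ik} - \bar Z_k(G_{ik})\} -
#' \int_0^{G_{ik}} \{Z_{ik} - \bar Z_k(t)\} e^{\hat\beta' Z_{ik}}
#' d\hat\Lambda_{0k}(t)}, summed over the subject's records across all
#' strata. Columns sum to (numerically) zero at the maximum partial
#' likelihood estimate. For the additive model, the analogous per-subject
#' integrated residual scores \eqn{\int \{Z - \bar Z_k(t)\} d\hat M_{ik}(t)}.
#'
#' @param fit a fitted model object.
#' @param records the gap-record data frame the model was fitted to.
#' @return Numeric matrix, one row per subject, one column per coefficient.
#' @export
score_residuals <- function(fit, records) UseMethod("score_residuals")

#' @export
score_residuals.cox_gap_fit <- function(fit, records) {
  des <- build_design(records, fit$design)
  if (!identical(des$covariates, fit$covariate_names))
    stop("records are inconsistent with the fitted design")
  D <- cox_score_residual_matrix(fit$coefficients, split_strata(des$records,
                                                               des$Z),
                                 des$records$id, length(fit$covariate_names))
  colnames(D) <- fit$covariate_names
  D
}

#' @export
print.cox_gap_fit <- function(x, digits = 4, ...) {
  cat("Stratified multiplicative gap-time hazards model (",
      x$design$effects, " effects)\n", sep = "")
  cat("  ", x$n_subjects, " subjects, ", x$n_records, " records, ",
      x$n_events, " events in ", nrow(x$strata), " strata\n", sep = "")
  cat("  log partial likelihood: ", format(x$loglik[["maximum"]],
                                           digits = digits),
      " (", x$iterations, " iterations, max |score| = ",
      format(x$score_norm, digits = 3), ")\n\n", sep = "")
  print(fit_table(x), digits = digits, row.names = FALSE)
  invisible(x)
}

#' Breslow cumulative baseline hazard of a stratum
#'
#' Estimates the cumulative baseline hazard of event order `order_k` on the
#' gap-time scale, \eqn{\hat\Lambda_{0k}(t) = \sum_{g \le t} d_k(g) /
#' \sum_{j \in R_k(g)} e^{\hat\beta' Z_j}}, a nondecreasing right-continuous
#' step function with \eqn{\hat\Lambda_{0k}(0) = 0}.
#'
#' @param fit a `"cox_gap_fit"`.
#' @param records the gap-record data frame the model was fitted to.
#' @param order_k stratum (event order) to estimate.
#' @param coefficients optional coefficient vector overriding the fitted one
#'   (forcing 0 reduces the estimator exactly to Nelson-Aalen).
#' @return An object of class `"gap_baseline"` with `times`, `increments`,
#'   `cumhaz` and the model tag.
#' @export
breslow_baseline <- function(fit, records, order_k, coefficients = NULL) {
  stopifnot(inherits(fit, "cox_gap_fit"))
  des <- build_design(records, fit$design)
  if (!identical(des$covariates, fit$covariate_names))
    stop("records are inconsistent with the fitted design")
  i <- which(des$records$order_k == order_k)
  if (!length(i)) {
    warning("stratum ", order_k, " is empty; returning empty baseline")
    return(structure(list(order_k = order_k, times = numeric(0),
                          increments = numeric(0), cumhaz = numeric(0),
                          model = "multiplicative"),
                     class = "gap_baseline"))
  }
  beta <- if (is.null(coefficients)) fit$coefficients
          else rep_len(coefficients, ncol(des$Z))
  Z <- des$Z[i, , drop = FALSE]
  st <- cox_stratum_stats(des$records$gap[i], des$records$status[i], Z,
                          drop(Z %*% beta))
  ev <- which(st$d > 0)
  if (!length(ev))
    warning("stratum ", order_k, " has no events; baseline is identically 0")
  inc <- st$d[ev] / st$S0[ev]
  structure(list(order_k = order_k, times = st$ug[ev], increments = inc,
                 cumhaz = cumsum(inc), model = "multiplicative"),
            class = "gap_baseline")
}

#' Evaluate a cumulative baseline hazard
#'
#' Right-continuous evaluation of \eqn{\hat\Lambda_{0k}(t)}. Multiplicative
#' baselines are step functions; additive baselines are step-plus-drift
#' (event-count jumps minus the integrated regression drift) and need not be
#' monotone. Evaluation beyond the last observed gap in the stratum is
#' clamped there, with a warning (no extrapolation).
#'
#' @param baseline a `"gap_baseline"` or `"additive_gap_baseline"`.
#' @param times numeric vector of gap times.
#' @return Numeric vector of cumulative hazard values.
#' @export
cumhaz_at <- function(baseline, times) UseMethod("cumhaz_at")

#' @export
cumhaz_at.gap_baseline <- function(baseline, times) {
  if (!length(baseline$times)) return(rep(0, length(times)))
  idx <- findInterval(times, baseline$times)
  c(0, baseline$cumhaz)[idx + 1L]
}

#' Predicted survival curve from a fitted model
#'
#' Multiplicative model: \eqn{S(t \mid z) = \exp\{-\hat\Lambda_{0k}(t)
#' e^{\hat\beta' z}\}}, a nonincreasing step function with \eqn{S(0) = 1}.
#' Additive model: \eqn{S(t \mid z) = \exp\{-\hat\Lambda_{0k}(t) -
#' \hat\beta' z \, t\}}; because the additive estimator does not constrain
#' fitted hazards to be nonnegative, the raw curve can exceed 1 or rise, so a
#' monotone-corrected version (running minimum, clipped to `[0, 1]`) is
#' returned alongside and a warning is emitted when the two differ.
#'
#' @param fit a fitted model object.
#' @param baseline the matching stratum baseline ([breslow_baseline()] or
#'   [additive_baseline()]).
#' @param z named numeric vector of covariate values on the original
#'   (unexpanded) covariates of the design.
#' @param times gap times at which to evaluate; defaults to the baseline's
#'   jump grid.
#' @return A data frame with columns `time`, `survival` and, for the additive
#'   model, `survival_raw` (uncorrected) alongside the monotone-corrected
#'   `survival`.
#' @export
predict_survival <- function(fit, baseline, z, times = NULL)
  UseMethod("predict_survival")

# linear predictor for a baseline's stratum given base-covariate values
stratum_lp <- function(fit, z, order_k) {
  spec <- fit$design
  miss <- setdiff(spec$covariates, names(z))
  if (length(miss))
    stop("missing covariate value(s): ", paste(miss, collapse = ", "))
  if (spec$effects == "common") {
    sum(fit$coefficients[spec$covariates] * z[spec$covariates])
  } else {
    nm <- paste0(spec$covariates, order_k)
    sum(fit$coefficients[nm] * z[spec$covariates])
  }
}

#' @export
predict_survival.cox_gap_fit <- function(fit, baseline, z, times = NULL) {
  stopifnot(inherits(baseline, "gap_baseline"))
  if (is.null(times)) times <- c(0, baseline$times)
  lp <- stratum_lp(fit, z, baseline$order_k)
  if (length(baseline$times) && any(times > max(baseline$times)))
    warning("times beyond the last observed gap are clamped there")
  ch <- cumhaz_at(baseline, times)
  data.frame(time = times, survival = exp(-ch * exp(lp)))
}
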