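# Shared fixtures and independent oracles.
#
# The oracles deliberately avoid the package's fitting code paths: they
# evaluate the printed estimating quantities by direct arithmetic (or 1-D
# numeric maximisation) so that agreement is a genuine cross-check.

# four single-order records with a binary covariate; events at gaps 1, 2, 3
# and one censored record at gap 4
fixture_f1 <- function() {
  data.frame(id = c("a", "b", "c", "d"), order_k = 1, gap = c(1, 2, 3, 4),
             status = c(1, 1, 1, 0), z = c(1, 0, 1, 0),
             stringsAsFactors = FALSE)
}

# log partial likelihood of fixture F1, written out term by term from the
# risk sets: {a,b,c,d} at gap 1, {b,c,d} at gap 2, {c,d} at gap 3
f1_cox_loglik <- function(b) {
  (b - log(2 * exp(b) + 2)) + (0 - log(exp(b) + 2)) + (b - log(exp(b) + 1))
}

# independent 1-D maximiser of the F1 partial likelihood
f1_cox_oracle_beta <- function() {
  optimize(f1_cox_loglik, c(-10, 10), maximum = TRUE, tol = 1e-12)$maximum
}

# central finite-difference second derivative (observed information oracle)
f1_cox_oracle_information <- function(beta, h = 1e-5) {
  -(f1_cox_loglik(beta + h) - 2 * f1_cox_loglik(beta) +
      f1_cox_loglik(beta - h)) / h^2
}

# direct arithmetic evaluation of the additive estimating sums on F1.
# Grid of distinct gaps 1,2,3,4 with unit spacing; risk sets
# {a,b,c,d}, {b,c,d}, {c,d}, {d} with z-means 1/2, 1/3, 1/2, 0.
f1_additive_oracle <- function() {
  z <- c(a = 1, b = 0, c = 1, d = 0)
  risk <- list(c("a", "b", "c", "d"), c("b", "c", "d"), c("c", "d"), "d")
  delta_t <- c(1, 1, 1, 1)
  events <- list(`1` = "a", `2` = "b", `3` = "c")  # gap value -> event id
  A_raw <- 0
  b_vec <- 0
  for (l in 1:4) {
    zr <- z[risk[[l]]]
    A_raw <- A_raw + delta_t[l] * sum((zr - mean(zr))^2)
    ev <- events[[as.character(l)]]
    if (!is.null(ev)) b_vec <- b_vec + (z[[ev]] - mean(zr))
  }
  list(beta = b_vec / A_raw, A_raw = A_raw, b = b_vec)
}

# random tie-free single-order fixture: continuous gaps, one binary and one
# continuous covariate, roughly 30% censoring
random_k1_records <- function(n, seed) {
  set.seed(seed)
  z1 <- rbinom(n, 1, 0.5)
  z2 <- rnorm(n)
  gap <- rexp(n, rate = exp(0.5 * z1 - 0.3 * z2) * 0.5)
  cens <- rexp(n, rate = 0.2)
  data.frame(id = sprintf("r%04d", seq_len(n)), order_k = 1,
             gap = pmin(gap, cens), status = as.numeric(gap <= cens),
             z1 = z1, z2 = z2, stringsAsFactors = FALSE)
}

# small multi-order cohort records for structural tests
small_cohort_records <- function(n = 150, seed = 1, k_max = 4,
                                 frailty_variance = 0.25) {
  cfg <- sim_config(n, k_max = k_max, frailty_variance = frailty_variance)
  build_gap_records(simulate_cohort(cfg, seed = seed), k_max = k_max)
}

# Nelson-Aalen cumulative hazard by direct tabulation (independent of the
# package's baseline code): increments d(t) / #{gap >= t} at event gaps
nelson_aalen_direct <- function(gap, status) {
  tt <- sort(unique(gap[status == 1]))
  inc <- vapply(tt, function(g) sum(status == 1 & gap == g) / sum(gap >= g),
                numeric(1))
  list(times = tt, cumhaz = cumsum(inc))
}
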