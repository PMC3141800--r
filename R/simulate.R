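# Gamma-frailty synthetic cohort generator.
#
# Emulates the structure of a pediatric ED-revisit cohort: per-subject binary
# sex-, race- and guardian-like covariates and an integer age-like covariate;
# up to k_max analysed event orders; within-subject positive correlation of
# gap times through a mean-1 gamma frailty; and a single per-subject
# right-censoring time on the total-time scale, which induces dependent
# censoring of the later gaps.

default_covariate_generators <- function() {
  list(sex = list(type = "binary", prob = 0.85),
       race = list(type = "binary", prob = 0.70),
       parent = list(type = "binary", prob = 0.55),
       age = list(type = "integer", min = 5, max = 18))
}

#' Configuration of the synthetic recurrent-event cohort
#'
#' Defines the data-generating process: constant per-order baseline hazards
#' \eqn{\lambda_{0k}} on the gap-time scale, a true coefficient vector acting
#' multiplicatively (\eqn{w_i \lambda_{0k} e^{\beta' z}}) or additively
#' (\eqn{w_i (\lambda_{0k} + \beta' z)}) on them, a mean-1 gamma frailty
#' \eqn{w_i} with variance `frailty_variance` shared by all of a subject's
#' gaps, and a per-subject censoring time drawn uniformly on
#' `[0, censor_max]` applied on the total-time scale. The defaults emulate
#' the scale of a pediatric firearm-injury ED revisit cohort: mostly male,
#' majority black, about half with a parent as guardian, ages 5-18, baseline
#' revisit rates rising with event order, follow-up of a few years, and
#' roughly half the subjects experiencing no revisit.
#'
#' @param n_subjects number of subjects.
#' @param k_max maximum analysed event order.
#' @param truth_model `"multiplicative"` or `"additive"`.
#' @param coefficients named true coefficient vector over the generated
#'   covariates (defaults depend on `truth_model`).
#' @param baseline_rates per-order constant baseline hazards, recycled (last
#'   value reused) beyond their length.
#' @param frailty_variance gamma frailty variance \eqn{\sigma^2 \ge 0}
#'   (0 switches the frailty off, making gaps conditionally independent).
#' @param censor_max upper end of the uniform total-time censoring
#'   distribution (same time unit as the baseline rates).
#' @param covariates named list of covariate generators, each
#'   `list(type = "binary", prob = )` or `list(type = "integer", min =, max = )`.
#' @param seed default random seed used by [simulate_cohort()] when none is
#'   passed there.
#' @return An object of class `"sim_config"`. Additive configurations are
#'   validated so that \eqn{\lambda_{0k} + \beta' z \ge 0} over the whole
#'   covariate support.
#' @examples
#' cfg <- sim_config(n_subjects = 50, seed = 1)
#' cohort <- simulate_cohort(cfg)
#' summarize_events(cohort)
#' @export
sim_config <- function(n_subjects,
                       k_max = 4L,
                       truth_model = c("multiplicative", "additive"),
                       coefficients = NULL,
                       baseline_rates = c(0.25, 0.30, 0.35, 0.38),
                       frailty_variance = 0.25,
                       censor_max = 6.4,
                       covariates = default_covariate_generators(),
                       seed = NULL) {
  truth_model <- match.arg(truth_model)
  if (is.null(coefficients)) {
    coefficients <- if (truth_model == "multiplicative")
      c(sex = -0.654, race = 0.335, age = 0.043, parent = 0.152)
    else
      c(sex = -0.152, race = 0.058, age = 0.009, parent = 0.033)
    coefficients <- coefficients[intersect(names(coefficients),
                                           names(covariates))]
  }
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 1L) stop("'n_subjects' must be >= 1")
  if (any(baseline_rates <= 0)) stop("baseline rates must be positive")
  if (frailty_variance < 0) stop("'frailty_variance' must be >= 0")
  if (censor_max <= 0) stop("'censor_max' must be positive")
  if (length(coefficients) &&
      (is.null(names(coefficients)) ||
       !all(names(coefficients) %in% names(covariates))))
    stop("'coefficients' must be named after generated covariates")
  for (nm in names(covariates)) {
    g <- covariates[[nm]]
    if (!g$type %in% c("binary", "integer"))
      stop("covariate '", nm, "': unknown generator type '", g$type, "'")
    if (g$type == "binary" && (g$prob < 0 || g$prob > 1))
      stop("covariate '", nm, "': probability outside [0, 1]")
    if (g$type == "integer" && g$min > g$max)
      stop("covariate '", nm, "': min > max")
  }
  cfg <- structure(list(n_subjects = n_subjects, k_max = as.integer(k_max),
                        truth_model = truth_model,
                        coefficients = coefficients,
                        baseline_rates = baseline_rates,
                        frailty_variance = frailty_variance,
                        censor_max = censor_max, covariates = covariates,
                        seed = seed),
                   class = "sim_config")
  if (truth_model == "additive") {
    lo <- sum(vapply(names(coefficients), function(nm) {
      g <- covariates[[nm]]; b <- coefficients[[nm]]
      rng <- if (g$type == "binary") c(0, 1) else c(g$min, g$max)
      min(b * rng)
    }, numeric(1)))
    if (any(baseline_rates + lo < 0))
      stop("additive truth reaches a negative hazard over the covariate ",
           "support (min baseline + worst-case beta'z = ",
           format(min(baseline_rates) + lo), "); raise the baseline rates ",
           "or shrink the coefficients")
  }
  cfg
}

# latent event orders drawn per subject; follow-up ending before this many
# events is overwhelmingly certain for any realistic configuration
.N_LATENT_GAPS <- 100L

draw_covariates <- function(generators) {
  vapply(generators, function(g) {
    switch(g$type,
           binary = rbinom(1L, 1L, g$prob),
           integer = sample(seq(g$min, g$max), 1L))
  }, numeric(1))
}

#' Simulate a recurrent-event cohort
#'
#' Generates subject histories under the process described in
#' [sim_config()]: per subject, covariates are drawn, a gamma frailty
#' \eqn{w_i} (mean 1, variance \eqn{\sigma^2}) is drawn, successive latent
#' gap times are exponential with hazard \eqn{w_i \lambda_{0k}
#' e^{\beta' z_i}} (multiplicative truth) or \eqn{w_i (\lambda_{0k} +
#' \beta' z_i)} (additive truth), and a single censoring time
#' \eqn{C_i \sim U(0, c_{\max})} truncates the event sequence on the
#' total-time scale. Subjects are simulated in order from a single seeded
#' stream, so the same seed and configuration reproduce the cohort exactly.
#'
#' @param config a [sim_config()].
#' @param seed overrides `config$seed`; one of the two must be set for
#'   reproducibility (if both are `NULL` the current RNG state is used).
#' @return An object of class `"simulated_cohort"`: a list with `histories`
#'   (subject histories, each carrying its latent `frailty` and latent
#'   uncensored `latent_gaps` for oracle checks) and `config`. Pass it (or
#'   its `histories`) to [build_gap_records()].
#' @export
simulate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) seed <- config$seed
  if (!is.null(seed)) set.seed(seed)
  sigma2 <- config$frailty_variance
  histories <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    z <- draw_covariates(config$covariates)
    w <- if (sigma2 > 0) rgamma(1L, shape = 1 / sigma2, scale = sigma2) else 1
    C <- runif(1L, 0, config$censor_max)
    bz <- sum(config$coefficients * z[names(config$coefficients)])
    # fixed-length latent sequence: the censoring transform then selects the
    # observed prefix, so observed histories are a deterministic transform of
    # the latent ones and the random stream stays aligned across censoring
    # configurations (stricter censoring can only remove events)
    ks <- seq_len(.N_LATENT_GAPS)
    lam0 <- config$baseline_rates[pmin(ks, length(config$baseline_rates))]
    rate <- if (config$truth_model == "multiplicative")
      w * lam0 * exp(bz) else w * (lam0 + bz)
    latent <- rexp(.N_LATENT_GAPS, pmax(rate, 1e-300))
    lat_times <- cumsum(latent)
    observed <- lat_times[lat_times <= C]
    h <- subject_history(sprintf("s%06d", i), observed, C, z)
    h$frailty <- w
    h$latent_gaps <- latent
    class(h) <- c("simulated_history", "subject_history")
    histories[[i]] <- h
  }
  structure(list(histories = histories, config = config),
            class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat("Simulated recurrent-event cohort: ", length(x$histories),
      " subjects (", x$config$truth_model, " truth, frailty variance ",
      x$config$frailty_variance, ")\n", sep = "")
  print(summarize_events(x))
  invisible(x)
}

#' Tabulate subjects by number of observed events
#'
#' The standard first look at a recurrent-event cohort: how many subjects
#' experienced 0, 1, 2, ... events during follow-up, with percentages and a
#' total row.
#'
#' @param histories a list of [subject_history()] objects or a
#'   `"simulated_cohort"`.
#' @return A data frame with columns `n_events`, `n_subjects`, `percent`;
#'   the last row is the total.
#' @export
summarize_events <- function(histories) {
  if (inherits(histories, "simulated_cohort")) histories <- histories$histories
  counts <- vapply(histories, function(h) length(h$event_times), numeric(1))
  lev <- 0:max(counts, 0)
  tab <- table(factor(counts, levels = lev))
  n <- length(histories)
  out <- data.frame(n_events = c(as.character(lev), "total"),
                    n_subjects = c(as.integer(tab), n),
                    percent = round(100 * c(as.integer(tab), n) / n, 1),
                    stringsAsFactors = FALSE)
  out
}

#' Kendall's tau implied by a gamma frailty
#'
#' For gap times that share a mean-1 gamma frailty with variance
#' \eqn{\sigma^2} (and are otherwise independent exponentials), the joint
#' distribution is a Clayton copula and the Kendall rank correlation between
#' any two of a subject's gap times is \eqn{\sigma^2 / (\sigma^2 + 2)}.
#' Useful as a closed-form oracle for the dependence the simulator injects.
#'
#' @param frailty_variance gamma frailty variance \eqn{\sigma^2 \ge 0}.
#' @return Kendall's tau in `[0, 1)`.
#' @export
frailty_kendall_tau <- function(frailty_variance) {
  stopifnot(frailty_variance >= 0)
  frailty_variance / (frailty_variance + 2)
}
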