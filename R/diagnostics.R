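# Model-adequacy outputs: per-record martingale and deviance residuals and
# Arjas-style observed-vs-expected cumulative diagnostics, for both hazard
# frameworks.

# per-record estimated cumulative intensity Lambda_hat_ik at the record's gap
record_cum_intensity <- function(fit, records) {
  des <- build_design(records, fit$design)
  if (!identical(des$covariates, fit$covariate_names))
    stop("records are inconsistent with the fitted design")
  out <- numeric(nrow(des$records))
  for (k in sort(unique(des$records$order_k))) {
    i <- which(des$records$order_k == k)
    if (inherits(fit, "cox_gap_fit")) {
      bl <- breslow_baseline(fit, records, k)
      lp <- drop(des$Z[i, , drop = FALSE] %*% fit$coefficients)
      out[i] <- cumhaz_at(bl, des$records$gap[i]) * exp(lp)
    } else {
      bl <- additive_baseline(fit, records, k)
      lp <- drop(des$Z[i, , drop = FALSE] %*% fit$coefficients)
      out[i] <- cumhaz_at(bl, des$records$gap[i]) + lp * des$records$gap[i]
    }
  }
  out
}

#' Martingale and deviance residuals
#'
#' Per-record martingale residuals \eqn{\hat M_{ik} = \delta_{ik} -
#' \hat\Lambda_{ik}(G_{ik})}, where the estimated cumulative intensity is
#' \eqn{\hat\Lambda_{0k}(G_{ik}) e^{\hat\beta' Z_{ik}}} for the
#' multiplicative model and \eqn{\hat\Lambda_{0k}(G_{ik}) + \hat\beta' Z_{ik}
#' G_{ik}} for the additive model. Under the multiplicative model with its
#' Breslow baseline the residuals sum to zero over all records, and the sum
#' of estimated intensities equals the observed event total (the conservation
#' identity that anchors the Arjas diagnostic). Deviance residuals are the
#' variance-stabilising transform computed by [deviance_residuals()].
#'
#' @param fit a `"cox_gap_fit"` or `"ly_additive_fit"`.
#' @param records the gap-record data frame the model was fitted to.
#' @return An object of class `"gap_residuals"`: a data frame with columns
#'   `id`, `order_k`, `gap`, `status`, `cum_intensity`, `martingale`,
#'   `deviance`, carrying the model tag in `attr(, "model")` and the
#'   per-subject aggregated martingale residuals in `attr(, "subject_totals")`.
#' @export
martingale_residuals <- function(fit, records) {
  model <- if (inherits(fit, "cox_gap_fit")) "multiplicative"
           else if (inherits(fit, "ly_additive_fit")) "additive"
           else stop("'fit' must be a cox_gap_fit or ly_additive_fit")
  lam <- record_cum_intensity(fit, records)
  m <- records$status - lam
  out <- data.frame(id = records$id, order_k = records$order_k,
                    gap = records$gap, status = records$status,
                    cum_intensity = lam, martingale = m,
                    stringsAsFactors = FALSE)
  # the additive model can legitimately produce event records with
  # cum_intensity < 0 (negative fitted hazard); their deviance transform is
  # undefined, so mark them NA rather than fail the whole residual set
  bad <- out$status == 1 & out$martingale > 1
  if (any(bad)) {
    warning(sum(bad), " event record(s) with negative estimated cumulative ",
            "intensity; deviance residual set to NA for those")
    out$deviance <- NA_real_
    out$deviance[!bad] <- deviance_residuals(out[!bad, , drop = FALSE])
  } else {
    out$deviance <- deviance_residuals(out)
  }
  subj <- rowsum(m, records$id)
  attr(out, "model") <- model
  attr(out, "subject_totals") <- setNames(subj[, 1L], rownames(subj))
  class(out) <- c("gap_residuals", "data.frame")
  out
}

#' Deviance transform of martingale residuals
#'
#' \eqn{d = \mathrm{sign}(\hat M) \sqrt{-2[\hat M + \delta \log(\delta -
#' \hat M)]}}, with the log term omitted for censored records
#' (\eqn{\delta = 0}). The transform is sign-preserving and strictly
#' increasing in \eqn{|\hat M|} on each status branch; it symmetrises the
#' skewed martingale residuals for plotting.
#'
#' @param residuals a `"gap_residuals"` object or any data frame with
#'   `martingale` and `status` columns.
#' @param tol negative square-root arguments beyond this tolerance raise an
#'   error (they indicate inconsistent inputs, e.g. an event record with
#'   \eqn{\hat M > 1}).
#' @return Numeric vector of per-record deviance residuals.
#' @export
deviance_residuals <- function(residuals, tol = 1e-8) {
  m <- residuals$martingale
  d <- residuals$status
  if (any(d == 1 & m > 1 + tol))
    stop("event record with martingale residual > 1: inconsistent inputs")
  arg <- -2 * (m + ifelse(d == 1, log(pmax(d - m, 0)), 0))
  if (any(arg < -tol))
    stop("negative deviance argument beyond tolerance: inconsistent inputs")
  sign(m) * sqrt(pmax(arg, 0))
}

#' Arjas-style observed-versus-expected diagnostic data
#'
#' Within each covariate group, records are ordered by their estimated
#' cumulative intensity and the running totals of observed events and of
#' summed model-estimated cumulative intensities are accumulated. Plotting
#' cumulative observed against cumulative expected gives the Arjas
#' diagnostic: a well-fitting model tracks the 45-degree line. For the
#' multiplicative model with its Breslow baseline, the overall endpoint
#' satisfies (total expected) = (total observed) exactly.
#'
#' @param fit a fitted model object.
#' @param records the gap-record data frame the model was fitted to.
#' @param group either the name of a covariate column in `records` (grouping
#'   by its distinct levels) or a vector with one group label per record;
#'   `NULL` puts everyone in one group.
#' @return A data frame with columns `group`, `rank`, `cum_observed`,
#'   `cum_expected`.
#' @export
arjas_data <- function(fit, records, group = NULL) {
  lam <- record_cum_intensity(fit, records)
  g <- if (is.null(group)) rep("all", nrow(records))
       else if (is.character(group) && length(group) == 1L) {
         if (!group %in% names(records))
           stop("grouping column not in records: ", group)
         as.character(records[[group]])
       } else {
         if (length(group) != nrow(records))
           stop("'group' must name a column or give one label per record")
         as.character(group)
       }
  parts <- lapply(split(seq_len(nrow(records)), g), function(idx) {
    o <- idx[order(lam[idx])]
    data.frame(group = g[o[1L]], rank = seq_along(o),
               cum_observed = cumsum(records$status[o]),
               cum_expected = cumsum(lam[o]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
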