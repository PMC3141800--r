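#' Subject-level recurrent event history
#'
#' Raw input form of one subject's observed event history: the ordered event
#' times on the time-since-enrollment scale, the end of follow-up, and the
#' baseline (time-fixed) covariates.
#'
#' @param id subject identifier (any atomic scalar).
#' @param event_times numeric vector of event times since enrollment, strictly
#'   increasing, possibly empty; every event time must be `<= followup_end`.
#' @param followup_end nonnegative time at which observation stops (the
#'   right-censoring time when it exceeds the last event).
#' @param covariates named numeric vector of baseline covariates.
#' @return An object of class `"subject_history"`.
#' @examples
#' subject_history("s1", c(2, 5, 6), 10, c(sex = 1, age = 14))
#' @export
subject_history <- function(id, event_times, followup_end, covariates) {
  event_times <- as.numeric(event_times)
  followup_end <- as.numeric(followup_end)
  if (length(id) != 1L) stop("'id' must be a scalar")
  if (length(followup_end) != 1L || is.na(followup_end) || followup_end < 0)
    stop("subject ", id, ": 'followup_end' must be a nonnegative scalar")
  if (anyNA(event_times) || any(event_times < 0))
    stop("subject ", id, ": event times must be nonnegative")
  if (length(event_times) > 1L && any(diff(event_times) <= 0))
    stop("subject ", id, ": event times must be strictly increasing")
  if (length(event_times) && max(event_times) > followup_end)
    stop("subject ", id, ": event time exceeds followup_end")
  if (length(covariates)) {
    covariates <- unlist(covariates)
    if (is.null(names(covariates)) || any(!nzchar(names(covariates))))
      stop("subject ", id, ": covariates must be named")
    if (anyNA(covariates))
      stop("subject ", id, ": missing covariate values are not allowed")
  }
  structure(
    list(id = id, event_times = event_times, followup_end = followup_end,
         covariates = covariates),
    class = "subject_history"
  )
}

#' @export
print.subject_history <- function(x, ...) {
  cat("Subject", format(x$id), "-", length(x$event_times), "event(s),",
      "follow-up end", format(x$followup_end), "\n")
  if (length(x$event_times))
    cat("  event times:", paste(format(x$event_times), collapse = ", "), "\n")
  if (length(x$covariates))
    cat("  covariates: ",
        paste(names(x$covariates), format(x$covariates), sep = "=",
              collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Design specification for a gap-time hazards fit
#'
#' Describes which covariates enter the linear predictor, whether their
#' effects are shared across event orders (`"common"`) or estimated separately
#' per order (`"order_specific"`, implemented by covariate-by-order
#' interaction columns), and the maximum event order retained.
#'
#' @param covariates character vector of covariate column names.
#' @param effects `"common"` for one coefficient per covariate across all
#'   orders, or `"order_specific"` for a distinct coefficient per order.
#' @param k_max maximum event order (stratum) retained, an integer `>= 1`.
#' @return An object of class `"design_spec"`.
#' @examples
#' design_spec(c("sex", "race", "age"), effects = "common", k_max = 4)
#' @export
design_spec <- function(covariates, effects = c("common", "order_specific"),
                        k_max = 4L) {
  effects <- match.arg(effects)
  covariates <- as.character(covariates)
  if (!length(covariates) || anyNA(covariates) || any(!nzchar(covariates)))
    stop("'covariates' must be a non-empty character vector")
  if (anyDuplicated(covariates))
    stop("duplicated covariate names: ",
         paste(unique(covariates[duplicated(covariates)]), collapse = ", "))
  k_max <- as.integer(k_max)
  if (length(k_max) != 1L || is.na(k_max) || k_max < 1L)
    stop("'k_max' must be an integer >= 1")
  structure(list(covariates = covariates, effects = effects, k_max = k_max),
            class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  cat("Design: ", x$effects, " effects, k_max = ", x$k_max,
      "\n  covariates: ", paste(x$covariates, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# column names a gap-record table must carry besides covariates
.GAP_CORE_COLS <- c("id", "order_k", "gap", "status")

# Validate a long-format gap-record table. Checks the per-subject run
# structure (orders 1..m with no holes, at most one censored record and it is
# the last) and, when 'covariates' is given, presence and completeness of
# those columns. Returns the table invisibly.
validate_gap_records <- function(records, covariates = NULL,
                                 require_contiguous = TRUE) {
  if (!is.data.frame(records) || !nrow(records))
    stop("'records' must be a non-empty data frame of gap records")
  missing_cols <- setdiff(.GAP_CORE_COLS, names(records))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  if (!is.numeric(records$gap) || anyNA(records$gap))
    stop("'gap' must be numeric with no missing values")
  if (anyNA(records$status) || !all(records$status %in% c(0, 1)))
    stop("'status' must be coded 0/1")
  if (anyNA(records$order_k) || any(records$order_k < 1) ||
      any(records$order_k != round(records$order_k)))
    stop("'order_k' must contain integers >= 1")
  if (any(records$gap < 0))
    stop("negative gap times are not allowed")
  if (any(records$gap <= 0 & records$status == 1))
    stop("event records must have gap > 0")
  if (anyDuplicated(records[c("id", "order_k")]))
    stop("duplicate (subject, order) pairs present")
  if (require_contiguous) {
    by_id <- split(seq_len(nrow(records)), records$id)
    for (idx in by_id) {
      ks <- sort(records$order_k[idx])
      if (!identical(as.integer(ks), seq_len(length(ks))))
        stop("subject ", records$id[idx[1L]],
             ": event orders must run 1..m with no holes")
      cens <- idx[records$status[idx] == 0]
      if (length(cens) > 1L)
        stop("subject ", records$id[idx[1L]],
             ": more than one censored record")
      if (length(cens) == 1L &&
          records$order_k[cens] != max(records$order_k[idx]))
        stop("subject ", records$id[idx[1L]],
             ": censored record is not the last order")
    }
  }
  if (!is.null(covariates)) {
    miss <- setdiff(covariates, names(records))
    if (length(miss))
      stop("covariate column(s) not in data: ", paste(miss, collapse = ", "))
    for (cn in covariates) {
      if (!is.numeric(records[[cn]]))
        stop("covariate '", cn, "' must be numeric")
      if (anyNA(records[[cn]]))
        stop("covariate '", cn, "' has missing values; ",
             "records with missing covariates are rejected")
    }
  }
  invisible(records)
}

#' Build gap-time records from subject histories
#'
#' Converts subject-level event histories into the long counting-process
#' format used by all fitting functions: one row per (subject, event order),
#' where each order resets the clock to zero, so order `k` contributes the
#' interval `(0, T_k - T_{k-1}]`. A subject with `m` observed events (after
#' truncation at `k_max`) contributes `m` event records; if `m < k_max` and
#' follow-up extends strictly beyond the last event, one final censored record
#' with the residual gap is added at order `m + 1`. Subjects censored before
#' reaching order `k` are absent from stratum `k` entirely, which is what
#' makes the per-stratum risk sets shrink with `k`.
#'
#' @param histories a list of [subject_history()] objects (a
#'   `"simulated_cohort"` is accepted and its observed histories used).
#' @param k_max maximum event order retained; events beyond it are dropped and
#'   no censored record is emitted past it.
#' @return A data frame with columns `id`, `order_k`, `gap`, `status` and one
#'   column per covariate.
#' @examples
#' h <- subject_history("s1", c(2, 5, 6), 10, c(sex = 1))
#' build_gap_records(list(h), k_max = 4)
#' @export
build_gap_records <- function(histories, k_max = 4L) {
  if (inherits(histories, "simulated_cohort")) histories <- histories$histories
  if (inherits(histories, "subject_history")) histories <- list(histories)
  if (!length(histories)) stop("'histories' is empty")
  k_max <- as.integer(k_max)
  if (k_max < 1L) stop("'k_max' must be >= 1")
  rows <- lapply(histories, function(h) {
    if (!inherits(h, "subject_history"))
      stop("'histories' must contain subject_history objects")
    ev <- h$event_times
    m <- min(length(ev), k_max)
    gaps <- if (m) diff(c(0, ev[seq_len(m)])) else numeric(0)
    status <- rep(1, m)
    # residual censored interval at order m+1, only when the subject has not
    # reached k_max events and follow-up extends strictly past the last event
    # (zero-length censored records carry no information); a zero-event
    # subject always contributes its single censored record
    last_t <- if (m) ev[m] else 0
    if (length(ev) < k_max && (m == 0L || h$followup_end > last_t)) {
      gaps <- c(gaps, h$followup_end - last_t)
      status <- c(status, 0)
    }
    if (!length(gaps)) return(NULL)
    out <- data.frame(id = rep(h$id, length(gaps)),
                      order_k = seq_along(gaps),
                      gap = gaps, status = status,
                      stringsAsFactors = FALSE)
    for (cn in names(h$covariates)) out[[cn]] <- unname(h$covariates[[cn]])
    out
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no usable records (all histories empty)")
  rec <- do.call(rbind, rows)
  rownames(rec) <- NULL
  # a subject with zero events and followup_end == 0 would yield a gap-0
  # censored record; keep it (it is at risk for no time and never counts)
  validate_gap_records(rec)
  rec
}

#' Expand covariates into order-specific interaction columns
#'
#' Replaces each covariate column `z` by `k_max` columns `z1..z<k_max>` with
#' `zj = z * I(order_k == j)`, the standard device for fitting one coefficient
#' per event order in a single stratified model. Original columns are removed;
#' the number of records is unchanged.
#'
#' @param records gap-record data frame (see [build_gap_records()]).
#' @param spec a [design_spec()] with `effects = "order_specific"`.
#' @return The expanded data frame; the new covariate names (in fitting
#'   order: covariate-major, order-minor) are in `attr(, "expanded_covariates")`.
#' @examples
#' rec <- data.frame(id = "a", order_k = 2, gap = 1, status = 1, guard = 1)
#' expand_order_specific(rec, design_spec("guard", "order_specific", k_max = 4))
#' @export
expand_order_specific <- function(records, spec) {
  stopifnot(inherits(spec, "design_spec"))
  if (spec$effects != "order_specific")
    stop("expansion requires effects = 'order_specific'")
  validate_gap_records(records, spec$covariates, require_contiguous = FALSE)
  if (any(records$order_k > spec$k_max))
    stop("record with order_k > k_max (", spec$k_max, ") present")
  out <- records[setdiff(names(records), spec$covariates)]
  new_names <- character(0)
  for (cn in spec$covariates) {
    for (j in seq_len(spec$k_max)) {
      nm <- paste0(cn, j)
      out[[nm]] <- records[[cn]] * as.numeric(records$order_k == j)
      new_names <- c(new_names, nm)
    }
  }
  attr(out, "expanded_covariates") <- new_names
  out
}

# design matrix + effective covariate names for a fit; expands when needed
build_design <- function(records, spec) {
  stopifnot(inherits(spec, "design_spec"))
  validate_gap_records(records, spec$covariates)
  if (any(records$order_k > spec$k_max))
    stop("record with order_k > k_max (", spec$k_max, ") present; ",
         "truncate with build_gap_records(k_max = ...) first")
  if (spec$effects == "order_specific") {
    ex <- expand_order_specific(records, spec)
    covs <- attr(ex, "expanded_covariates")
    list(records = ex, covariates = covs,
         Z = as.matrix(ex[covs]))
  } else {
    list(records = records, covariates = spec$covariates,
         Z = as.matrix(records[spec$covariates]))
  }
}

#' Read and write long-format gap-time tables
#'
#' `read_gap_table()` reads a delimited text file (comma or tab separated,
#' header row required) into a gap-record data frame. Either a `gap` column or
#' the pair (`tstart`, `tstop`) must be present; in the latter case
#' `gap = tstop - tstart`. Column names are configurable through `columns`,
#' whose defaults mirror the conventional counting-process layout
#' (`id`, `visit`/`order_k`, `tstart`, `tstop`, `status`). `write_gap_table()`
#' writes
#' the canonical columns back out; a written table reads back to identical
#' records.
#'
#' @param path file path.
#' @param columns named list mapping the canonical roles `id`, `order`,
#'   `gap`, `tstart`, `tstop`, `status` to column names in the file.
#' @param covariates optional character vector naming the covariate columns to
#'   retain; default: every column not consumed by the mapping.
#' @param sep field separator; `NULL` (default) auto-detects comma vs tab from
#'   the header line.
#' @return `read_gap_table()`: a validated gap-record data frame.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' rec <- data.frame(id = c("a", "a"), order_k = 1:2, gap = c(2, 3),
#'                   status = c(1, 0), sex = c(1, 1))
#' write_gap_table(rec, f)
#' identical(read_gap_table(f), rec)
#' @export
read_gap_table <- function(path, columns = list(), covariates = NULL,
                           sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  map <- modifyList(list(id = "id", order = NULL, gap = "gap",
                         tstart = "tstart", tstop = "tstop",
                         status = "status"), columns)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
  if (is.null(map$order)) {   # accept the conventional names for the order
    hit <- intersect(c("visit", "order_k", "order"), names(raw))
    map$order <- if (length(hit)) hit[[1L]] else "visit"
  }
  need <- function(role) {
    cn <- map[[role]]
    if (!cn %in% names(raw))
      stop("missing mandatory column '", cn, "' (role: ", role, ")")
    raw[[cn]]
  }
  out <- data.frame(id = need("id"), order_k = as.integer(need("order")),
                    stringsAsFactors = FALSE)
  if (map$gap %in% names(raw)) {
    out$gap <- as.numeric(need("gap"))
    used <- c(map$id, map$order, map$gap, map$status)
  } else if (all(c(map$tstart, map$tstop) %in% names(raw))) {
    out$gap <- as.numeric(need("tstop")) - as.numeric(need("tstart"))
    used <- c(map$id, map$order, map$tstart, map$tstop, map$status)
  } else {
    stop("need either a '", map$gap, "' column or both '", map$tstart,
         "' and '", map$tstop, "'")
  }
  st <- need("status")
  if (!all(st %in% c(0, 1, "0", "1")))
    stop("'", map$status, "' must be coded 0/1")
  out$status <- as.numeric(st)
  if (anyNA(out$gap)) stop("non-numeric gap/tstart/tstop values")
  if (is.null(covariates)) covariates <- setdiff(names(raw), used)
  for (cn in covariates) {
    if (!cn %in% names(raw)) stop("covariate column not in file: ", cn)
    out[[cn]] <- as.numeric(raw[[cn]])
  }
  validate_gap_records(out, covariates)
  out
}

#' @rdname read_gap_table
#' @param records gap-record data frame to write.
#' @return `write_gap_table()`: the path, invisibly.
#' @export
write_gap_table <- function(records, path, sep = ",") {
  validate_gap_records(records, require_contiguous = FALSE)
  if (is.null(sep)) sep <- ","
  write.table(records, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Coefficient summary table of a fitted model
#'
#' One row per coefficient with the estimate, naive and sandwich standard
#' errors, the Wald chi-square `(estimate / sandwich_se)^2` on 1 df, and its
#' upper-tail p-value. This mirrors the standard printed layout for these
#' models (`Estimate`, `Naive_SE`, `Sandwich_SE`, `Chisq`, `Prob`).
#'
#' @param fit a `"cox_gap_fit"` or `"ly_additive_fit"`.
#' @return A data frame with columns `covariate`, `estimate`, `naive_se`,
#'   `sandwich_se`, `chisq`, `p_value`.
#' @export
fit_table <- function(fit) {
  if (!inherits(fit, c("cox_gap_fit", "ly_additive_fit")))
    stop("'fit' must be a cox_gap_fit or ly_additive_fit")
  est <- fit$coefficients
  naive_se <- sqrt(diag(fit$naive_covariance))
  sand_se <- sqrt(diag(fit$robust_covariance))
  chisq <- (est / sand_se)^2
  data.frame(covariate = names(est), estimate = unname(est),
             naive_se = unname(naive_se), sandwich_se = unname(sand_se),
             chisq = unname(chisq),
             p_value = unname(pchisq(chisq, df = 1, lower.tail = FALSE)),
             stringsAsFactors = FALSE)
}

#' @rdname fit_table
#' @param path file path for the delimited output.
#' @param sep field separator.
#' @export
write_fit_table <- function(fit, path, sep = ",") {
  write.table(fit_table(fit), path, sep = sep, row.names = FALSE,
              quote = FALSE)
  invisible(path)
}
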