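#' Build a survival table from classified cell tracks
#'
#' One record per track: dead tracks contribute `(death_time, event = 1)`,
#' censored or lost tracks `(censor_time, event = 0)`. Optional covariates
#' are extracted from the per-track intensity series — e.g. the reporter
#' intensity at the frame closest to 24 h post-transfection, or the
#' day-2 / day-1 intensity ratio. A covariate whose frame is missing for a
#' cell is recorded as `NA`; the record is retained.
#'
#' @param tracks List of `cell_track`s, all classified by [call_death()].
#' @param covariates Named list describing covariates to attach. Each
#'   element is either a function(track) -> numeric, or a list with
#'   `channel` and one of `at_hour` (intensity at the observation nearest
#'   that hour, within half the frame interval) or `ratio_hours =
#'   c(h2, h1)` (intensity ratio between the two nearest observations).
#'
#' @return data.frame with `id`, `group`, `time_days`, `event`, and one
#'   column per covariate.
#' @export
build_survival_table <- function(tracks, covariates = list()) {
  rows <- lapply(tracks, function(tr) {
    if (identical(tr$status, "unclassified"))
      stop("track without exit time: run call_death() first")
    dead <- identical(tr$status, "dead")
    time <- if (dead) tr$death_time else tr$censor_time
    if (is.na(time)) stop("track without exit time")
    rec <- data.frame(id = tr$id,
                      group = tr$group %||% NA_character_,
                      time_days = time, event = as.integer(dead),
                      stringsAsFactors = FALSE)
    for (nm in names(covariates)) {
      rec[[nm]] <- extract_covariate(tr, covariates[[nm]])
    }
    rec
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

extract_covariate <- function(track, spec) {
  if (is.function(spec)) return(spec(track))
  ts <- extract_timeseries(track, spec$channel)
  half_ivl <- if (length(track$timestamps_h) > 1)
    min(diff(track$timestamps_h)) / 2 else Inf
  at <- function(hour) {
    i <- which.min(abs(ts$time_h - hour))
    if (abs(ts$time_h[i] - hour) > half_ivl) return(NA_real_)
    ts$mean[i]
  }
  if (!is.null(spec$at_hour)) return(at(spec$at_hour))
  if (!is.null(spec$ratio_hours)) {
    v2 <- at(spec$ratio_hours[1]); v1 <- at(spec$ratio_hours[2])
    return(v2 / v1)
  }
  stop("covariate spec must give `at_hour` or `ratio_hours`")
}

#' Fit a grouped Cox proportional-hazards model
#'
#' Per-group hazard ratios relative to a reference group, from the Cox
#' partial likelihood with the Efron correction for ties (observation on
#' a daily imaging grid makes ties ubiquitous). Wraps
#' [survival::coxph()].
#'
#' @param records Survival table (data.frame with `time_days`, `event`,
#'   and the grouping column).
#' @param group_factor Name of the grouping column (default `"group"`).
#' @param reference Reference group level; default the first level.
#'
#' @return A `cox_fit`: list with `reference`, `ties = "efron"`, and
#'   `table` — one row per non-reference group with `beta` (log HR),
#'   `hr`, `se`, `z`, `p`, and `n`; plus `n_events` and the underlying
#'   [survival::coxph()] fit.
#' @export
fit_cox <- function(records, group_factor = "group", reference = NULL) {
  g <- records[[group_factor]]
  if (is.null(g)) stop(sprintf("no column '%s' in records", group_factor))
  levs <- unique(as.character(g))
  if (length(levs) < 2L) stop("need at least 2 groups")
  if (any(table(factor(g, levels = levs)) == 0L))
    stop("a group has zero observations")
  if (sum(records$event) < 1L) stop("no information: no events observed")
  reference <- reference %||% levs[1]
  if (!reference %in% levs) stop("reference group not present")
  fg <- factor(as.character(g), levels = c(reference, setdiff(levs, reference)))
  fit <- survival::coxph(
    survival::Surv(records$time_days, records$event) ~ fg,
    ties = "efron")
  beta <- unname(coef(fit))
  se <- sqrt(diag(vcov(fit)))
  groups <- levels(fg)[-1]
  tab <- data.frame(
    group = groups, beta = beta, hr = exp(beta), se = unname(se),
    z = beta / unname(se),
    p = 2 * pnorm(-abs(beta / unname(se))),
    n = as.integer(table(fg)[groups]),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(reference = reference,
                 n_reference = sum(fg == reference),
                 n_events = sum(records$event),
                 ties = "efron", table = tab, coxph = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox proportional hazards (Efron ties), reference = %s (n = %d, %d events total)\n",
              x$reference, x$n_reference, x$n_events))
  tab <- x$table
  tab$hr <- sprintf("%.3f", tab$hr)
  tab$p <- format.pval(tab$p, digits = 3)
  print(tab[, c("group", "hr", "se", "p", "n")], row.names = FALSE)
  invisible(x)
}

#' Cumulative risk-of-death curve
#'
#' The Kaplan–Meier complement `1 - S(t)`: a right-continuous,
#' nondecreasing step function in `[0, 1]` of the cumulative death
#' fraction against time — the standard presentation of single-cell
#' longitudinal survival data.
#'
#' @param records Survival table.
#' @param group Optional group label to subset to.
#' @return data.frame with `time_days` and `cum_risk` (step values after
#'   each event time), including a leading `(0, 0)` row.
#' @export
cumulative_risk_curve <- function(records, group = NULL) {
  if (!is.null(group)) records <- records[records$group == group, ]
  if (nrow(records) < 1L) stop("no records")
  sf <- survival::survfit(
    survival::Surv(records$time_days, records$event) ~ 1)
  data.frame(time_days = c(0, sf$time), cum_risk = c(0, 1 - sf$surv))
}
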