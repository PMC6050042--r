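#' Simulate an interval-censored single-cell survival cohort
#'
#' Draws per-cell death times from a proportional-hazards model
#' (exponential baseline by default, Weibull via `shape`) and observes
#' them on a discrete imaging schedule, emulating a longitudinal
#' fluorescence microscopy experiment in which cells are imaged at fixed
#' intervals (24 h in the reference design) and a death can only be seen
#' at the first frame after it occurs. Cells surviving past `follow_up`
#' are censored there.
#'
#' Each cell also receives a day-1 expression level (log-normal, AU),
#' which can drive its hazard through `log_hazard_fun` in addition to the
#' group effect — this is how smooth expression-risk relationships are
#' simulated for the penalized-spline models.
#'
#' @param n_per_group Cells per group (scalar or vector matching groups).
#' @param group_log_hrs Named numeric vector of log hazard ratios, one
#'   per group; the reference group should carry 0.
#' @param baseline_hazard Baseline hazard rate per day (> 0).
#' @param follow_up Follow-up length in days (> 0).
#' @param interval_days Imaging interval in days; observed event times are
#'   discretized upward to this grid.
#' @param shape Weibull shape; 1 (default) gives an exponential baseline.
#' @param expression_meanlog,expression_sdlog Log-normal parameters of the
#'   day-1 expression covariate (AU).
#' @param log_hazard_fun Optional function g(x): added to the per-cell log
#'   hazard as a function of expression.
#' @param seed Integer seed (required; the generator is deterministic
#'   given the seed).
#'
#' @return A list with `records` (data.frame: `id`, `group`, `time_days`,
#'   `event`, `expr_day1`) and `truth` (per-cell true continuous death
#'   times and the generating parameters).
#' @export
simulate_survival_cohort <- function(n_per_group, group_log_hrs,
                                     baseline_hazard, follow_up = 10,
                                     interval_days = 1, shape = 1,
                                     expression_meanlog = log(500),
                                     expression_sdlog = 0.6,
                                     log_hazard_fun = NULL, seed) {
  if (length(group_log_hrs) == 0L || is.null(names(group_log_hrs)))
    stop("empty group map: `group_log_hrs` must be a named vector")
  stopifnot(baseline_hazard > 0, follow_up > 0, interval_days > 0, shape > 0)
  groups <- names(group_log_hrs)
  n_per_group <- rep_len(n_per_group, length(groups))
  n <- sum(n_per_group)
  with_seed(seed, {
    group <- rep(groups, times = n_per_group)
    expr <- rlnorm(n, expression_meanlog, expression_sdlog)
    eta <- group_log_hrs[group]
    if (!is.null(log_hazard_fun)) eta <- eta + log_hazard_fun(expr)
    # PH Weibull: S(t) = exp(-h0 * t^shape * e^eta)
    u <- rexp(n)
    t_true <- (u / (baseline_hazard * exp(eta)))^(1 / shape)
    t_obs <- ceiling(t_true / interval_days) * interval_days
    event <- as.integer(t_obs <= follow_up)
    time <- ifelse(event == 1L, pmax(t_obs, interval_days), follow_up)
    records <- data.frame(
      id = seq_len(n), group = group, time_days = time, event = event,
      expr_day1 = expr, stringsAsFactors = FALSE, row.names = NULL
    )
    truth <- list(
      true_death_time = t_true, group_log_hrs = group_log_hrs,
      baseline_hazard = baseline_hazard, shape = shape,
      log_hazard_fun = log_hazard_fun, follow_up = follow_up,
      interval_days = interval_days
    )
    list(records = records, truth = truth)
  })
}

#' Simulate a FRAP recovery trace
#'
#' Forward model of single-exponential fluorescence recovery after
#' photobleaching, \eqn{y(t) = A(1 - e^{-\tau t})}: the normalized,
#' floor-subtracted recovery starts at exactly 0 immediately post-bleach
#' and asymptotes to the mobile-fraction plateau `A`. Gaussian noise of
#' standard deviation `noise_sd` (in recovery-fraction units) is added to
#' all points after the bleach frame.
#'
#' @param A Plateau (recovery fraction), in (0, 1].
#' @param tau Recovery rate constant, per second (> 0).
#' @param duration Trace length in seconds; the default 60 s covers ~8
#'   half-times at the default rate.
#' @param dt Sampling interval in seconds (> 0); the 1 s default matches
#'   typical confocal FRAP acquisition and keeps several samples on the
#'   rising phase (dt of about t1/2 / 5 or finer).
#' @param noise_sd Gaussian noise sd as a recovery fraction (>= 0).
#' @param bleach_roi_area_um2 Bleached ROI area in square micrometres
#'   (carried on the trace for downstream diffusion estimates).
#' @param seed Integer seed; `NULL` only valid when `noise_sd = 0`.
#'
#' @return A `frap_trace`: data.frame with `time_s`, `recovery`, and
#'   attribute `bleach_roi_area_um2`.
#' @export
simulate_frap_trace <- function(A, tau, duration = 60, dt = 1,
                                noise_sd = 0, bleach_roi_area_um2 = pi,
                                seed = NULL) {
  stopifnot(A > 0, A <= 1, tau > 0, dt > 0, duration >= dt)
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (noise_sd > 0 && is.null(seed)) stop("a seed is required when noise_sd > 0")
  with_seed(seed, {
    t <- seq(0, duration, by = dt)
    y <- A * (1 - exp(-tau * t))
    if (noise_sd > 0) y[-1] <- y[-1] + rnorm(length(t) - 1L, 0, noise_sd)
    frap_trace(t, y, bleach_roi_area_um2)
  })
}

#' Construct a FRAP trace object
#'
#' @param time_s Times post-bleach in seconds, strictly increasing, first 0.
#' @param recovery Normalized recovery values (floor-subtracted fraction of
#'   pre-bleach integrated density).
#' @param bleach_roi_area_um2 Bleach ROI area (square micrometres).
#' @return A `frap_trace` data.frame.
#' @export
frap_trace <- function(time_s, recovery, bleach_roi_area_um2 = NA_real_) {
  stopifnot(length(time_s) == length(recovery), all(diff(time_s) > 0),
            time_s[1] == 0)
  structure(
    data.frame(time_s = time_s, recovery = recovery),
    bleach_roi_area_um2 = bleach_roi_area_um2,
    class = c("frap_trace", "data.frame")
  )
}

#' Simulate an optical pulse labeling (OPL) decay trace
#'
#' Photoconversion of a Dendra2-type tag creates a pulse of red-channel
#' signal that decays as the protein is cleared; the noiseless trace is
#' \eqn{I(t) = I_0 \cdot 2^{-t/t_{1/2}}}. Noise is multiplicative
#' log-normal with coefficient of variation `noise_cv`, keeping
#' intensities strictly positive.
#'
#' @param half_life Protein half-life in hours (> 0).
#' @param n_timepoints Number of samples (>= 2).
#' @param interval Sampling interval in hours.
#' @param i0 Initial photoconverted intensity (AU).
#' @param noise_cv Multiplicative noise CV (>= 0).
#' @param seed Integer seed; `NULL` only valid when `noise_cv = 0`.
#'
#' @return An `opl_trace` data.frame with `time_h`, `intensity`.
#' @export
simulate_opl_trace <- function(half_life, n_timepoints = 11, interval = 9.6,
                               i0 = 100, noise_cv = 0, seed = NULL) {
  if (half_life <= 0) stop("half_life must be positive")
  stopifnot(n_timepoints >= 2, interval > 0, i0 > 0)
  if (noise_cv < 0) stop("noise_cv must be nonnegative")
  if (noise_cv > 0 && is.null(seed)) stop("a seed is required when noise_cv > 0")
  with_seed(seed, {
    t <- (seq_len(n_timepoints) - 1L) * interval
    i <- i0 * 2^(-t / half_life)
    if (noise_cv > 0) i <- i * exp(rnorm(n_timepoints, 0, noise_cv))
    structure(data.frame(time_h = t, intensity = i),
              class = c("opl_trace", "data.frame"))
  })
}
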