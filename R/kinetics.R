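# FRAP and optical-pulse-labeling kinetics.
#
# The recovery model is y(t) = A (1 - e^(-tau t)) with half-time
# t1/2 = ln(2)/tau; the diffusion coefficient is D = 0.88 w^2 / (4 t1/2)
# with the effective squared bleach radius w^2 approximated by the ROI
# area divided by pi; viscosity follows from Einstein-Stokes,
# eta = kB T / (6 pi D r), with the Stokes radius of a globular protein
# of molecular weight M (kDa) estimated as r = 0.66 M^(1/3) nm.

BOLTZMANN_J_PER_K <- 1.380649e-23

#' Normalize a FRAP image series to a recovery trace
#'
#' Implements the integrated-density normalization protocol for a
#' bleached sub-region of a granule: the whole-granule integrated density
#' is measured pre-bleach, the pre-bleach fraction of that density inside
#' the bleach ROI is computed, the immediate post-bleach value of that
#' fraction is taken as the floor, and recovery is the floor-subtracted
#' ROI fraction at each post-bleach frame. Frames are rigid-body
#' registered to the first pre-bleach frame before measurement.
#'
#' @param pre_bleach 3D array (rows x cols x frames) of pre-bleach frames
#'   (>= 1 frame).
#' @param post_bleach 3D array of post-bleach frames; the first frame is
#'   the immediate post-bleach (floor) frame at time 0.
#' @param granule_mask Logical matrix: the whole granule.
#' @param bleach_roi_mask Logical matrix: the bleached ROI, a subset of
#'   the granule mask.
#' @param times_s Post-bleach frame times in seconds (first must be 0).
#' @param pixel_size_um Pixel size, used for the ROI area carried on the
#'   trace.
#' @param register Apply [register_stack()] first (default TRUE; disable
#'   for pre-aligned synthetic stacks).
#' @return A [frap_trace()].
#' @export
normalize_frap <- function(pre_bleach, post_bleach, granule_mask,
                           bleach_roi_mask, times_s,
                           pixel_size_um = 1, register = TRUE) {
  stopifnot(length(dim(pre_bleach)) == 3L, length(dim(post_bleach)) == 3L)
  if (!any(granule_mask)) stop("empty granule mask")
  if (!any(bleach_roi_mask)) stop("empty bleach ROI mask")
  if (any(bleach_roi_mask & !granule_mask))
    stop("bleach ROI must lie inside the granule mask")
  if (times_s[1] != 0) stop("post-bleach times must start at 0")
  n_pre <- dim(pre_bleach)[3]
  if (register) {
    all_frames <- array(c(pre_bleach, post_bleach),
                        dim = c(dim(pre_bleach)[1:2],
                                n_pre + dim(post_bleach)[3]))
    st <- time_lapse_stack(list(ch = all_frames),
                           timestamps_h = seq_len(dim(all_frames)[3]))
    st <- register_stack(st, reference_frame = 1L)$stack
    pre_bleach <- st$channels$ch[, , seq_len(n_pre), drop = FALSE]
    post_bleach <- st$channels$ch[, , -seq_len(n_pre), drop = FALSE]
  }
  int_dens <- function(arr, mask)
    apply(arr, 3, function(m) sum(m[mask]))
  granule_pre <- mean(int_dens(pre_bleach, granule_mask))
  roi_pre_frac <- mean(int_dens(pre_bleach, bleach_roi_mask)) / granule_pre
  roi_frac <- int_dens(post_bleach, bleach_roi_mask) / granule_pre
  floor_frac <- roi_frac[1]
  if (floor_frac >= roi_pre_frac)
    stop("ineffective bleach: no post-bleach decline in ROI fraction")
  frap_trace(times_s, roi_frac - floor_frac,
             bleach_roi_area_um2 = sum(bleach_roi_mask) * pixel_size_um^2)
}

#' Fit the single-exponential FRAP recovery model
#'
#' Nonlinear least squares for \eqn{y(t) = A(1 - e^{-\tau t})}.
#' Initialization: `A0 = max(y)`, `tau0` from a log-linear fit of
#' `1 - y/A0`; on failure, three perturbed restarts before declaring
#' non-convergence. `A` is bounded to (0, 1.5] and `tau` to be positive.
#'
#' @param trace A [frap_trace()] (or data.frame with `time_s`,
#'   `recovery`), >= 5 points.
#' @return A `frap_fit`: `A`, `tau`, `t_half` (s), `residual_rms`,
#'   `bleach_roi_area_um2` (carried from the trace), and the `nls` fit.
#' @export
fit_recovery <- function(trace) {
  t <- trace$time_s; y <- trace$recovery
  if (length(t) < 5L) stop("need at least 5 points")
  A0 <- max(y)
  if (A0 <= 0) stop("non-convergence: trace never rises above zero")
  # initial tau: time of half-rise (robust to plateau noise), refined by
  # a log-linear fit of 1 - y/A0 over the rising phase
  i_half <- which(y >= A0 / 2)[1]
  tau0 <- if (!is.na(i_half) && t[i_half] > 0) log(2) / t[i_half] else
    1 / max(t)
  Ai <- 1.05 * A0
  rising <- y > 0 & y < 0.9 * Ai & t > 0 & t <= 3 / tau0
  if (sum(rising) >= 3) {
    sl <- coef(lm(log(1 - y[rising] / Ai) ~ t[rising]))[2]
    if (is.finite(sl) && sl < 0) tau0 <- -sl
  }
  if (max(t) < 1 / tau0)
    warning("trace span is short relative to the recovery time scale")
  starts <- list(c(A = min(A0, 1.5), tau = tau0),
                 c(A = min(1.1 * A0, 1.5), tau = 2 * tau0),
                 c(A = min(0.9 * A0, 1.4), tau = 0.5 * tau0),
                 c(A = 0.5, tau = 1 / max(t)))
  fit <- NULL
  best_sse <- Inf
  for (s in starts) {
    cand <- tryCatch(
      minpack.lm::nlsLM(y ~ A * (1 - exp(-tau * t)),
                        start = as.list(s),
                        lower = c(A = 1e-8, tau = 1e-10),
                        upper = c(A = 1.5, tau = Inf),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(cand)) {
      sse <- sum(residuals(cand)^2)
      if (sse < best_sse) { best_sse <- sse; fit <- cand }
    }
  }
  if (is.null(fit))
    stop(sprintf(
      "non-convergence after %d starts (A0 = %.3g, tau0 = %.3g)",
      length(starts), A0, tau0))
  cf <- coef(fit)
  structure(list(
    A = unname(cf["A"]), tau = unname(cf["tau"]),
    t_half = half_time(unname(cf["tau"])),
    residual_rms = sqrt(mean(residuals(fit)^2)),
    bleach_roi_area_um2 = attr(trace, "bleach_roi_area_um2") %||% NA_real_,
    nls = fit
  ), class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf("FRAP fit: A = %.3f, tau = %.4g /s, t1/2 = %.2f s (rms %.3g)\n",
              x$A, x$tau, x$t_half, x$residual_rms))
  invisible(x)
}

#' Half-time of recovery
#'
#' \eqn{t_{1/2} = \ln(2)/\tau} for a single-exponential recovery.
#'
#' @param tau Recovery rate constant (> 0), per second.
#' @return Half-time in seconds.
#' @export
half_time <- function(tau) {
  if (any(tau <= 0)) stop("tau must be positive")
  log(2) / tau
}

#' Diffusion coefficient from a spot-bleach recovery
#'
#' \eqn{D = 0.88 w^2 / (4 t_{1/2})}, with the effective squared bleach
#' radius approximated from the ROI area as \eqn{w^2 = area/\pi} (the
#' spot-bleach geometry is approximate for half-granule ROIs, hence the
#' area-based estimate).
#'
#' @param bleach_roi_area Bleach ROI area in square micrometres (> 0).
#' @param t_half Recovery half-time in seconds (> 0).
#' @return D in square micrometres per second.
#' @export
diffusion_coefficient <- function(bleach_roi_area, t_half) {
  if (any(bleach_roi_area <= 0)) stop("area must be positive")
  if (any(t_half <= 0)) stop("t_half must be positive")
  w2 <- bleach_roi_area / pi
  0.88 * w2 / (4 * t_half)
}

#' Minimal Stokes radius of a globular protein
#'
#' \eqn{R_{min} = 0.66 M^{1/3}} nm for molecular weight M in kDa — the
#' radius of the smallest sphere bounding a globular protein of that
#' mass.
#'
#' @param M Molecular weight in kDa (> 0).
#' @return Radius in nm.
#' @export
stokes_radius <- function(M) {
  if (any(M <= 0)) stop("molecular weight must be positive")
  0.66 * M^(1 / 3)
}

#' Viscosity from the Einstein-Stokes relation
#'
#' \eqn{\eta = k_B T / (6 \pi D r)}, with unit conversion handled
#' internally (D in um^2/s, r in nm, eta returned in Pa s).
#'
#' @param D Diffusion coefficient in square micrometres per second (> 0).
#' @param T_kelvin Temperature in kelvin (> 0); 310.15 K corresponds to
#'   imaging at 37 degrees C.
#' @param r Stokes radius in nm (> 0).
#' @return Viscosity in Pa s.
#' @export
viscosity <- function(D, T_kelvin = 310.15, r) {
  if (any(D <= 0) || any(T_kelvin <= 0) || any(r <= 0))
    stop("all inputs must be positive")
  D_si <- D * 1e-12   # m^2/s
  r_si <- r * 1e-9    # m
  BOLTZMANN_J_PER_K * T_kelvin / (6 * pi * D_si * r_si)
}

#' Full FRAP kinetic report for one bleach experiment
#'
#' Chains [fit_recovery()], [half_time()], [diffusion_coefficient()],
#' [stokes_radius()] and [viscosity()] into the per-granule parameter set:
#' plateau, rate, half-time, diffusion coefficient, and Einstein-Stokes
#' viscosity for a protein of molecular weight `M_kda`.
#'
#' @param trace A [frap_trace()] carrying its bleach ROI area.
#' @param M_kda Molecular weight of the tagged protein (kDa).
#' @param T_kelvin Temperature (K).
#' @return A list extending the `frap_fit` with `w2_um2`, `D_um2_s`,
#'   `stokes_radius_nm`, `M_kda`, `T_kelvin`, `eta_pa_s`.
#' @export
frap_report <- function(trace, M_kda, T_kelvin = 310.15) {
  fit <- fit_recovery(trace)
  area <- fit$bleach_roi_area_um2
  if (is.na(area)) stop("trace carries no bleach ROI area")
  D <- diffusion_coefficient(area, fit$t_half)
  r <- stokes_radius(M_kda)
  c(unclass(fit)[c("A", "tau", "t_half", "residual_rms")],
    list(bleach_roi_area_um2 = area, w2_um2 = area / pi, D_um2_s = D,
         stokes_radius_nm = r, M_kda = M_kda, T_kelvin = T_kelvin,
         eta_pa_s = viscosity(D, T_kelvin, r)))
}

#' Protein half-life from an optical pulse labeling decay trace
#'
#' Ordinary least squares on the log-transformed photoconverted-channel
#' intensity against time: the decay constant is minus the slope and the
#' half-life is \eqn{\ln(2)/k}. A rising trace (negative estimated decay
#' constant) is flagged invalid rather than reported as a negative
#' half-life.
#'
#' @param trace An `opl_trace` (or data.frame with `time_h`,
#'   `intensity`), >= 3 points, all intensities > 0.
#' @return A `half_life_fit`: `k` (per hour), `half_life_h`, `r_squared`,
#'   `valid`.
#' @export
fit_opl_halflife <- function(trace) {
  t <- trace$time_h; i <- trace$intensity
  if (length(t) < 3L) stop("need at least 3 points")
  if (any(i <= 0)) stop("intensities must be positive")
  fit <- lm(log(i) ~ t)
  k <- -unname(coef(fit)[2])
  li <- log(i)
  r2 <- 1 - sum(residuals(fit)^2) / sum((li - mean(li))^2)
  structure(list(
    k = k,
    half_life_h = if (k > 0) log(2) / k else NA_real_,
    r_squared = r2,
    valid = k > 0
  ), class = "half_life_fit")
}

#' @export
print.half_life_fit <- function(x, ...) {
  if (x$valid)
    cat(sprintf("OPL half-life: %.2f h (k = %.4g /h, R^2 = %.3f)\n",
                x$half_life_h, x$k, x$r_squared))
  else cat("OPL fit invalid: signal does not decay\n")
  invisible(x)
}
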