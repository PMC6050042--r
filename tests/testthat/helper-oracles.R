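# Independent oracles used to cross-check the package implementation.
# These deliberately avoid every package code path they are used to test.

# Efron-tie Cox log partial likelihood for a single binary covariate,
# written directly from the definition (loop over event times).
efron_loglik_oracle <- function(time, event, x, beta) {
  ll <- 0
  for (t_j in unique(time[event == 1])) {
    D <- which(time == t_j & event == 1)
    R <- which(time >= t_j)
    d <- length(D)
    wR <- exp(beta * x[R])
    wD <- exp(beta * x[D])
    ll <- ll + sum(beta * x[D])
    for (m in seq_len(d) - 1) {
      ll <- ll - log(sum(wR) - (m / d) * sum(wD))
    }
  }
  ll
}

# Exhaustive grid maximization of the Efron partial likelihood over
# beta in [-3, 3].
cox_grid_beta <- function(records, reference, step = 1e-4) {
  stopifnot(length(unique(records$group)) == 2)
  x <- as.numeric(records$group != reference)
  grid <- seq(-3, 3, by = step)
  ll <- vapply(grid, function(b)
    efron_loglik_oracle(records$time_days, records$event, x, b), 1)
  grid[which.max(ll)]
}

# Two-sided Fisher exact p by full enumeration of the hypergeometric
# tables with the observed margins (sum of tables no more probable than
# the observed, with the same 1 + 1e-7 relative tolerance R uses).
fisher_p_enum <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Minimal two-blob frame stack for segmentation tests.
make_blob_stack <- function(peaks = c(100, 80), centers = list(c(15, 15), c(45, 40)),
                            sigma = 3, size = 64, background = 0, n_frames = 1) {
  img <- matrix(background, size, size)
  for (i in seq_along(peaks))
    img <- lfmkit:::add_gaussian_blob(img, centers[[i]][1], centers[[i]][2],
                                      sigma, sigma, 0, peaks[i])
  arr <- array(rep(img, n_frames), dim = c(size, size, n_frames))
  time_lapse_stack(list(morphology = arr, reporter = arr),
                   timestamps_h = 24 * seq_len(n_frames))
}

# Hand-built classified cell_track for survival-table tests.
make_track <- function(id, group, status, exit_day, timestamps_h = 24 * (1:10),
                       means = NULL) {
  nobs <- sum(timestamps_h / 24 <= exit_day)
  obs <- data.frame(
    frame = seq_len(nobs), time_h = timestamps_h[seq_len(nobs)],
    label = 1L, x = 10, y = 10, area = 50L, eccentricity = 0.8,
    solidity = 1,
    mean_morphology = if (is.null(means)) 100 else means[seq_len(nobs)],
    total_morphology = 5000,
    mean_reporter = 200, total_reporter = 10000
  )
  structure(list(id = id, group = group, obs = obs,
                 timestamps_h = timestamps_h, field_size = c(64, 64),
                 status = status,
                 death_time = if (status == "dead") exit_day else NA_real_,
                 censor_time = if (status != "dead") exit_day else NA_real_),
            class = "cell_track")
}
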