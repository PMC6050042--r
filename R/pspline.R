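# Penalized-spline smooth-risk models.
#
# Shared machinery: a cubic B-spline basis with interior knots at
# covariate quantiles and a second-order roughness penalty (the exact
# curvature integral), with the smoothing parameter chosen by AIC over a
# log-spaced grid. Used inside a Cox partial likelihood (smooth
# log-relative-hazard of a continuous covariate, Efron ties) and inside a
# binomial logit model (smooth event probability, e.g. granule onset).

# Basis ------------------------------------------------------------------

# Cubic B-spline basis with interior knots at covariate quantiles. The
# covariate is affinely mapped to [0, 1] internally so the curvature
# penalty and the lambda grid live on a fixed scale regardless of the
# covariate's units.
spline_basis <- function(x, n_knots = 8L, degree = 3L) {
  rng <- range(x)
  if (diff(rng) <= 0) stop("no variation in covariate")
  u <- (x - rng[1]) / diff(rng)
  probs <- seq_len(n_knots) / (n_knots + 1)
  interior <- unique(quantile(u, probs, names = FALSE, type = 7))
  knots <- c(rep(0, degree + 1L), interior, rep(1, degree + 1L))
  list(knots = knots, degree = degree, range = rng)
}

eval_basis <- function(basis, x) {
  # clamp to the training range so the curve is evaluable everywhere
  x <- pmin(pmax(x, basis$range[1]), basis$range[2])
  u <- (x - basis$range[1]) / diff(basis$range)
  splines::splineDesign(basis$knots, u, ord = basis$degree + 1L,
                        outer.ok = TRUE)
}

# Second-order roughness penalty: the exact curvature integral
# Omega_ij = int B_i''(u) B_j''(u) du over the (scaled) covariate domain.
# Unlike a coefficient-difference penalty, its null space is the linear
# functions of the covariate for any knot layout, so quantile knots do
# not bias the smooth limit. For cubic splines B'' is piecewise linear,
# making 2-point Gauss quadrature on each inter-knot interval exact.
curvature_penalty <- function(basis) {
  kn <- basis$knots
  ord <- basis$degree + 1L
  brk <- unique(kn)
  gauss <- c(-1, 1) / sqrt(3)
  pts <- unlist(lapply(seq_len(length(brk) - 1L), function(i) {
    a <- brk[i]; b <- brk[i + 1L]
    (a + b) / 2 + (b - a) / 2 * gauss
  }))
  wts <- rep(diff(brk) / 2, each = 2L)
  D2 <- splines::splineDesign(kn, pts, ord = ord, derivs = 2L,
                              outer.ok = TRUE)
  crossprod(D2 * sqrt(wts))
}

# Orthonormal complement of the all-ones coefficient direction (the
# constant function, not identifiable inside a Cox model).
drop_constant_dir <- function(k) {
  qr.Q(qr(matrix(1, k, 1)), complete = TRUE)[, -1, drop = FALSE]
}

# Selection-aware p-value for the smooth effect.
#
# The smoothing parameter is chosen by AIC over a grid, so the natural
# test statistic is the selected AIC advantage over the null model,
# T = max_lambda [LRT(lambda) - 2 edf(lambda)]. Referring LRT(lambda-hat)
# to a chi-square on edf degrees of freedom ignores the selection and is
# anti-conservative. Instead the null distribution of T is computed
# directly: writing the null-information / penalty pencil in whitened
# coordinates (U' H U = I, U' P U = diag(s)), the quadratic approximation
# gives LRT(lambda) = sum_i rho_i (2 - rho_i) z_i^2 and
# edf(lambda) = sum_i rho_i with rho_i = 1/(1 + lambda s_i) and
# z ~ N(0, I), so T's null law is simulated exactly in that
# approximation (fixed internal seed; does not touch the caller's RNG).
selection_pvalue <- function(H_null, P, lambda_grid, t_obs,
                             n_mc = 4000L, mc_seed = 371L) {
  k <- ncol(H_null)
  R <- tryCatch(chol(H_null), error = function(e)
    chol(H_null + diag(1e-8 * max(diag(H_null)), k)))
  Rinv <- backsolve(R, diag(k))
  s <- pmax(eigen(t(Rinv) %*% P %*% Rinv, symmetric = TRUE,
                  only.values = TRUE)$values, 0)
  W <- vapply(lambda_grid, function(l) {
    rho <- 1 / (1 + l * s)
    c(rho * (2 - rho), sum(rho))
  }, numeric(k + 1))
  with_seed(mc_seed, {
    Z2 <- matrix(rnorm(n_mc * k)^2, n_mc, k)
    gains <- Z2 %*% W[seq_len(k), , drop = FALSE]
    gains <- sweep(gains, 2, 2 * W[k + 1, ])
    t_null <- do.call(pmax, as.data.frame(gains))
    (1 + sum(t_null >= t_obs)) / (n_mc + 1)
  })
}

# Efron partial likelihood -----------------------------------------------

# Log partial likelihood, gradient and observed information of a Cox
# model with linear predictor X beta, Efron tie correction.
cox_efron <- function(time, event, X, beta, hessian = TRUE) {
  n <- nrow(X); k <- ncol(X)
  eta <- drop(X %*% beta)
  eta <- eta - mean(eta)
  w <- exp(eta)
  od <- order(time, decreasing = TRUE)
  ts <- time[od]; ws <- w[od]; Xs <- X[od, , drop = FALSE]
  cw <- cumsum(ws)
  cwX <- apply(ws * Xs, 2, cumsum)
  if (n == 1L) cwX <- matrix(cwX, 1L)
  if (hessian) {
    pairs <- which(upper.tri(diag(k), diag = TRUE), arr.ind = TRUE)
    XX <- Xs[, pairs[, 1], drop = FALSE] * Xs[, pairs[, 2], drop = FALSE]
    cwXX <- apply(ws * XX, 2, cumsum)
    if (n == 1L) cwXX <- matrix(cwXX, 1L)
    unpack <- function(v) {
      M <- matrix(0, k, k)
      M[cbind(pairs[, 1], pairs[, 2])] <- v
      M[cbind(pairs[, 2], pairs[, 1])] <- v
      M
    }
  }
  ll <- 0
  g <- numeric(k)
  H <- matrix(0, k, k)
  for (t_j in unique(time[event == 1L])) {
    q <- sum(ts >= t_j)           # risk set size in sorted order
    Dj <- which(time == t_j & event == 1L)
    d <- length(Dj)
    S0 <- cw[q]; S1 <- cwX[q, ]
    S0D <- sum(w[Dj])
    S1D <- colSums(X[Dj, , drop = FALSE] * w[Dj])
    if (hessian) {
      S2 <- unpack(cwXX[q, ])
      S2D <- unpack(colSums(XX[match(Dj, od), , drop = FALSE] * w[Dj]))
    }
    ll <- ll + sum(eta[Dj])
    g <- g + colSums(X[Dj, , drop = FALSE])
    for (m in seq_len(d) - 1L) {
      fr <- m / d
      den <- S0 - fr * S0D
      s1 <- S1 - fr * S1D
      ll <- ll - log(den)
      g <- g - s1 / den
      if (hessian) {
        s2 <- S2 - fr * S2D
        H <- H + s2 / den - tcrossprod(s1 / den)
      }
    }
  }
  list(loglik = ll, grad = g, info = if (hessian) H else NULL)
}

# Newton-Raphson with step halving on the penalized partial likelihood.
cox_pen_newton <- function(time, event, X, P, lambda, beta0 = NULL,
                           tol = 1e-8, max_iter = 100L) {
  k <- ncol(X)
  beta <- beta0 %||% numeric(k)
  pll <- function(d) d$loglik
  cur <- cox_efron(time, event, X, beta)
  obj <- cur$loglik - lambda / 2 * drop(crossprod(beta, P %*% beta))
  for (it in seq_len(max_iter)) {
    A <- cur$info + lambda * P
    gpen <- cur$grad - lambda * drop(P %*% beta)
    step <- tryCatch(solve(A, gpen), error = function(e)
      solve(A + diag(1e-8, k), gpen))
    if (max(abs(step)) < tol) break
    sz <- 1
    repeat {
      beta_new <- beta + sz * step
      cand <- cox_efron(time, event, X, beta_new)
      obj_new <- cand$loglik -
        lambda / 2 * drop(crossprod(beta_new, P %*% beta_new))
      if (is.finite(obj_new) && obj_new >= obj - 1e-12) break
      sz <- sz / 2
      if (sz < 1e-10) { beta_new <- beta; cand <- cur; obj_new <- obj; break }
    }
    converged <- max(abs(beta_new - beta)) < tol
    beta <- beta_new; cur <- cand; obj <- obj_new
    if (converged) break
  }
  list(beta = beta, loglik = cur$loglik, grad = cur$grad, info = cur$info)
}

# Smooth hazard model ----------------------------------------------------

#' Penalized-spline Cox model of risk against a continuous covariate
#'
#' Models the log relative hazard as a smooth function of a single-cell
#' covariate (e.g. reporter intensity at 24 h): a cubic B-spline
#' expansion inside the Cox partial likelihood (Efron ties) with a
#' second-order roughness (curvature) penalty on the fitted function. The
#' smoothing parameter is chosen by AIC (`-2 loglik + 2 edf`, with
#' effective degrees of freedom `tr[(H + lambda P)^-1 H]`) over a
#' log-spaced grid. The overall covariate effect is tested by a penalized
#' likelihood-ratio statistic on `edf` degrees of freedom.
#'
#' @param records Survival table with `time_days`, `event` and the
#'   covariate column; needs >= 50 complete records and >= 10 events.
#' @param covariate Name of the covariate column.
#' @param n_knots Interior knots, placed at covariate quantiles.
#' @param lambda_grid Smoothing-parameter grid (default 30 log-spaced
#'   values in `10^[-2, 6]`).
#' @param n_grid Evaluation grid size for the returned curve.
#'
#' @return A `spline_hazard_fit`: the chosen `lambda`, `edf`, `loglik`,
#'   overall `p`, the knot vector and coefficients, a `curve` data.frame
#'   (`x`, centered `log_hr` with pointwise `se`, `lo`, `hi`), and a
#'   `predict_fn(x)` returning the centered log relative hazard.
#' @export
fit_penalized_spline_hazard <- function(records, covariate, n_knots = 8L,
                                        lambda_grid = 10^seq(-2, 6,
                                                             length.out = 30),
                                        n_grid = 100L) {
  ok <- is.finite(records[[covariate]])
  rec <- records[ok, , drop = FALSE]
  if (nrow(rec) < 50L) stop("need >= 50 records with the covariate")
  if (sum(rec$event) < 10L) stop("need >= 10 events")
  x <- rec[[covariate]]
  if (diff(range(x)) <= 0) stop("no variation in covariate")
  basis <- spline_basis(x, n_knots)
  B <- eval_basis(basis, x)
  k <- ncol(B)
  Z <- drop_constant_dir(k)
  Xz <- B %*% Z
  Pz <- t(Z) %*% curvature_penalty(basis) %*% Z

  time <- rec$time_days; event <- rec$event
  null_ll <- cox_efron(time, event, Xz, numeric(ncol(Xz)),
                       hessian = FALSE)$loglik
  grid <- sort(lambda_grid, decreasing = TRUE)   # smooth -> wiggly, warm start
  fits <- vector("list", length(grid))
  beta <- NULL
  for (i in seq_along(grid)) {
    f <- cox_pen_newton(time, event, Xz, Pz, grid[i], beta0 = beta)
    beta <- f$beta
    A <- f$info + grid[i] * Pz
    f$edf <- sum(diag(solve(A, f$info)))
    f$aic <- -2 * f$loglik + 2 * f$edf
    f$lambda <- grid[i]
    fits[[i]] <- f
  }
  aics <- vapply(fits, `[[`, 0, "aic")
  best <- fits[[which.min(aics)]]
  lambda <- best$lambda
  A <- best$info + lambda * Pz
  # Bayesian covariance of the penalized fit: pointwise bands from
  # (H + lambda P)^-1 absorb smoothing bias better than the sandwich
  V <- solve(A)
  lrt <- 2 * (best$loglik - null_ll)
  H0 <- cox_efron(time, event, Xz, numeric(ncol(Xz)))$info
  t_obs <- max(2 * (vapply(fits, `[[`, 0, "loglik") - null_ll) -
                 2 * vapply(fits, `[[`, 0, "edf"))
  p <- selection_pvalue(H0, Pz, grid, t_obs)

  center <- colMeans(Xz)
  gamma <- best$beta
  predict_fn <- function(xnew) {
    Cn <- eval_basis(basis, xnew) %*% Z
    drop(sweep(Cn, 2, center) %*% gamma)
  }
  xg <- seq(basis$range[1], basis$range[2], length.out = n_grid)
  Cg <- sweep(eval_basis(basis, xg) %*% Z, 2, center)
  fit_g <- drop(Cg %*% gamma)
  se_g <- sqrt(pmax(rowSums((Cg %*% V) * Cg), 0))
  curve <- data.frame(x = xg, log_hr = fit_g, se = se_g,
                      lo = fit_g - 1.96 * se_g, hi = fit_g + 1.96 * se_g)

  structure(list(
    covariate = covariate, knots = basis$knots, degree = basis$degree,
    coefficients = gamma, Z = Z, lambda = lambda, edf = best$edf,
    loglik = best$loglik, null_loglik = null_ll, lrt = lrt, p = p,
    aic_path = data.frame(lambda = grid, aic = aics,
                          edf = vapply(fits, `[[`, 0, "edf")),
    curve = curve, predict_fn = predict_fn, n = nrow(rec),
    n_events = sum(event)
  ), class = "spline_hazard_fit")
}

#' @export
print.spline_hazard_fit <- function(x, ...) {
  cat(sprintf(
    "Penalized-spline hazard fit: %s (n = %d, %d events)\n  lambda = %.3g, edf = %.2f, LRT = %.2f, p = %.3g\n",
    x$covariate, x$n, x$n_events, x$lambda, x$edf, x$lrt, x$p))
  invisible(x)
}

# Smooth binomial onset model --------------------------------------------

#' Penalized-spline logistic model of granule-onset risk
#'
#' Models the probability that a cell diffuse on day 1 develops an
#' intranuclear granule by day 3 as a smooth function of a predictor
#' (day-1 expression, or the day-2 / day-1 expression ratio): intercept
#' plus a cubic B-spline expansion with curvature penalty, logit link, fitted by penalized IRLS with the smoothing parameter chosen by
#' AIC. The predictor effect is tested by a penalized likelihood-ratio
#' statistic against the intercept-only model on `edf - 1` degrees of
#' freedom.
#'
#' @param predictor Numeric predictor per cell.
#' @param onset Logical/0-1 outcome: granule present by the horizon.
#' @param n_knots,lambda_grid,n_grid As in
#'   [fit_penalized_spline_hazard()].
#'
#' @return A `spline_onset_fit`: `lambda`, `edf`, `loglik`, `p`, a
#'   `curve` data.frame (`x`, `prob`, `lo`, `hi` on the probability
#'   scale), and `predict_fn(x)` returning onset probabilities.
#' @export
fit_granule_onset_model <- function(predictor, onset, n_knots = 8L,
                                    lambda_grid = 10^seq(-2, 6,
                                                         length.out = 30),
                                    n_grid = 100L) {
  ok <- is.finite(predictor) & !is.na(onset)
  x <- predictor[ok]
  y <- as.integer(onset[ok])
  if (!all(y %in% 0:1)) stop("onset must be logical or 0/1")
  if (all(y == 1L) || all(y == 0L)) stop("degenerate outcome")
  if (diff(range(x)) <= 0) stop("no variation in predictor")
  basis <- spline_basis(x, n_knots)
  B <- eval_basis(basis, x)
  k <- ncol(B)
  Z <- drop_constant_dir(k)
  X <- cbind(1, B %*% Z)
  P <- matrix(0, ncol(X), ncol(X))
  P[-1, -1] <- t(Z) %*% curvature_penalty(basis) %*% Z

  loglik <- function(eta) {
    mu <- plogis(eta)
    sum(y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300)))
  }
  irls <- function(lambda, beta0 = NULL) {
    beta <- beta0 %||% c(qlogis(mean(y)), numeric(ncol(X) - 1L))
    for (it in 1:100) {
      eta <- drop(X %*% beta)
      mu <- plogis(eta)
      w <- pmax(mu * (1 - mu), 1e-10)
      z <- eta + (y - mu) / w
      XtW <- t(X * w)
      A <- XtW %*% X + lambda * P
      beta_new <- solve(A, XtW %*% z)
      if (max(abs(beta_new - beta)) < 1e-8) { beta <- beta_new; break }
      beta <- drop(beta_new)
    }
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    Ihat <- t(X * w) %*% X
    A <- Ihat + lambda * P
    edf <- sum(diag(solve(A, Ihat)))
    list(beta = drop(beta), loglik = loglik(eta), edf = edf,
         aic = -2 * loglik(eta) + 2 * edf, info = Ihat, A = A,
         lambda = lambda)
  }
  grid <- sort(lambda_grid, decreasing = TRUE)
  fits <- vector("list", length(grid))
  beta <- NULL
  for (i in seq_along(grid)) {
    fits[[i]] <- irls(grid[i], beta0 = beta)
    beta <- fits[[i]]$beta
  }
  aics <- vapply(fits, `[[`, 0, "aic")
  best <- fits[[which.min(aics)]]
  null_ll <- loglik(rep(qlogis(mean(y)), length(y)))
  lrt <- 2 * (best$loglik - null_ll)
  # null information with the intercept profiled out
  w0 <- mean(y) * (1 - mean(y))
  H0_full <- w0 * crossprod(X)
  H0 <- H0_full[-1, -1, drop = FALSE] -
    tcrossprod(H0_full[-1, 1]) / H0_full[1, 1]
  t_obs <- max(2 * (vapply(fits, `[[`, 0, "loglik") - null_ll) -
                 2 * (vapply(fits, `[[`, 0, "edf") - 1))
  p <- selection_pvalue(H0, P[-1, -1, drop = FALSE], grid, t_obs)

  V <- solve(best$A)      # Bayesian covariance, as in the hazard model
  beta <- best$beta
  predict_fn <- function(xnew) {
    Xn <- cbind(1, eval_basis(basis, xnew) %*% Z)
    plogis(drop(Xn %*% beta))
  }
  xg <- seq(basis$range[1], basis$range[2], length.out = n_grid)
  Xg <- cbind(1, eval_basis(basis, xg) %*% Z)
  eta_g <- drop(Xg %*% beta)
  se_g <- sqrt(pmax(rowSums((Xg %*% V) * Xg), 0))
  curve <- data.frame(x = xg, prob = plogis(eta_g),
                      lo = plogis(eta_g - 1.96 * se_g),
                      hi = plogis(eta_g + 1.96 * se_g))
  structure(list(
    knots = basis$knots, degree = basis$degree, coefficients = beta,
    lambda = best$lambda, edf = best$edf, loglik = best$loglik,
    null_loglik = null_ll, lrt = lrt, p = p, curve = curve,
    predict_fn = predict_fn, n = length(y), n_onset = sum(y)
  ), class = "spline_onset_fit")
}

#' @export
print.spline_onset_fit <- function(x, ...) {
  cat(sprintf(
    "Penalized-spline onset model (n = %d, %d onsets)\n  lambda = %.3g, edf = %.2f, LRT = %.2f, p = %.3g\n",
    x$n, x$n_onset, x$lambda, x$edf, x$lrt, x$p))
  invisible(x)
}
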