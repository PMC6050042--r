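test_that("FRAP normalization inverts the generating recovery", {
  A <- 0.6; tau <- 0.05
  sz <- 40
  gm <- lfmkit:::disc_mask(c(sz, sz), 19.5, 19.5, 10)
  bm <- gm; bm[, 1:20] <- FALSE            # bleach the right half
  pre <- array(0, c(sz, sz, 3))
  for (i in 1:3) { m <- matrix(0, sz, sz); m[gm] <- 100; pre[, , i] <- m }
  times <- seq(0, 300, by = 10)
  gi <- sum(gm) * 100
  f0 <- sum(bm) * 100 / gi
  post <- array(0, c(sz, sz, length(times)))
  for (i in seq_along(times)) {
    m <- matrix(0, sz, sz); m[gm] <- 100
    m[bm] <- (0.2 * f0 + A * (1 - exp(-tau * times[i]))) * gi / sum(bm)
    post[, , i] <- m
  }
  tr <- normalize_frap(pre, post, gm, bm, times, register = FALSE)
  expect_equal(tr$recovery[1], 0)
  expect_equal(tr$recovery, A * (1 - exp(-tau * times)), tolerance = 1e-6)
  expect_equal(attr(tr, "bleach_roi_area_um2"), sum(bm))
  fit <- fit_recovery(tr)
  expect_equal(fit$A, A, tolerance = 1e-6)
  expect_equal(fit$tau, tau, tolerance = 1e-6)
  # identical pre/post frames: nothing was bleached
  expect_error(normalize_frap(pre, pre, gm, bm, c(0, 10, 20),
                              register = FALSE), "ineffective bleach")
  bad <- bm; bad[1, 1] <- TRUE
  expect_error(normalize_frap(pre, post, gm, bad, times, register = FALSE),
               "inside the granule")
})

test_that("recovery fitting is exact without noise and robust with it", {
  tr <- simulate_frap_trace(0.8, 0.1, duration = 600, dt = 10, noise_sd = 0)
  f <- fit_recovery(tr)
  expect_equal(f$A, 0.8, tolerance = 1e-6)
  expect_equal(f$tau, 0.1, tolerance = 1e-6)
  expect_equal(f$t_half, log(2) / 0.1, tolerance = 1e-6)
  ok <- vapply(1:10, function(s) {
    tn <- simulate_frap_trace(0.8, 0.1, noise_sd = 0.05, seed = s)
    fn <- fit_recovery(tn)
    abs(fn$A - 0.8) / 0.8 <= 0.1 && abs(fn$tau - 0.1) / 0.1 <= 0.1
  }, TRUE)
  expect_gte(mean(ok), 0.9)
  expect_error(fit_recovery(frap_trace(seq(0, 100, 10), rep(0, 11))),
               "non-convergence")
  expect_error(fit_recovery(frap_trace(c(0, 1, 2), c(0, 0.1, 0.2))),
               "5 points")
})

test_that("half-time, diffusion, Stokes radius follow their closed forms", {
  expect_equal(half_time(log(2)), 1)
  expect_equal(half_time(0.1), 6.931472, tolerance = 1e-6)
  expect_equal(half_time(0.2), half_time(0.1) / 2)
  expect_error(half_time(0), "positive")
  expect_equal(diffusion_coefficient(pi, 1), 0.22)
  expect_equal(diffusion_coefficient(pi, 0.88), 0.25)
  expect_equal(diffusion_coefficient(2 * pi, 1),
               2 * diffusion_coefficient(pi, 1))
  expect_error(diffusion_coefficient(-1, 1), "positive")
  expect_equal(stokes_radius(106.4), 3.13, tolerance = 0.005)
  expect_equal(stokes_radius(1), 0.66)
  expect_equal(stokes_radius(8), 1.32)
  expect_error(stokes_radius(0), "positive")
})

test_that("Einstein-Stokes viscosity is unit-coherent", {
  # hand arithmetic: kB*T = 1.380649e-23 * 310.15 = 4.282083e-21 J;
  # 6*pi*D*r = 6*pi * 1e-12 * 3.13e-9 = 5.899910e-20 -> eta = 0.0725788
  expect_equal(viscosity(1, 310.15, 3.13), 0.0725788, tolerance = 1e-6)
  expect_equal(viscosity(2, 310.15, 3.13), viscosity(1, 310.15, 3.13) / 2)
  expect_equal(viscosity(1, 310.15, 6.26), viscosity(1, 310.15, 3.13) / 2)
  # round trip: water-like eta at 298 K, r = 1 nm
  eta <- 0.001
  D <- 1.380649e-23 * 298 / (6 * pi * eta * 1e-9) * 1e12
  expect_equal(viscosity(D, 298, 1), eta, tolerance = 1e-12)
  expect_error(viscosity(-1, 310, 3), "positive")
})

test_that("frap_report chains the full kinetic parameter set", {
  tr <- simulate_frap_trace(0.6, 0.05, noise_sd = 0,
                            bleach_roi_area_um2 = 2 * pi)
  rep <- frap_report(tr, M_kda = 106.4)
  expect_equal(rep$w2_um2, 2)
  expect_equal(rep$D_um2_s, 0.88 * 2 / (4 * log(2) / 0.05), tolerance = 1e-6)
  expect_equal(rep$stokes_radius_nm, stokes_radius(106.4))
  expect_equal(rep$eta_pa_s,
               viscosity(rep$D_um2_s, 310.15, rep$stokes_radius_nm))
  # slower recovery at fixed area -> smaller D -> higher viscosity
  rep_slow <- frap_report(simulate_frap_trace(0.6, 0.01, duration = 600,
                                              dt = 5, noise_sd = 0,
                                              bleach_roi_area_um2 = 2 * pi),
                          M_kda = 106.4)
  expect_lt(rep_slow$D_um2_s, rep$D_um2_s)
  expect_gt(rep_slow$eta_pa_s, rep$eta_pa_s)
})

test_that("OPL half-life fitting matches the closed form and flags rises", {
  tr <- simulate_opl_trace(24, n_timepoints = 5, interval = 24, noise_cv = 0)
  f <- fit_opl_halflife(tr)
  expect_equal(f$half_life_h, 24, tolerance = 1e-10)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  # scale invariance
  tr5 <- tr; tr5$intensity <- tr5$intensity * 5
  expect_equal(fit_opl_halflife(tr5)$half_life_h, 24, tolerance = 1e-10)
  # rising signal flagged invalid
  rising <- data.frame(time_h = 0:5, intensity = 2^(0:5))
  expect_false(fit_opl_halflife(rising)$valid)
  expect_error(fit_opl_halflife(data.frame(time_h = 0:3,
                                           intensity = c(1, 2, 0, 4))),
               "positive")
  ok <- vapply(1:10, function(s) {
    o <- simulate_opl_trace(24, noise_cv = 0.05, seed = s)
    abs(fit_opl_halflife(o)$half_life_h - 24) / 24 <= 0.05
  }, TRUE)
  expect_gte(mean(ok), 0.9)
})
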