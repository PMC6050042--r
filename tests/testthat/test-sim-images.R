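test_that("noise-free fields render one bright component per live cell", {
  cfg <- sim_config(n_cells = 3, field_size = c(128, 128),
                    baseline_hazard = 0, read_noise_frac = 0,
                    neurites = FALSE, total_days = 5, seed = 21)
  sim <- simulate_timelapse(cfg)
  for (f in seq_along(sim$truth$timestamps_h)) {
    img <- sim$stack$channels$reporter[, , f]
    lab <- EBImage::bwlabel(img > lfmkit:::otsu_threshold(img))
    expect_equal(max(lab), 3)
  }
})

test_that("a dying cell decays to background within one frame", {
  cfg <- sim_config(n_cells = 1, field_size = c(64, 64),
                    fixed_death_days = 4, read_noise_frac = 0.02,
                    seed = 22)
  sim <- simulate_timelapse(cfg)
  noise_sd <- cfg$read_noise_frac * max(exp(cfg$expression_meanlog),
                                        cfg$morphology_peak)
  day5 <- sim$stack$channels$reporter[, , 5]
  expect_lte(mean(day5), cfg$background + 3 * noise_sd)
  expect_equal(sim$truth$cells$death_frame, 4L)
})

test_that("timelapse simulation is deterministic and validates config", {
  cfg <- sim_config(n_cells = 10, field_size = c(192, 192), seed = 23)
  a <- simulate_timelapse(cfg)
  b <- simulate_timelapse(cfg)
  expect_identical(a$stack$channels, b$stack$channels)
  expect_identical(a$truth$cells, b$truth$cells)
  expect_error(sim_config(n_cells = 0, seed = 1), "empty cohort")
  expect_error(
    simulate_timelapse(sim_config(n_cells = 100, field_size = c(48, 48),
                                  seed = 2)),
    "field too small")
})

test_that("granule state is monotone once acquired", {
  cfg <- sim_config(n_cells = 40, puncta_contrast = 2,
                    granule_onset_intercept = -1, granule_onset_slope = 4,
                    baseline_hazard = 0, seed = 24)
  sim <- simulate_timelapse(cfg)
  g <- sim$truth$granular
  expect_true(all(g[, -1] >= g[, -ncol(g)]))
})

test_that("nuclear image classes are indistinguishable at zero contrast", {
  nd <- simulate_nuclear_images(100, 100, puncta_contrast = 0, seed = 12)
  cvs <- vapply(nd, function(x) nuclear_cv(x$image, x$mask), 1)
  lab <- vapply(nd, `[[`, "", "label")
  ks <- suppressWarnings(
    ks.test(cvs[lab == "granular"], cvs[lab == "diffuse"]))
  expect_gt(ks$p.value, 0.01)
})

test_that("granular nuclei carry higher CV at high contrast", {
  # puncta ~10x the diffuse background level
  nuc <- simulate_nuclear_images(50, 50, puncta_contrast = 10,
                                 contrast_sdlog = 0, seed = 13)
  cvs <- vapply(nuc, function(x) nuclear_cv(x$image, x$mask), 1)
  lab <- vapply(nuc, `[[`, "", "label")
  expect_gt(mean(cvs[lab == "granular"]), mean(cvs[lab == "diffuse"]))
  expect_identical(simulate_nuclear_images(5, 5, seed = 9),
                   simulate_nuclear_images(5, 5, seed = 9))
  expect_error(simulate_nuclear_images(0, 0, seed = 1), "both counts")
})
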