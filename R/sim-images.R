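# Rendering helpers -----------------------------------------------------

# Add an anisotropic Gaussian blob to `img` (matrix, rows = y, cols = x).
# (x0, y0) are 0-based pixel coordinates; sigma_u/sigma_v the major/minor
# axis sds in px; theta the major-axis angle. Values add onto the image.
add_gaussian_blob <- function(img, x0, y0, sigma_u, sigma_v, theta, peak,
                              cutoff = 3.5) {
  w <- ceiling(cutoff * max(sigma_u, sigma_v))
  rows <- max(1L, floor(y0 + 1 - w)):min(nrow(img), ceiling(y0 + 1 + w))
  cols <- max(1L, floor(x0 + 1 - w)):min(ncol(img), ceiling(x0 + 1 + w))
  if (length(rows) == 0L || length(cols) == 0L) return(img)
  dy <- (rows - 1) - y0
  dx <- (cols - 1) - x0
  du <- outer(dy, dx, function(y, x)  cos(theta) * x + sin(theta) * y)
  dv <- outer(dy, dx, function(y, x) -sin(theta) * x + cos(theta) * y)
  img[rows, cols] <- img[rows, cols] +
    peak * exp(-0.5 * ((du / sigma_u)^2 + (dv / sigma_v)^2))
  img
}

# Add a thin line segment (a crude neurite) of given intensity.
add_segment <- function(img, x0, y0, angle, length, intensity) {
  t <- seq(0, length, by = 0.5)
  px <- round(x0 + t * cos(angle)) + 1L
  py <- round(y0 + t * sin(angle)) + 1L
  ok <- px >= 1L & px <= ncol(img) & py >= 1L & py <= nrow(img)
  idx <- unique(cbind(py[ok], px[ok]))
  img[idx] <- img[idx] + intensity
  img
}

#' Logical disc mask
#'
#' Convenience constructor for circular ROIs: `TRUE` inside a disc of
#' the given radius centred at 0-based pixel coordinates `(cx, cy)`.
#'
#' @param size Matrix size, `c(rows, cols)`.
#' @param cx,cy Centre (0-based pixel coordinates; x = column, y = row).
#' @param radius Radius in pixels.
#' @return A logical matrix.
#' @export
disc_mask <- function(size, cx, cy, radius) {
  dy <- (seq_len(size[1]) - 1) - cy
  dx <- (seq_len(size[2]) - 1) - cx
  outer(dy, dx, function(y, x) x^2 + y^2) <= radius^2
}

# Place n centres uniformly with a minimum pairwise separation.
place_cells <- function(n, field_size, min_sep, margin) {
  xs <- numeric(0); ys <- numeric(0)
  tries <- 0L
  while (length(xs) < n) {
    x <- runif(1, margin, field_size[2] - 1 - margin)
    y <- runif(1, margin, field_size[1] - 1 - margin)
    if (length(xs) == 0L || min((xs - x)^2 + (ys - y)^2) >= min_sep^2) {
      xs <- c(xs, x); ys <- c(ys, y); tries <- 0L
    } else {
      tries <- tries + 1L
      if (tries > 2000L)
        stop("field too small for requested number of cells")
    }
  }
  cbind(x = xs, y = ys)
}

# Configuration ----------------------------------------------------------

#' Configuration for the synthetic time-lapse generator
#'
#' Bundles and validates every parameter of the forward imaging model:
#' field geometry, cohort size, per-cell expression distribution
#' (log-normal, AU), survival model (baseline hazard per day plus group
#' log hazard ratios and/or a smooth log-hazard function of expression),
#' the imaging schedule, the granule-onset model (logistic in the
#' day-over-day expression ratio), and the camera noise model.
#'
#' @param field_size Image size in pixels, `c(rows, cols)`.
#' @param n_cells Number of cells in the field (> 0).
#' @param groups Character vector recycled over cells, or a single group.
#' @param expression_meanlog,expression_sdlog Log-normal expression (AU).
#' @param baseline_hazard Baseline death hazard per day (>= 0; 0 disables
#'   death).
#' @param group_log_hrs Named log hazard ratios per group.
#' @param log_hazard_fun Optional smooth log-hazard term g(expression).
#' @param start_h,interval_h,total_days Imaging schedule: first frame at
#'   `start_h` hours post-transfection, then every `interval_h` hours out
#'   to `total_days` days.
#' @param soma_radius_px,soma_radius_sd Mean and sd of soma radius (px).
#' @param soma_axis_ratio Major/minor axis ratio of live somata; dying
#'   somata round up to ratio 1.
#' @param morphology_peak Peak intensity of the cell-fill channel (AU).
#' @param neurites Render thin neurite segments in the morphology channel.
#' @param granule_onset_intercept,granule_onset_slope Logistic model for
#'   per-frame granule onset as a function of (expression ratio - 1).
#' @param n_puncta,puncta_radius_px,puncta_contrast Intranuclear puncta
#'   count, Gaussian radius (px), and amplitude relative to expression.
#' @param read_noise_frac Gaussian read-noise sd as a fraction of the
#'   median soma peak.
#' @param poisson_noise Add Poisson shot noise.
#' @param background Constant background level (AU).
#' @param drift_sd Per-frame centroid random-walk sd (px).
#' @param fixed_death_days Optional per-cell death days (NA = never);
#'   overrides the hazard model, for controlled experiments.
#' @param seed Integer seed (mandatory).
#'
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(field_size = c(320, 320), n_cells = 50,
                       groups = "control",
                       expression_meanlog = log(500),
                       expression_sdlog = 0.6,
                       baseline_hazard = 0.1,
                       group_log_hrs = NULL,
                       log_hazard_fun = NULL,
                       start_h = 24, interval_h = 24, total_days = 10,
                       soma_radius_px = 6, soma_radius_sd = 0.8,
                       soma_axis_ratio = 1.8,
                       morphology_peak = 200, neurites = TRUE,
                       granule_onset_intercept = -4,
                       granule_onset_slope = 6,
                       n_puncta = 4, puncta_radius_px = 1.5,
                       puncta_contrast = 0,
                       read_noise_frac = 0.02, poisson_noise = FALSE,
                       background = 10, drift_sd = 0.3,
                       fixed_death_days = NULL, seed) {
  if (n_cells == 0) stop("empty cohort: n_cells must be positive")
  stopifnot(n_cells > 0, all(field_size > 0), interval_h > 0,
            total_days > 0, start_h >= 0, soma_radius_px > 0,
            soma_axis_ratio >= 1, read_noise_frac >= 0, background >= 0,
            baseline_hazard >= 0, drift_sd >= 0, puncta_contrast >= 0)
  if (is.null(group_log_hrs)) {
    group_log_hrs <- setNames(rep(0, length(unique(groups))), unique(groups))
  }
  if (missing(seed)) stop("a seed is mandatory in sim_config")
  cfg <- list(
    field_size = field_size, n_cells = as.integer(n_cells), groups = groups,
    expression_meanlog = expression_meanlog,
    expression_sdlog = expression_sdlog,
    baseline_hazard = baseline_hazard, group_log_hrs = group_log_hrs,
    log_hazard_fun = log_hazard_fun,
    start_h = start_h, interval_h = interval_h, total_days = total_days,
    soma_radius_px = soma_radius_px, soma_radius_sd = soma_radius_sd,
    soma_axis_ratio = soma_axis_ratio, morphology_peak = morphology_peak,
    neurites = neurites,
    granule_onset_intercept = granule_onset_intercept,
    granule_onset_slope = granule_onset_slope,
    n_puncta = n_puncta, puncta_radius_px = puncta_radius_px,
    puncta_contrast = puncta_contrast,
    read_noise_frac = read_noise_frac, poisson_noise = poisson_noise,
    background = background, drift_sd = drift_sd,
    fixed_death_days = fixed_death_days, seed = seed
  )
  class(cfg) <- "sim_config"
  cfg
}

# Time-lapse simulator ---------------------------------------------------

#' Simulate a ground-truthed fluorescence time-lapse experiment
#'
#' Renders a two-channel (morphology + reporter) time-lapse stack of
#' Gaussian-profile somata with optional neurites and intranuclear
#' puncta. Cells die according to the configured proportional-hazards
#' model; a dying cell is rendered once as a rounded (eccentricity ~ 0),
#' dimmed soma at its death frame and disappears into background at the
#' next frame, mimicking the rounding-then-loss-of-fluorescence morphology
#' used to call death in live imaging.
#'
#' @param config A [sim_config()].
#' @return A list with `stack` (a [time_lapse_stack()]) and `truth` — the
#'   per-cell ground truth (positions per frame, radius, expression,
#'   death frame/day or censoring, granule state per frame).
#' @export
simulate_timelapse <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  with_seed(cfg$seed, {
    n <- cfg$n_cells
    timestamps <- seq(cfg$start_h, cfg$total_days * 24, by = cfg$interval_h)
    nf <- length(timestamps)
    group <- rep_len(cfg$groups, n)

    radius <- pmax(2, rnorm(n, cfg$soma_radius_px, cfg$soma_radius_sd))
    min_sep <- 4.5 * mean(radius)
    pos0 <- place_cells(n, cfg$field_size, min_sep, margin = 2 * max(radius))
    theta <- runif(n, 0, pi)
    expr <- rlnorm(n, cfg$expression_meanlog, cfg$expression_sdlog)
    morph_peak <- cfg$morphology_peak * rlnorm(n, 0, 0.1)

    # per-frame expression trajectory: per-cell growth + wobble
    growth <- rlnorm(n, log(1.08), 0.08)
    expr_f <- matrix(0, n, nf)
    expr_f[, 1] <- expr
    for (f in 2:max(2, nf)) if (f <= nf)
      expr_f[, f] <- expr_f[, f - 1] * growth * rlnorm(n, 0, 0.05)

    # true death times (continuous days), then the frame where observed
    if (!is.null(cfg$fixed_death_days)) {
      t_true <- rep_len(cfg$fixed_death_days, n)
    } else if (cfg$baseline_hazard > 0) {
      eta <- cfg$group_log_hrs[group]
      if (!is.null(cfg$log_hazard_fun)) eta <- eta + cfg$log_hazard_fun(expr)
      t_true <- rexp(n) / (cfg$baseline_hazard * exp(eta))
    } else {
      t_true <- rep(NA_real_, n)
    }
    death_frame <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      if (!is.na(t_true[i])) {
        f <- which(timestamps >= t_true[i] * 24)
        if (length(f) > 0) death_frame[i] <- f[1]
      }
    }

    # granule onset: logistic in day-over-day expression ratio, monotone
    granular <- matrix(FALSE, n, nf)
    if (cfg$puncta_contrast > 0 && nf >= 2) {
      for (f in 2:nf) {
        ratio <- expr_f[, f] / expr_f[, f - 1]
        p_on <- plogis(cfg$granule_onset_intercept +
                         cfg$granule_onset_slope * (ratio - 1))
        granular[, f] <- granular[, f - 1] | (runif(n) < p_on)
      }
    }
    # fixed puncta offsets per cell (relative to centroid)
    puncta <- lapply(seq_len(n), function(i) {
      k <- max(1L, rpois(1, cfg$n_puncta))
      r <- radius[i] * 0.45 * sqrt(runif(k))
      a <- runif(k, 0, 2 * pi)
      cbind(dx = r * cos(a), dy = r * sin(a))
    })

    drift <- array(0, dim = c(n, 2, nf))
    if (cfg$drift_sd > 0 && nf >= 2) {
      for (f in 2:nf)
        drift[, , f] <- drift[, , f - 1] +
          matrix(rnorm(2 * n, 0, cfg$drift_sd), n, 2)
    }

    ar <- cfg$soma_axis_ratio
    sig_u <- radius * sqrt(ar)   # major axis sd
    sig_v <- radius / sqrt(ar)   # minor axis sd
    neurite_angles <- lapply(seq_len(n), function(i) runif(3, 0, 2 * pi))

    morph <- array(0, dim = c(cfg$field_size, nf))
    repr  <- array(0, dim = c(cfg$field_size, nf))
    noise_sd <- cfg$read_noise_frac *
      max(exp(cfg$expression_meanlog), cfg$morphology_peak)

    for (f in seq_len(nf)) {
      im <- matrix(cfg$background, cfg$field_size[1], cfg$field_size[2])
      ir <- matrix(cfg$background, cfg$field_size[1], cfg$field_size[2])
      for (i in seq_len(n)) {
        dead_before <- !is.na(death_frame[i]) && f > death_frame[i]
        if (dead_before) next
        x <- pos0[i, 1] + drift[i, 1, f]
        y <- pos0[i, 2] + drift[i, 2, f]
        dying <- !is.na(death_frame[i]) && f == death_frame[i]
        if (dying) {
          # rounded, dimmed soma: eccentricity -> 0, then gone next frame
          s <- radius[i]
          im <- add_gaussian_blob(im, x, y, s, s, 0, 0.4 * morph_peak[i])
          ir <- add_gaussian_blob(ir, x, y, s, s, 0, 0.4 * expr_f[i, f])
        } else {
          im <- add_gaussian_blob(im, x, y, sig_u[i], sig_v[i], theta[i],
                                  morph_peak[i])
          ir <- add_gaussian_blob(ir, x, y, sig_u[i], sig_v[i], theta[i],
                                  expr_f[i, f])
          if (cfg$neurites)
            for (a in neurite_angles[[i]])
              im <- add_segment(im, x, y, a, 2.5 * radius[i],
                                0.18 * morph_peak[i])
          if (granular[i, f]) {
            for (p in seq_len(nrow(puncta[[i]])))
              ir <- add_gaussian_blob(ir, x + puncta[[i]][p, 1],
                                      y + puncta[[i]][p, 2],
                                      cfg$puncta_radius_px,
                                      cfg$puncta_radius_px, 0,
                                      cfg$puncta_contrast * expr_f[i, f])
          }
        }
      }
      if (noise_sd > 0) {
        im <- im + matrix(rnorm(length(im), 0, noise_sd), nrow(im))
        ir <- ir + matrix(rnorm(length(ir), 0, noise_sd), nrow(ir))
      }
      if (cfg$poisson_noise) {
        im[] <- rpois(length(im), pmax(im, 0))
        ir[] <- rpois(length(ir), pmax(ir, 0))
      }
      morph[, , f] <- pmax(im, 0)
      repr[, , f]  <- pmax(ir, 0)
    }

    stack <- time_lapse_stack(list(morphology = morph, reporter = repr),
                              timestamps_h = timestamps)
    positions <- array(rep(t(pos0), nf), dim = c(2, n, nf))
    positions <- aperm(positions, c(2, 1, 3)) + drift

    truth <- list(
      cells = data.frame(
        id = seq_len(n), group = group,
        x0 = pos0[, 1], y0 = pos0[, 2], radius = radius,
        expression = expr, morph_peak = morph_peak,
        death_frame = death_frame,
        death_day = timestamps[death_frame] / 24,
        true_death_day = t_true,
        censored = is.na(death_frame),
        stringsAsFactors = FALSE
      ),
      positions = positions,       # n x (x,y) x frames, 0-based px
      expression_by_frame = expr_f,
      granular = granular,
      timestamps_h = timestamps,
      config = cfg
    )
    list(stack = stack, truth = truth)
  })
}

# Nuclear image simulator ------------------------------------------------

#' Simulate annotated nuclear reporter images
#'
#' Generates small single-nucleus reporter images with known
#' granular/diffuse labels, emulating the hand-annotated set used to
#' calibrate a CV-based granule classifier. Granular nuclei carry bright
#' puncta on a partially depleted diffuse background (total signal is
#' redistributed, not added); diffuse nuclei carry only smooth large-scale
#' heterogeneity. At `puncta_contrast = 0` the two classes are generated
#' by an identical process.
#'
#' Per-nucleus puncta contrast is log-normally dispersed around
#' `puncta_contrast`, so classes overlap as they do in real data rather
#' than separating perfectly.
#'
#' @param n_granular,n_diffuse Number of nuclei per class (>= 0, not both
#'   zero).
#' @param puncta_contrast Mean puncta amplitude relative to the diffuse
#'   nuclear level (>= 0).
#' @param contrast_sdlog Log-sd of per-nucleus contrast dispersion.
#' @param n_puncta Mean puncta count per granular nucleus (Poisson, >= 1).
#' @param puncta_radius_px Gaussian radius of puncta (px).
#' @param nucleus_radius Nuclear disc radius (px).
#' @param base_intensity Diffuse nuclear level (AU).
#' @param noise_sd Additive Gaussian noise sd (AU).
#' @param image_size Image side length (px).
#' @param seed Integer seed (mandatory).
#'
#' @return A list of `length n_granular + n_diffuse`, each element a list
#'   with `image`, `mask` (logical nuclear mask) and `label`
#'   (`"granular"` or `"diffuse"`).
#' @export
simulate_nuclear_images <- function(n_granular, n_diffuse,
                                    puncta_contrast = 2.5,
                                    contrast_sdlog = 0.6,
                                    n_puncta = 4, puncta_radius_px = 1.8,
                                    nucleus_radius = 9,
                                    base_intensity = 100, noise_sd = 10,
                                    image_size = 32, seed) {
  stopifnot(n_granular >= 0, n_diffuse >= 0)
  if (n_granular + n_diffuse == 0) stop("both counts are zero")
  stopifnot(puncta_contrast >= 0, noise_sd >= 0)
  with_seed(seed, {
    cx <- (image_size - 1) / 2
    mask <- disc_mask(c(image_size, image_size), cx, cx, nucleus_radius)
    labels <- c(rep("granular", n_granular), rep("diffuse", n_diffuse))
    lapply(labels, function(lab) {
      img <- matrix(0, image_size, image_size)
      # chromatin-scale texture shared by both classes: what keeps the
      # diffuse-class CV well away from zero, as in real nuclei
      nb <- 8L
      for (b in seq_len(nb)) {
        a <- runif(1, 0, 2 * pi); r <- nucleus_radius * 0.7 * sqrt(runif(1))
        img <- add_gaussian_blob(img, cx + r * cos(a), cx + r * sin(a),
                                 nucleus_radius * 0.25, nucleus_radius * 0.25,
                                 0, base_intensity * runif(1, -0.65, 0.65))
      }
      contrast <- if (lab == "granular" && puncta_contrast > 0)
        puncta_contrast * rlnorm(1, 0, contrast_sdlog) else 0
      deplete <- 0.35 * contrast / (1 + contrast)
      img <- img + base_intensity * (1 - deplete)
      if (contrast > 0) {
        k <- max(1L, rpois(1, n_puncta))
        for (p in seq_len(k)) {
          a <- runif(1, 0, 2 * pi)
          r <- (nucleus_radius - puncta_radius_px - 1) * sqrt(runif(1))
          img <- add_gaussian_blob(img, cx + r * cos(a), cx + r * sin(a),
                                   puncta_radius_px, puncta_radius_px, 0,
                                   base_intensity * contrast)
        }
      }
      img <- img + matrix(rnorm(length(img), 0, noise_sd), image_size)
      img <- pmax(img, 0)
      img[!mask] <- 0
      list(image = img, mask = mask, label = lab)
    })
  })
}
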