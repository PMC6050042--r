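# Segmentation -----------------------------------------------------------

# Shoelace polygon area of the convex hull of a pixel point set.
hull_area <- function(x, y) {
  pts <- unique(cbind(x, y))
  if (nrow(pts) < 3L) return(nrow(pts))
  h <- chull(pts)
  hx <- pts[h, 1]; hy <- pts[h, 2]
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
}

#' Segment somata in one frame of a time-lapse stack
#'
#' Thresholds the requested channel (Otsu by default, optionally with an
#' absolute intensity floor), labels connected components, and filters
#' them by pixel area and solidity, mirroring the size / morphology /
#' intensity criteria used to draw single-neuron ROIs in automated
#' longitudinal imaging.
#'
#' @param stack A [time_lapse_stack()].
#' @param frame Frame index (1-based).
#' @param channel Channel name to segment on (default `"morphology"`).
#' @param min_area,max_area Area filter in pixels (`min_area < max_area`).
#' @param threshold_policy `"otsu"` (per-frame Otsu, with `abs_floor` as a
#'   lower bound if given) or `"absolute"` (use `abs_floor` directly).
#' @param abs_floor Absolute intensity floor (AU).
#' @param min_solidity Minimum area / convex-hull-area ratio.
#'
#' @return A `frame_rois` object: list with `labels` (integer label
#'   matrix) and `rois`, a data.frame with one row per ROI: `label`,
#'   0-based centroid `x`, `y`, `area`, `eccentricity`, `solidity`, and
#'   per-channel `mean_*` and `total_*` intensities.
#' @export
segment_frame <- function(stack, frame, channel = "morphology",
                          min_area = 20, max_area = 5000,
                          threshold_policy = c("otsu", "absolute"),
                          abs_floor = NULL, min_solidity = 0.3) {
  threshold_policy <- match.arg(threshold_policy)
  stopifnot(min_area < max_area)
  img <- get_frame(stack, channel, frame)
  thr <- switch(threshold_policy,
    otsu = max(otsu_threshold(img), abs_floor %||% -Inf),
    absolute = {
      if (is.null(abs_floor)) stop("absolute policy requires `abs_floor`")
      abs_floor
    })
  bw <- img > thr
  empty <- function() {
    structure(list(labels = matrix(0L, nrow(img), ncol(img)),
                   rois = roi_feature_frame(stack, frame, integer(0),
                                            integer(0)),
                   frame = frame, channel = channel, threshold = thr),
              class = "frame_rois")
  }
  if (!any(bw)) return(empty())
  lab <- EBImage::bwlabel(bw)
  lab <- matrix(as.integer(lab), nrow(img), ncol(img))
  idx <- which(lab > 0L)
  feats <- roi_feature_frame(stack, frame, idx, lab[idx])
  keep <- feats$area >= min_area & feats$area <= max_area &
    feats$solidity >= min_solidity
  drop_labels <- feats$label[!keep]
  if (length(drop_labels)) lab[lab %in% drop_labels] <- 0L
  feats <- feats[keep, , drop = FALSE]
  # relabel 1..k for uniqueness/compactness
  if (nrow(feats)) {
    new_ids <- seq_len(nrow(feats))
    lab[lab > 0L] <- new_ids[match(lab[lab > 0L], feats$label)]
    feats$label <- new_ids
  }
  rownames(feats) <- NULL
  structure(list(labels = lab, rois = feats, frame = frame,
                 channel = channel, threshold = thr),
            class = "frame_rois")
}

# Compute per-ROI features from flat pixel indices and their labels.
roi_feature_frame <- function(stack, frame, idx, labs) {
  ch_names <- names(stack$channels)
  if (length(idx) == 0L) {
    out <- data.frame(label = integer(0), x = numeric(0), y = numeric(0),
                      area = integer(0), eccentricity = numeric(0),
                      solidity = numeric(0))
    for (ch in ch_names) {
      out[[paste0("mean_", ch)]] <- numeric(0)
      out[[paste0("total_", ch)]] <- numeric(0)
    }
    return(out)
  }
  nr <- dim(stack$channels[[1]])[1]
  y <- (idx - 1L) %% nr          # 0-based row
  x <- (idx - 1L) %/% nr         # 0-based col
  f <- factor(labs)
  ulab <- as.integer(levels(f))
  area <- as.integer(tabulate(f))
  mx <- tapply(x, f, mean); my <- tapply(y, f, mean)
  # second central moments -> eccentricity of the equivalent ellipse
  mxx <- tapply(x^2, f, mean) - mx^2
  myy <- tapply(y^2, f, mean) - my^2
  mxy <- tapply(x * y, f, mean) - mx * my
  tr2 <- (mxx + myy) / 2
  det_rt <- sqrt(pmax(((mxx - myy) / 2)^2 + mxy^2, 0))
  l1 <- tr2 + det_rt
  l2 <- pmax(tr2 - det_rt, 0)
  ecc <- ifelse(l1 > 0, sqrt(pmax(1 - l2 / pmax(l1, 1e-12), 0)), 0)
  sol <- vapply(levels(f), function(l) {
    s <- labs == as.integer(l)
    ha <- hull_area(x[s], y[s])
    if (ha <= 0) 1 else min(sum(s) / ha, 1)
  }, 1)
  out <- data.frame(label = ulab, x = as.numeric(mx), y = as.numeric(my),
                    area = area, eccentricity = as.numeric(ecc),
                    solidity = as.numeric(sol))
  for (ch in ch_names) {
    v <- stack$channels[[ch]][, , frame][idx]
    m <- tapply(v, f, mean)
    out[[paste0("mean_", ch)]] <- as.numeric(m)
    out[[paste0("total_", ch)]] <- as.numeric(m) * area
  }
  out
}

#' Segment every frame of a stack
#'
#' @inheritParams segment_frame
#' @param ... Passed to [segment_frame()].
#' @return A list of `frame_rois`, one per frame.
#' @export
segment_stack <- function(stack, ...) {
  lapply(seq_len(n_frames(stack)), function(f) segment_frame(stack, f, ...))
}

# Tracking ---------------------------------------------------------------

#' Track segmented cells across frames
#'
#' Greedy mutual-nearest-centroid linking: candidate (track, ROI) pairs
#' within `max_displacement` are assigned in order of increasing distance
#' (ties broken by smaller distance, then smaller label id); unmatched
#' ROIs seed new tracks; a track unmatched for more than `gap_frames`
#' consecutive frames stops being a linking candidate (it has vanished —
#' a death or a departure, resolved later by [call_death()]).
#'
#' @param stack A [time_lapse_stack()].
#' @param per_frame_rois List of `frame_rois` (one per frame), e.g. from
#'   [segment_stack()].
#' @param max_displacement Maximum linking distance in px; default twice
#'   the median equivalent soma radius of the first non-empty frame.
#' @param gap_frames Frames a track may go unobserved and still relink.
#'
#' @return List of `cell_track` objects, each with `id`, an `obs`
#'   data.frame (frame, time_h, x, y, area, eccentricity, per-channel
#'   means/totals) and bookkeeping fields used by [call_death()].
#' @export
track_cells <- function(stack, per_frame_rois, max_displacement = NULL,
                        gap_frames = 1L) {
  nf <- n_frames(stack)
  if (nf == 0L || length(per_frame_rois) != nf)
    stop("ROIs must be supplied for every frame of a non-empty stack")
  if (is.null(max_displacement)) {
    for (fr in per_frame_rois) {
      if (nrow(fr$rois)) {
        max_displacement <- 2 * median(sqrt(fr$rois$area / pi))
        break
      }
    }
    max_displacement <- max_displacement %||% 10
  }
  tracks <- list()        # each: list(obs = list of rows, last_frame, last_x, last_y)
  for (f in seq_len(nf)) {
    rois <- per_frame_rois[[f]]$rois
    active <- which(vapply(tracks, function(tr)
      tr$last_frame >= f - 1L - gap_frames, TRUE))
    assigned_roi <- rep(FALSE, nrow(rois))
    if (length(active) && nrow(rois)) {
      tx <- vapply(tracks[active], `[[`, 0, "last_x")
      ty <- vapply(tracks[active], `[[`, 0, "last_y")
      d <- sqrt(outer(tx, rois$x, "-")^2 + outer(ty, rois$y, "-")^2)
      cand <- which(d <= max_displacement, arr.ind = TRUE)
      if (nrow(cand)) {
        ord <- order(d[cand], rois$label[cand[, 2]])
        cand <- cand[ord, , drop = FALSE]
        used_tr <- rep(FALSE, length(active))
        for (k in seq_len(nrow(cand))) {
          i <- cand[k, 1]; j <- cand[k, 2]
          if (used_tr[i] || assigned_roi[j]) next
          used_tr[i] <- TRUE; assigned_roi[j] <- TRUE
          ti <- active[i]
          tracks[[ti]]$obs[[length(tracks[[ti]]$obs) + 1L]] <-
            cbind(frame = f, time_h = stack$timestamps_h[f], rois[j, ])
          tracks[[ti]]$last_frame <- f
          tracks[[ti]]$last_x <- rois$x[j]; tracks[[ti]]$last_y <- rois$y[j]
        }
      }
    }
    for (j in which(!assigned_roi)) {
      tracks[[length(tracks) + 1L]] <- list(
        obs = list(cbind(frame = f, time_h = stack$timestamps_h[f],
                         rois[j, ])),
        last_frame = f, last_x = rois$x[j], last_y = rois$y[j])
    }
  }
  d <- dim(stack$channels[[1]])
  lapply(seq_along(tracks), function(i) {
    obs <- do.call(rbind, tracks[[i]]$obs)
    rownames(obs) <- NULL
    structure(list(id = i, group = NA_character_, obs = obs,
                   timestamps_h = stack$timestamps_h,
                   field_size = d[1:2],
                   status = "unclassified",
                   death_time = NA_real_, censor_time = NA_real_),
              class = "cell_track")
  })
}

# Death calling ----------------------------------------------------------

#' Classify a track as dead, censored alive, or lost
#'
#' Applies the qualitative live-imaging death criteria — soma rounding,
#' loss of fluorescence, disappearance — as three quantitative rules, in
#' precedence order:
#' (a) the morphology-channel mean intensity falls below
#' `fluorescence_floor` times its initial value;
#' (b) the ROI vanishes and never reappears;
#' (c) eccentricity drops by at least `roundness_jump` between consecutive
#' observations and the intensity declines thereafter.
#' Death time is the timestamp (in days) of the first frame satisfying
#' the winning rule. A track whose last centroid lies within
#' `edge_margin` px of the field border is treated as having left the
#' field (`lost`) and is censored, as is a track that survives to the
#' last frame.
#'
#' @param track A `cell_track` from [track_cells()].
#' @param fluorescence_floor Fraction of initial intensity below which
#'   rule (a) fires.
#' @param roundness_jump Absolute eccentricity drop that arms rule (c).
#' @param channel Channel whose mean intensity drives rules (a) and (c).
#' @param edge_margin Border margin in px for the lost-cell heuristic.
#'
#' @return The track with `status` (`"dead"`, `"alive-at-end"`,
#'   `"lost"`), and exactly one of `death_time` / `censor_time` set (days).
#' @export
call_death <- function(track, fluorescence_floor = 0.25,
                       roundness_jump = 0.5, channel = "morphology",
                       edge_margin = 0) {
  obs <- track$obs
  if (nrow(obs) < 2L && length(track$timestamps_h) > 1L && obs$frame[1] ==
      length(track$timestamps_h)) {
    # single observation at the final frame: nothing to classify
    track$status <- "alive-at-end"
    track$censor_time <- obs$time_h[1] / 24
    return(track)
  }
  intens <- obs[[paste0("mean_", channel)]]
  ecc <- obs$eccentricity
  ts <- track$timestamps_h
  nf <- length(ts)

  # (a) fluorescence falls below floor x initial
  a_hit <- which(intens < fluorescence_floor * intens[1])
  t_a <- if (length(a_hit)) obs$time_h[a_hit[1]] else NA_real_

  # (b) vanishes and never reappears (track ends before the stack does)
  last_f <- obs$frame[nrow(obs)]
  at_edge <- FALSE
  if (edge_margin > 0) {
    lx <- obs$x[nrow(obs)]; ly <- obs$y[nrow(obs)]
    at_edge <- lx < edge_margin | ly < edge_margin |
      lx > track$field_size[2] - 1 - edge_margin |
      ly > track$field_size[1] - 1 - edge_margin
  }
  t_b <- if (last_f < nf && !at_edge) ts[last_f + 1L] else NA_real_

  # (c) rounding: eccentricity drop then declining intensity
  t_c <- NA_real_
  if (nrow(obs) >= 2L) {
    for (i in 2:nrow(obs)) {
      if (ecc[i] <= ecc[i - 1] - roundness_jump) {
        later <- intens[i:nrow(obs)]
        if (all(later <= intens[i - 1]) && (i == nrow(obs) ||
            all(diff(later) <= 0))) {
          t_c <- obs$time_h[i]
          break
        }
      }
    }
  }

  t_death <- if (!is.na(t_a)) t_a else if (!is.na(t_b)) t_b else t_c
  if (!is.na(t_death)) {
    track$status <- "dead"
    track$death_time <- t_death / 24
    track$censor_time <- NA_real_
    track$obs <- obs[obs$time_h <= t_death, , drop = FALSE]
  } else {
    track$status <- if (at_edge && last_f < nf) "lost" else "alive-at-end"
    track$death_time <- NA_real_
    track$censor_time <- obs$time_h[nrow(obs)] / 24
  }
  track
}

#' Extract a per-cell intensity time series
#'
#' One `(time_h, mean intensity)` point per frame in which the cell has
#' an ROI; frames where the cell was not observed are omitted, never
#' interpolated.
#'
#' @param track A `cell_track`.
#' @param channel Channel name.
#' @return data.frame with `time_h` and `mean`.
#' @export
extract_timeseries <- function(track, channel) {
  col <- paste0("mean_", channel)
  if (is.null(track$obs) || nrow(track$obs) == 0L)
    stop("track has no ROIs")
  if (!col %in% names(track$obs))
    stop(sprintf("channel '%s' not present on track", channel))
  data.frame(time_h = track$obs$time_h, mean = track$obs[[col]])
}

# Registration -----------------------------------------------------------

fft_freqs <- function(n) {
  f <- 0:(n - 1)
  ifelse(f > n / 2, f - n, f)
}

# Phase correlation with upsampled-DFT subpixel refinement. Returns the
# (dy, dx) by which `img` is displaced relative to `ref` (content moved
# down/right positive); applying the negated shift aligns img onto ref.
phase_corr_shift <- function(ref, img, upsample = 20L) {
  nr <- nrow(ref); nc <- ncol(ref)
  R <- fft(ref) * Conj(fft(img))
  R <- R / pmax(Mod(R), 1e-12)
  cc <- Re(fft(R, inverse = TRUE))
  pk <- which.max(cc) - 1L
  py <- pk %% nr; px <- pk %/% nr
  dy0 <- if (py > nr / 2) py - nr else py
  dx0 <- if (px > nc / 2) px - nc else px
  # refine on a +/-1 px window at 1/upsample resolution
  uy <- dy0 + seq(-1, 1, by = 1 / upsample)
  ux <- dx0 + seq(-1, 1, by = 1 / upsample)
  fy <- fft_freqs(nr) / nr
  fx <- fft_freqs(nc) / nc
  Ey <- exp(2i * pi * outer(uy, fy))          # |uy| x nr
  Ex <- exp(2i * pi * outer(fx, ux))          # nc x |ux|
  cc_fine <- Mod(Ey %*% R %*% Ex)
  best <- which(cc_fine == max(cc_fine), arr.ind = TRUE)[1, ]
  c(dy = -uy[best[1]], dx = -ux[best[2]])
}

# Translate image content by (dy, dx) pixels via the Fourier shift
# theorem (periodic boundary).
apply_shift <- function(img, dy, dx) {
  nr <- nrow(img); nc <- ncol(img)
  ph <- exp(-2i * pi * (outer(fft_freqs(nr) / nr * dy, rep(1, nc)) +
                          outer(rep(1, nr), fft_freqs(nc) / nc * dx)))
  Re(fft(fft(img) * ph, inverse = TRUE)) / (nr * nc)
}

rotate_bilinear <- function(img, angle_deg) {
  if (angle_deg == 0) return(img)
  a <- angle_deg * pi / 180
  nr <- nrow(img); nc <- ncol(img)
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  yy <- matrix(seq_len(nr), nr, nc) - cy
  xx <- matrix(rep(seq_len(nc), each = nr), nr, nc) - cx
  sy <- -sin(a) * xx + cos(a) * yy + cy
  sx <-  cos(a) * xx + sin(a) * yy + cx
  y0 <- floor(sy); x0 <- floor(sx)
  wy <- sy - y0; wx <- sx - x0
  gv <- function(r, c) {
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    v <- numeric(length(r)); v[ok] <- img[cbind(r[ok], c[ok])]
    v
  }
  out <- (1 - wy) * (1 - wx) * gv(y0, x0) + (1 - wy) * wx * gv(y0, x0 + 1) +
    wy * (1 - wx) * gv(y0 + 1, x0) + wy * wx * gv(y0 + 1, x0 + 1)
  matrix(out, nr, nc)
}

#' Rigid-body registration of a time-lapse stack
#'
#' Aligns every frame to a reference frame by translation (phase
#' correlation with upsampled-DFT subpixel refinement), optionally adding
#' a small-angle rotation grid search. Featureless frames yield a warning
#' and an identity transform.
#'
#' @param stack A [time_lapse_stack()] with at least 2 frames.
#' @param reference_frame Index of the reference frame.
#' @param channel Channel used to estimate the transforms (applied to all
#'   channels).
#' @param rotation If `TRUE`, search rotations in
#'   `seq(-max_angle, max_angle, angle_step)` degrees.
#' @param max_angle,angle_step Rotation search grid (degrees).
#' @return List with `stack` (aligned) and `transforms`, a data.frame of
#'   per-frame `dx`, `dy` (px, the applied correction) and `angle` (deg).
#' @export
register_stack <- function(stack, reference_frame = 1L,
                           channel = names(stack$channels)[1],
                           rotation = FALSE, max_angle = 5,
                           angle_step = 0.5) {
  nf <- n_frames(stack)
  if (nf < 2L) stop("registration needs at least 2 frames")
  ref <- get_frame(stack, channel, reference_frame)
  tf <- data.frame(frame = seq_len(nf), dx = 0, dy = 0, angle = 0)
  out <- stack
  for (f in seq_len(nf)) {
    if (f == reference_frame) next
    img <- get_frame(stack, channel, f)
    if (sd(img) < 1e-12 || sd(ref) < 1e-12) {
      warning(sprintf("frame %d featureless; identity transform", f))
      next
    }
    best_angle <- 0
    if (rotation) {
      angles <- seq(-max_angle, max_angle, by = angle_step)
      score <- vapply(angles, function(a) {
        r <- rotate_bilinear(img, a)
        cr <- fft(ref) * Conj(fft(r))
        max(Re(fft(cr / pmax(Mod(cr), 1e-12), inverse = TRUE)))
      }, 1)
      best_angle <- angles[which.max(score)]
      if (best_angle != 0) img <- rotate_bilinear(img, best_angle)
    }
    s <- phase_corr_shift(ref, img)   # displacement of img vs ref
    dy <- -s[["dy"]]; dx <- -s[["dx"]]   # correction to apply
    tf$dy[f] <- dy; tf$dx[f] <- dx; tf$angle[f] <- best_angle
    for (ch in names(out$channels)) {
      frm <- get_frame(stack, ch, f)
      if (best_angle != 0) frm <- rotate_bilinear(frm, best_angle)
      out$channels[[ch]][, , f] <- apply_shift(frm, dy, dx)
    }
  }
  list(stack = out, transforms = tf)
}
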