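# Ground-truth audits for the simulated imaging pipeline: every metric
# compares pipeline output against the simulator's SimGroundTruth.

#' Segmentation detection score against ground truth
#'
#' Greedily matches detected ROI centroids to true cell positions at one
#' frame (a match must lie within `radius_mult` times the cell's soma
#' radius); unmatched truth cells are false negatives, unmatched ROIs
#' false positives.
#'
#' @param frame_rois A `frame_rois` from [segment_frame()].
#' @param truth `truth` from [simulate_timelapse()].
#' @param frame Frame index.
#' @param radius_mult Match radius in units of soma radius.
#' @return List with `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
detection_score <- function(frame_rois, truth, frame, radius_mult = 1) {
  alive <- which(is.na(truth$cells$death_frame) |
                   truth$cells$death_frame >= frame)
  rois <- frame_rois$rois
  if (length(alive) == 0L)
    return(list(tp = 0L, fp = nrow(rois), fn = 0L, precision = NA_real_,
                recall = NA_real_, f1 = NA_real_))
  tx <- truth$positions[alive, 1, frame]
  ty <- truth$positions[alive, 2, frame]
  tol <- radius_mult * truth$cells$radius[alive]
  tp <- 0L
  used <- rep(FALSE, nrow(rois))
  if (nrow(rois)) {
    d <- sqrt(outer(tx, rois$x, "-")^2 + outer(ty, rois$y, "-")^2)
    cand <- which(d <= tol, arr.ind = TRUE)   # tol recycles over truth rows
    if (nrow(cand)) {
      cand <- cand[order(d[cand]), , drop = FALSE]
      used_t <- rep(FALSE, length(alive))
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (used_t[i] || used[j]) next
        used_t[i] <- TRUE; used[j] <- TRUE; tp <- tp + 1L
      }
    }
  }
  fp <- sum(!used); fn <- length(alive) - tp
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- tp / (tp + fn)
  f1 <- if (is.na(precision) || precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(tp = tp, fp = fp, fn = fn, precision = precision, recall = recall,
       f1 = f1)
}

#' Match tracks to ground-truth cells and audit purity and death calls
#'
#' Each track observation is assigned to the nearest true cell position
#' at its frame (within `radius_mult` soma radii); a track's identity is
#' the modal assignment, its purity the fraction of observations agreeing
#' with it. For matched tracks of cells that truly die, the called death
#' day is compared with the true (frame-discretized) death day.
#'
#' @param tracks Classified `cell_track`s.
#' @param truth `truth` from [simulate_timelapse()].
#' @param radius_mult Match radius in soma radii.
#' @return data.frame: one row per track with `track_id`, `truth_id`,
#'   `purity`, `called_death_day`, `true_death_day`, `frame_error`
#'   (days / interval).
#' @export
track_audit <- function(tracks, truth, radius_mult = 1.5) {
  interval_days <- diff(truth$timestamps_h[1:2]) / 24
  rows <- lapply(tracks, function(tr) {
    ids <- vapply(seq_len(nrow(tr$obs)), function(k) {
      f <- tr$obs$frame[k]
      d <- sqrt((truth$positions[, 1, f] - tr$obs$x[k])^2 +
                  (truth$positions[, 2, f] - tr$obs$y[k])^2)
      i <- which.min(d)
      if (d[i] <= radius_mult * truth$cells$radius[i]) i else NA_integer_
    }, 1L)
    ids_ok <- ids[!is.na(ids)]
    if (!length(ids_ok))
      return(data.frame(track_id = tr$id, truth_id = NA_integer_,
                        purity = 0, called_death_day = NA_real_,
                        true_death_day = NA_real_,
                        frame_error = NA_real_))
    modal <- as.integer(names(which.max(table(ids_ok))))
    purity <- mean(ids_ok == modal)
    true_dd <- truth$cells$death_day[modal]
    called <- if (identical(tr$status, "dead")) tr$death_time else NA_real_
    data.frame(track_id = tr$id, truth_id = modal, purity = purity,
               called_death_day = called, true_death_day = true_dd,
               frame_error = (called - true_dd) / interval_days)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
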