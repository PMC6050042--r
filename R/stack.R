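#' Time-lapse image stack
#'
#' Container for a multi-channel, timestamped 2D fluorescence time series.
#' Each channel is a numeric array of dimension `rows x cols x frames` in
#' arbitrary intensity units (AU); timestamps are hours post-transfection
#' and must be strictly increasing.
#'
#' @param channels Named list of 3D numeric arrays, one per channel (e.g.
#'   `morphology` for the cell-fill marker, `reporter` for the tagged
#'   protein). All arrays must share one dimension.
#' @param timestamps_h Numeric vector of per-frame acquisition times in
#'   hours, strictly increasing, length equal to the number of frames.
#' @param pixel_size_um Optional pixel size in micrometres per pixel.
#'
#' @return An object of class `time_lapse_stack`.
#' @export
time_lapse_stack <- function(channels, timestamps_h, pixel_size_um = NULL) {
  if (!is.list(channels) || length(channels) == 0L || is.null(names(channels)) ||
      any(!nzchar(names(channels))))
    stop("`channels` must be a non-empty named list of 3D arrays")
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    stop("every channel must be a rows x cols x frames array")
  d1 <- dims[[1]]
  if (!all(vapply(dims, function(d) identical(d, d1), TRUE)))
    stop("all channels must share one array dimension")
  if (any(vapply(channels, function(a) any(a < 0), TRUE)))
    stop("channel intensities must be nonnegative")
  timestamps_h <- as.numeric(timestamps_h)
  if (length(timestamps_h) != d1[3])
    stop("length(timestamps_h) must equal the number of frames")
  if (any(diff(timestamps_h) <= 0))
    stop("timestamps must be strictly increasing")
  structure(
    list(channels = channels, timestamps_h = timestamps_h,
         pixel_size_um = pixel_size_um),
    class = "time_lapse_stack"
  )
}

#' @export
print.time_lapse_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf(
    "time_lapse_stack: %d x %d px, %d frames (%.0f-%.0f h), channels: %s\n",
    d[1], d[2], d[3], min(x$timestamps_h), max(x$timestamps_h),
    paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

n_frames <- function(stack) dim(stack$channels[[1]])[3]

get_frame <- function(stack, channel, frame) {
  if (!channel %in% names(stack$channels))
    stop(sprintf("channel '%s' not present in stack", channel))
  stack$channels[[channel]][, , frame]
}

#' Write a time-lapse stack to multi-page TIFF files plus a YAML sidecar
#'
#' One 32-bit float multi-page TIFF per channel
#' (`<basename>_<channel>.tif`) and a `<basename>.yaml` sidecar recording
#' timestamps, channel names and pixel size.
#'
#' @param stack A [time_lapse_stack()].
#' @param dir Output directory (created if missing).
#' @param basename File name stem.
#' @return Invisibly, the sidecar path.
#' @export
write_stack <- function(stack, dir, basename = "stack") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  scales <- numeric(0)
  for (ch in names(stack$channels)) {
    arr <- stack$channels[[ch]]
    # TIFF samples live in [0,1]; record the intensity scale in the sidecar
    sc <- max(arr, 1e-12)
    pages <- lapply(seq_len(dim(arr)[3]), function(i) arr[, , i] / sc)
    f <- file.path(dir, sprintf("%s_%s.tif", basename, ch))
    tiff::writeTIFF(pages, f, bits.per.sample = 32L, reduce = FALSE)
    files[ch] <- basename(f)
    scales[ch] <- sc
  }
  meta <- list(
    channels = as.list(files),
    intensity_scale = as.list(scales),
    timestamps_h = as.numeric(stack$timestamps_h),
    pixel_size_um = stack$pixel_size_um
  )
  sidecar <- file.path(dir, paste0(basename, ".yaml"))
  yaml::write_yaml(meta, sidecar)
  invisible(sidecar)
}

#' Read a time-lapse stack written by [write_stack()]
#'
#' @param sidecar Path to the YAML sidecar file.
#' @return A [time_lapse_stack()].
#' @export
read_stack <- function(sidecar) {
  meta <- yaml::read_yaml(sidecar)
  dir <- dirname(sidecar)
  channels <- lapply(names(meta$channels), function(ch) {
    pages <- tiff::readTIFF(file.path(dir, meta$channels[[ch]]), all = TRUE)
    sc <- meta$intensity_scale[[ch]] %||% 1
    array(unlist(pages), dim = c(dim(pages[[1]]), length(pages))) * sc
  })
  names(channels) <- names(meta$channels)
  time_lapse_stack(channels, as.numeric(meta$timestamps_h),
                   pixel_size_um = meta$pixel_size_um)
}
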