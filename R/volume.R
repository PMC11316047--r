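#' Multi-channel image volume
#'
#' The universal image container: a named list of intensity arrays (one per
#' channel), each either a 2D matrix `[y, x]` or a 3D array `[y, x, z]`
#' (planes stacked along the third dimension), plus the physical voxel sizes
#' in micrometres. Channels are addressed by name, never by position, so
#' multi-channel assays (e.g. TOM20/PDH or GFP/mCherry) are order
#' independent.
#'
#' Physical coordinates follow a voxel-centre convention: the centre of the
#' voxel with 0-based index `i` along an axis with spacing `h` lies at
#' `(i + 0.5) * h` micrometres.
#'
#' @param channels named list of numeric arrays with identical dimensions
#'   (`[y, x]` or `[y, x, z]`). A bare array is accepted and becomes a single
#'   channel named `"ch1"`.
#' @param voxel_size named numeric vector with elements `x`, `y` and (for 3D
#'   data) `z`, in micrometres per voxel. All entries must be positive.
#' @param frame_interval optional frame interval in seconds (used when the
#'   volume is one frame of a time-lapse).
#'
#' @return An object of class `ImageVolume`.
#' @examples
#' vol <- image_volume(array(0, c(8, 8, 3)), voxel_size = c(x = .1, y = .1, z = .3))
#' dim(get_channel(vol, "ch1"))
#' @export
image_volume <- function(channels, voxel_size, frame_interval = NULL) {
  if (is.array(channels) || is.matrix(channels)) channels <- list(ch1 = channels)
  if (!is.list(channels) || length(channels) == 0L || is.null(names(channels)) ||
      any(!nzchar(names(channels)))) {
    stop("'channels' must be a non-empty named list of arrays")
  }
  dims <- lapply(channels, dim)
  if (any(vapply(dims, is.null, logical(1)))) stop("channels must be matrices or arrays")
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L) {
    stop("all channels must share identical dimensions")
  }
  nd <- length(dims[[1L]])
  if (!nd %in% c(2L, 3L)) stop("channel arrays must be 2D [y,x] or 3D [y,x,z]")
  need <- if (nd == 3L) c("x", "y", "z") else c("x", "y")
  voxel_size <- unlist(voxel_size)
  if (is.null(names(voxel_size)) || !all(need %in% names(voxel_size))) {
    stop("'voxel_size' must be named and contain: ", paste(need, collapse = ", "))
  }
  voxel_size <- voxel_size[need]
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0)) {
    stop("voxel sizes must be positive and finite")
  }
  for (ch in names(channels)) {
    v <- channels[[ch]]
    if (any(!is.finite(v))) stop("channel '", ch, "' contains non-finite intensities")
    if (any(v < 0)) stop("channel '", ch, "' contains negative intensities")
    storage.mode(channels[[ch]]) <- "double"
  }
  if (!is.null(frame_interval)) {
    frame_interval <- as.numeric(frame_interval)
    if (length(frame_interval) != 1L || !is.finite(frame_interval) || frame_interval <= 0) {
      stop("'frame_interval' must be a single positive number of seconds")
    }
  }
  structure(list(channels = channels, voxel_size = voxel_size,
                 frame_interval = frame_interval),
            class = "ImageVolume")
}

#' @export
print.ImageVolume <- function(x, ...) {
  d <- dim(x$channels[[1L]])
  cat("ImageVolume:", paste(d, collapse = " x "),
      if (length(d) == 3L) "[y,x,z]" else "[y,x]", "\n")
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  cat("  voxel size (um):",
      paste(sprintf("%s=%g", names(x$voxel_size), x$voxel_size), collapse = " "), "\n")
  if (!is.null(x$frame_interval)) cat("  frame interval (s):", x$frame_interval, "\n")
  invisible(x)
}

#' Extract one channel from an ImageVolume
#'
#' @param volume an `ImageVolume`.
#' @param channel channel name; with a single-channel volume it may be omitted.
#' @return The intensity array of that channel.
#' @export
get_channel <- function(volume, channel = NULL) {
  stopifnot(inherits(volume, "ImageVolume"))
  if (is.null(channel)) {
    if (length(volume$channels) != 1L) {
      stop("volume has ", length(volume$channels),
           " channels; specify one of: ", paste(names(volume$channels), collapse = ", "))
    }
    return(volume$channels[[1L]])
  }
  if (!channel %in% names(volume$channels)) {
    stop("no channel named '", channel, "'; available: ",
         paste(names(volume$channels), collapse = ", "))
  }
  volume$channels[[channel]]
}

#' Time-lapse image sequence
#'
#' An ordered list of [image_volume()] frames sharing geometry, with a common
#' frame interval.
#'
#' @param frames list of `ImageVolume` objects with identical channel names,
#'   dimensions and voxel sizes.
#' @param frame_interval time between consecutive frames, seconds (> 0).
#' @return An object of class `ImageTimelapse`.
#' @export
image_timelapse <- function(frames, frame_interval) {
  if (!is.list(frames) || length(frames) < 1L ||
      !all(vapply(frames, inherits, logical(1), "ImageVolume"))) {
    stop("'frames' must be a list of ImageVolume objects")
  }
  if (!is.numeric(frame_interval) || length(frame_interval) != 1L ||
      !is.finite(frame_interval) || frame_interval <= 0) {
    stop("'frame_interval' must be a single positive number of seconds")
  }
  ref <- frames[[1L]]
  for (f in frames) {
    if (!identical(names(f$channels), names(ref$channels)) ||
        !identical(dim(f$channels[[1L]]), dim(ref$channels[[1L]]))) {
      stop("all frames must share channel names and dimensions")
    }
  }
  structure(list(frames = frames, frame_interval = frame_interval),
            class = "ImageTimelapse")
}

#' @export
print.ImageTimelapse <- function(x, ...) {
  cat("ImageTimelapse:", length(x$frames), "frames, interval",
      x$frame_interval, "s\n")
  print(x$frames[[1L]])
  invisible(x)
}

# voxel-centre physical coordinates (um) of 1-based indices along one axis
voxel_centers <- function(n, h) (seq_len(n) - 0.5) * h
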