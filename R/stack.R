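#' Multi-channel time-lapse image stack
#'
#' An `ImageStack` holds a time-lapse movie as a 4-D numeric array with axis
#' order T, C, Y, X together with the calibration metadata every downstream
#' stage needs: channel names, pixel size (micrometres per pixel) and frame
#' interval (seconds).
#'
#' @param data 4-D numeric array, dimensions `(frames, channels, rows, cols)`.
#'   A 3-D `(frames, rows, cols)` array is promoted to a single channel.
#' @param channels character vector of channel names, one per channel axis
#'   entry (e.g. `c("PI4P", "PIP2", "dye")`).
#' @param pixel_size pixel edge length in micrometres per pixel.
#' @param frame_interval time between consecutive frames in seconds.
#' @param bit_depth integer bit depth of the source data, used to derive the
#'   saturation threshold (`2^bit_depth - 1`); `NULL` for floating-point data
#'   with no defined saturation level.
#' @param meta optional named list of free-form metadata (provenance, applied
#'   drift track, ...).
#'
#' @return An object of class `ImageStack`.
#' @export
image_stack <- function(data, channels = NULL, pixel_size = 1,
                        frame_interval = 1, bit_depth = NULL, meta = list()) {
  if (length(dim(data)) == 3L) {
    data <- array(data, dim = c(dim(data)[1], 1L, dim(data)[2], dim(data)[3]))
  }
  if (length(dim(data)) != 4L)
    stop("ImageStack data must be a 4-D array (T, C, Y, X)")
  nc <- dim(data)[2]
  if (is.null(channels)) channels <- paste0("ch", seq_len(nc))
  if (length(channels) != nc)
    stop(sprintf("%d channel names supplied for %d channels",
                 length(channels), nc))
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be > 0")
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be > 0")
  structure(list(data = data, channels = as.character(channels),
                 pixel_size = pixel_size, frame_interval = frame_interval,
                 bit_depth = bit_depth, meta = meta),
            class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("ImageStack: %d frames x %d channels x %d x %d px\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  channels: %s\n", paste(x$channels, collapse = ", ")))
  cat(sprintf("  pixel_size: %g um/px, frame_interval: %g s\n",
              x$pixel_size, x$frame_interval))
  invisible(x)
}

#' @export
dim.ImageStack <- function(x) dim(x$data)

#' Number of frames / channels in a stack
#' @param stack an `ImageStack`.
#' @return integer count.
#' @export
n_frames <- function(stack) dim(stack$data)[1]

#' @rdname n_frames
#' @export
n_channels <- function(stack) dim(stack$data)[2]

#' Times (seconds) of each frame, starting at 0
#' @param stack an `ImageStack`.
#' @return numeric vector of length `n_frames(stack)`.
#' @export
frame_times <- function(stack) (seq_len(n_frames(stack)) - 1) * stack$frame_interval

# Resolve a channel given by name or index to an index.
channel_index <- function(stack, channel) {
  if (is.numeric(channel)) {
    ch <- as.integer(channel)
    if (ch < 1L || ch > n_channels(stack)) stop("channel index out of range")
    return(ch)
  }
  ch <- match(channel, stack$channels)
  if (is.na(ch))
    stop(sprintf("unknown channel '%s' (have: %s)", channel,
                 paste(stack$channels, collapse = ", ")))
  ch
}

#' Extract one frame of one channel as a matrix
#' @param stack an `ImageStack`.
#' @param frame frame index (1-based).
#' @param channel channel name or index.
#' @return numeric matrix (rows = Y, cols = X).
#' @export
get_frame <- function(stack, frame, channel = 1L) {
  ch <- channel_index(stack, channel)
  if (frame < 1L || frame > n_frames(stack)) stop("frame index out of range")
  stack$data[frame, ch, , ]
}

# Saturation threshold for a stack (Inf when bit depth is unknown).
saturation_level <- function(stack) {
  if (is.null(stack$bit_depth)) Inf else 2^stack$bit_depth - 1
}
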