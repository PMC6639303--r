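#' Time-lapse image stack
#'
#' Container for a T x C x Y x X intensity series with acquisition metadata.
#' Intensities are detector counts in arbitrary units (AU). Coordinates are
#' 1-based (row, col) pixel centres throughout the package.
#'
#' @param pixels Numeric array. Accepted shapes: T x C x Y x X, T x Y x X
#'   (C = 1 inserted) or Y x X (single frame, single channel).
#' @param frame_interval Seconds between frames (> 0).
#' @param channel_names Character vector of length C; defaults to
#'   `"ch1" ... "chC"`.
#' @param injury_frame Optional 1-based index of the injury/bleach frame.
#' @param pixel_size Optional pixel edge length in micrometres.
#' @return Object of class `time_lapse_stack`.
#' @export
time_lapse_stack <- function(pixels, frame_interval, channel_names = NULL,
                             injury_frame = NULL, pixel_size = NULL) {
  nd <- length(dim(pixels))
  if (nd == 2) dim(pixels) <- c(1, 1, dim(pixels))
  else if (nd == 3) {
    d <- dim(pixels); dim(pixels) <- c(d[1], 1, d[2], d[3])
  } else if (nd != 4) stop("pixels must have 2, 3 or 4 dimensions")
  d <- dim(pixels)
  if (d[1] < 1 || d[2] < 1) stop("stack needs at least one frame and channel")
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be a positive number of seconds")
  channel_names <- channel_names %||% paste0("ch", seq_len(d[2]))
  if (length(channel_names) != d[2])
    stop(sprintf("%d channel names supplied for %d channels",
                 length(channel_names), d[2]))
  if (!is.null(injury_frame)) {
    injury_frame <- as.integer(injury_frame)
    if (injury_frame < 1 || injury_frame > d[1])
      stop("injury_frame must index a frame of the stack")
  }
  structure(list(pixels = pixels, frame_interval = frame_interval,
                 channel_names = as.character(channel_names),
                 injury_frame = injury_frame, pixel_size = pixel_size),
            class = "time_lapse_stack")
}

#' @export
print.time_lapse_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<time_lapse_stack> %d frame(s) x %d channel(s) x %d x %d px, dt = %.4g s\n",
              d[1], d[2], d[3], d[4], x$frame_interval))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  if (!is.null(x$injury_frame))
    cat(sprintf("  injury at frame %d\n", x$injury_frame))
  invisible(x)
}

#' @export
dim.time_lapse_stack <- function(x) dim(x$pixels)

# resolve a channel given as name or index
channel_index <- function(stack, channel) {
  if (is.character(channel)) {
    i <- match(channel, stack$channel_names)
    if (is.na(i)) stop(sprintf("channel '%s' not found (have: %s)", channel,
                               paste(stack$channel_names, collapse = ", ")))
    i
  } else {
    i <- as.integer(channel)
    if (i < 1 || i > dim(stack$pixels)[2]) stop("channel index out of range")
    i
  }
}

# one channel of one frame as a Y x X matrix
frame_matrix <- function(stack, frame, channel = 1) {
  ci <- channel_index(stack, channel)
  d <- dim(stack$pixels)
  matrix(stack$pixels[frame, ci, , ], d[3], d[4])
}
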