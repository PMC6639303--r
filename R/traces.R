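#' Kinetic trace
#'
#' A time-indexed scalar fluorescence series for one region of interest.
#' Times are in seconds relative to the injury (or bleach) event: the
#' annotated event frame sits at time 0, pre-event frames at negative times.
#'
#' @param times Numeric vector of times in seconds, strictly increasing with
#'   constant spacing.
#' @param values Numeric vector, same length: raw intensities (AU) or
#'   dimensionless delta-F/F depending on `kind`.
#' @param kind `"raw"` or `"dff"`.
#' @param frame_interval Seconds between frames; inferred from `times` when
#'   omitted.
#' @param baseline_window Integer c(first, last) frame indices (1-based into
#'   this trace) of the baseline used (or to be used) for delta-F/F.
#' @param injury_index 1-based index of the frame at time 0, if annotated.
#' @param meta Free-form named list carried along (channel, background
#'   correction flag, generator ground truth, ...).
#' @return Object of class `kinetic_trace`.
#' @export
kinetic_trace <- function(times, values, kind = c("raw", "dff"),
                          frame_interval = NULL, baseline_window = NULL,
                          injury_index = NULL, meta = list()) {
  kind <- match.arg(kind)
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values))
    stop("times and values must have the same length")
  if (length(times) >= 2) {
    dts <- diff(times)
    if (any(dts <= 0)) stop("times must be strictly increasing")
    if (max(dts) - min(dts) > 1e-6 * max(dts))
      stop("times must be evenly spaced")
    fi <- mean(dts)
  } else fi <- frame_interval %||% NA_real_
  if (!is.null(frame_interval) && is.finite(fi) &&
      abs(frame_interval - fi) > 1e-6 * fi)
    stop("frame_interval does not match the spacing of times")
  if (!is.null(baseline_window)) {
    baseline_window <- as.integer(baseline_window)
    stopifnot(length(baseline_window) == 2,
              baseline_window[1] >= 1,
              baseline_window[2] <= length(times),
              baseline_window[1] <= baseline_window[2])
  }
  if (!is.null(injury_index)) {
    injury_index <- as.integer(injury_index)
    stopifnot(injury_index >= 1, injury_index <= length(times))
  }
  structure(list(times = times, values = values, kind = kind,
                 frame_interval = fi, baseline_window = baseline_window,
                 injury_index = injury_index, meta = meta),
            class = "kinetic_trace")
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat(sprintf("<kinetic_trace> %s, %d frames at %.4g s, t = [%.4g, %.4g] s\n",
              x$kind, length(x$times), x$frame_interval,
              x$times[1], x$times[length(x$times)]))
  if (!is.null(x$injury_index))
    cat(sprintf("  injury/bleach at frame %d\n", x$injury_index))
  if (!is.null(x$baseline_window))
    cat(sprintf("  baseline frames %d:%d\n",
                x$baseline_window[1], x$baseline_window[2]))
  invisible(x)
}

#' @export
as.data.frame.kinetic_trace <- function(x, ...) {
  data.frame(time = x$times, value = x$values)
}
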