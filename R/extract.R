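# Turning a stack plus ROIs into background-corrected delta-F/F traces.

# resolve an ROI argument (roi_set, polygon matrix, or logical mask) to a
# logical pixel mask matching the stack's image dimensions
roi_mask <- function(roi, dim) {
  if (inherits(roi, "roi_set")) return(polygon_mask(roi$cell_polygon, dim))
  if (is.logical(roi)) {
    if (!all(dim(roi) == dim)) stop("ROI mask dimensions do not match stack")
    return(roi)
  }
  if (is.matrix(roi) && ncol(roi) == 2) return(polygon_mask(roi, dim))
  stop("roi must be an roi_set, an n x 2 polygon, or a logical mask")
}

#' Extract the mean-intensity trace of an ROI
#'
#' One value per frame: the mean intensity over the ROI pixels, with the
#' per-frame mean of a background ROI subtracted when one is supplied.
#' Times are reported relative to the stack's injury frame (0 at injury)
#' when annotated, otherwise from 0 at the first frame.
#'
#' @param stack A [time_lapse_stack()].
#' @param roi The cell region: an [roi_set()] (its `cell_polygon` is used),
#'   an n x 2 polygon matrix, or a logical mask.
#' @param channel Channel name or index.
#' @param background Optional background region: `TRUE` to use the
#'   `background_polygon` of `roi`, or a polygon/mask. `NULL` (default)
#'   disables background correction.
#' @return Raw [kinetic_trace()]; `meta$background_corrected` records
#'   whether correction was applied.
#' @export
extract_mean_trace <- function(stack, roi, channel = 1, background = NULL) {
  stopifnot(inherits(stack, "time_lapse_stack"))
  d <- dim(stack$pixels)
  imdim <- d[3:4]
  ci <- channel_index(stack, channel)
  mask <- roi_mask(roi, imdim)
  if (!any(mask)) stop("ROI does not intersect the image")
  bg_mask <- NULL
  if (isTRUE(background)) {
    if (!inherits(roi, "roi_set") || is.null(roi$background_polygon))
      stop("background = TRUE needs an roi_set with a background_polygon")
    bg_mask <- polygon_mask(roi$background_polygon, imdim)
  } else if (!is.null(background) && !isFALSE(background)) {
    bg_mask <- roi_mask(background, imdim)
  }
  if (!is.null(bg_mask) && !any(bg_mask))
    stop("background ROI does not intersect the image")

  vals <- numeric(d[1])
  for (t in seq_len(d[1])) {
    fr <- matrix(stack$pixels[t, ci, , ], imdim[1], imdim[2])
    vals[t] <- mean(fr[mask])
    if (!is.null(bg_mask)) vals[t] <- vals[t] - mean(fr[bg_mask])
  }
  inj <- stack$injury_frame
  times <- if (is.null(inj)) (seq_len(d[1]) - 1) * stack$frame_interval
           else (seq_len(d[1]) - inj) * stack$frame_interval
  kinetic_trace(times, vals, kind = "raw",
                baseline_window = if (!is.null(inj) && inj >= 3) c(1L, inj - 1L),
                injury_index = inj,
                meta = list(channel = stack$channel_names[ci],
                            roi_area = sum(mask),
                            background_corrected = !is.null(bg_mask)))
}

#' Convert a raw trace to delta-F/F
#'
#' `(F - F0) / F0` with `F0` the mean over the baseline window, so the
#' output has baseline mean 0 and is invariant to positive scaling of the
#' raw trace.
#'
#' @param trace Raw [kinetic_trace()].
#' @param baseline_window Integer c(first, last) frame indices; defaults to
#'   the trace's own baseline window, or to all frames strictly before the
#'   injury frame (at least 2 required).
#' @return A [kinetic_trace()] of kind `"dff"`.
#' @export
to_delta_f_over_f <- function(trace, baseline_window = NULL) {
  stopifnot(inherits(trace, "kinetic_trace"))
  if (trace$kind == "dff") stop("trace is already delta-F/F")
  bw <- baseline_window %||% trace$baseline_window
  if (is.null(bw)) {
    if (is.null(trace$injury_index) || trace$injury_index < 3)
      stop("no baseline window: need >= 2 frames before the injury frame")
    bw <- c(1L, trace$injury_index - 1L)
  }
  bw <- as.integer(bw)
  if (bw[2] - bw[1] + 1 < 2) stop("baseline window must span >= 2 frames")
  if (!is.null(trace$injury_index) && bw[2] >= trace$injury_index)
    stop("baseline window must precede the injury frame")
  f0 <- mean(trace$values[bw[1]:bw[2]])
  if (!is.finite(f0) || f0 <= 0)
    stop("baseline mean F0 <= 0: check the intensity offset and background ",
         "correction before computing delta-F/F")
  kinetic_trace(trace$times, (trace$values - f0) / f0, kind = "dff",
                baseline_window = bw, injury_index = trace$injury_index,
                meta = c(trace$meta, list(f0 = f0)))
}

#' Block-mean downsampling of a trace
#'
#' Averages consecutive blocks of `factor` frames; times become the block
#' centres. Trailing frames that do not fill a block are dropped.
#'
#' @param trace A [kinetic_trace()].
#' @param factor Integer block length (>= 1).
#' @return Downsampled [kinetic_trace()] (baseline/injury annotations are
#'   dropped; the kind is preserved).
#' @export
downsample_trace <- function(trace, factor) {
  stopifnot(inherits(trace, "kinetic_trace"))
  factor <- as.integer(factor)
  if (factor < 1) stop("factor must be >= 1")
  n <- length(trace$times)
  if (factor > n) stop("factor exceeds the trace length")
  if (factor == 1) return(trace)
  nb <- n %/% factor
  idx <- seq_len(nb * factor)
  blk <- rep(seq_len(nb), each = factor)
  vals <- as.numeric(tapply(trace$values[idx], blk, mean))
  times <- as.numeric(tapply(trace$times[idx], blk, mean))
  kinetic_trace(times, vals, kind = trace$kind, meta = trace$meta)
}
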