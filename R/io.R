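# Reading and writing image stacks and ROI sidecars.
#
# Pixels are stored on disk as 16-bit unsigned integers in multi-page TIFF
# files. Multi-channel stacks are written as channel-interleaved single-plane
# pages (page = (t-1)*C + c) because grayscale+alpha pages do not round-trip
# integer data reliably; the channel count must therefore be supplied on
# read whenever C > 1 (pages alone are ambiguous).

#' Write a time-lapse stack to a multi-page TIFF
#'
#' Values must be integer counts in [0, 65535]; the synthetic generators all
#' quantise to this range so a write/read cycle is bit-exact.
#'
#' @param stack A [time_lapse_stack()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "time_lapse_stack"))
  px <- stack$pixels
  if (any(px < 0 | px > 65535) || any(px != round(px)))
    stop("pixels must be integer counts in [0, 65535] to write a 16-bit TIFF")
  d <- dim(px)
  pages <- vector("list", d[1] * d[2])
  k <- 1L
  for (t in seq_len(d[1])) {
    for (c in seq_len(d[2])) {
      pages[[k]] <- matrix(px[t, c, , ], d[3], d[4]) / 65535
      k <- k + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  invisible(path)
}

#' Read a multi-page TIFF as a time-lapse stack
#'
#' Axis inference: with one channel, pages are frames. With `channel_names`
#' of length C > 1 the pages are de-interleaved as written by
#' [write_stack()] (channel fastest). Supplying the channel count is
#' mandatory for multi-channel files because the page layout alone is
#' ambiguous.
#'
#' @param path TIFF file path.
#' @param frame_interval Seconds between frames.
#' @param channel_names Channel labels; length defines C. Default one
#'   channel `"ch1"`.
#' @param injury_frame,pixel_size Optional metadata, see
#'   [time_lapse_stack()].
#' @return A [time_lapse_stack()].
#' @export
read_stack <- function(path, frame_interval, channel_names = "ch1",
                       injury_frame = NULL, pixel_size = NULL) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(!vapply(pages, is.matrix, logical(1))))
    stop("ambiguous axis layout: multi-plane TIFF pages are not supported; ",
         "write stacks with write_stack() (channel-interleaved pages)")
  nC <- length(channel_names)
  nP <- length(pages)
  if (nP %% nC != 0)
    stop(sprintf("%d pages cannot hold %d channels: page count must be T x C",
                 nP, nC))
  nT <- nP %/% nC
  d <- dim(pages[[1]])
  px <- array(0, c(nT, nC, d[1], d[2]))
  k <- 1L
  for (t in seq_len(nT)) {
    for (c in seq_len(nC)) {
      px[t, c, , ] <- pages[[k]]
      k <- k + 1L
    }
  }
  time_lapse_stack(px, frame_interval = frame_interval,
                   channel_names = channel_names,
                   injury_frame = injury_frame, pixel_size = pixel_size)
}

#' Write an ROI set to a JSON sidecar
#'
#' The schema is a JSON object with keys `cell_polygon`,
#' `injury_point`, `background_polygon`, `bleach_region`; polygons are
#' arrays of `[row, col]` pairs (1-based pixel centres). Numbers are written
#' at full precision so the round trip is lossless.
#'
#' @param roi An [roi_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roiset <- function(roi, path) {
  stopifnot(inherits(roi, "roi_set"))
  obj <- list(cell_polygon = unname(roi$cell_polygon))
  if (!is.null(roi$injury_point)) obj$injury_point <- roi$injury_point
  if (!is.null(roi$background_polygon))
    obj$background_polygon <- unname(roi$background_polygon)
  if (!is.null(roi$bleach_region))
    obj$bleach_region <- unname(roi$bleach_region)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Read an ROI set from a JSON sidecar
#'
#' Coordinates are validated on load (simple polygons, background disjoint
#' from the cell, injury point on or inside the outline).
#'
#' @param path JSON file written by [write_roiset()] or conforming to its
#'   schema.
#' @return An [roi_set()].
#' @export
read_roiset <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  roi_set(cell_polygon = obj$cell_polygon,
          injury_point = if (!is.null(obj$injury_point)) as.numeric(obj$injury_point),
          background_polygon = obj$background_polygon,
          bleach_region = obj$bleach_region)
}

#' Save a synthetic generator result with its ground-truth sidecars
#'
#' Writes `<name>.tif` (the stack), `<name>_roi.json` (the ROI set, when the
#' generator provides one) and `<name>_truth.json` (machine-readable ground
#' truth: model parameters, seed, and per-frame/per-cell truth).
#'
#' @param gen Result of one of the `generate_*` functions that return a
#'   stack.
#' @param dir Output directory (created if missing).
#' @param name Base file name.
#' @return Named character vector of the files written, invisibly.
#' @export
write_synthetic <- function(gen, dir, name) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c(stack = file.path(dir, paste0(name, ".tif")))
  write_stack(gen$stack, files[["stack"]])
  if (!is.null(gen$roi)) {
    files[["roi"]] <- file.path(dir, paste0(name, "_roi.json"))
    write_roiset(gen$roi, files[["roi"]])
  }
  truth <- gen$truth
  tr <- list(seed = gen$seed, model = gen$model %||% gen$spec)
  if (inherits(truth, "kinetic_trace")) {
    tr$trace <- list(times = truth$times, values = truth$values,
                     kind = truth$kind, injury_index = truth$injury_index)
  } else if (inherits(truth, "fragmentation_result")) {
    tr$fragmentation <- list(axis_length = truth$axis_length,
                             fragmented_length = truth$fragmented_length,
                             fragmented_fraction = truth$fragmented_fraction)
    tr$label_mask_true_pixels <- which(gen$label_mask)
  } else if (is.data.frame(truth)) {
    tr$cells <- truth
  }
  files[["truth"]] <- file.path(dir, paste0(name, "_truth.json"))
  jsonlite::write_json(tr, files[["truth"]], digits = NA, auto_unbox = TRUE,
                       force = TRUE)
  invisible(files)
}
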