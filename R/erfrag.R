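# Injury-axis ER fragmentation scoring: the fraction of the cell's longest
# axis from the injury point over which tubular ER has become punctate.

#' Fragmentation result
#'
#' @param axis_length Axis length, pixels.
#' @param fragmented_length Fragmented run length from the injury point,
#'   pixels.
#' @param fragmented_fraction `fragmented_length / axis_length`.
#' @param axis_coordinates Ordered pixel path from injury point to the far
#'   boundary.
#' @param per_window_scores Optional data frame of per-axis-position texture
#'   scores.
#' @param distal_fragmented_length Above-threshold length outside the
#'   contiguous run (isolated distal punctate windows, reported separately).
#' @return Object of class `fragmentation_result`.
#' @export
fragmentation_result <- function(axis_length, fragmented_length,
                                 fragmented_fraction, axis_coordinates,
                                 per_window_scores = NULL,
                                 distal_fragmented_length = 0) {
  if (fragmented_length < -1e-9 || fragmented_length > axis_length + 1e-9)
    stop("fragmented_length must lie in [0, axis_length]")
  structure(list(axis_length = axis_length,
                 fragmented_length = fragmented_length,
                 fragmented_fraction = fragmented_fraction,
                 axis_coordinates = axis_coordinates,
                 per_window_scores = per_window_scores,
                 distal_fragmented_length = distal_fragmented_length),
            class = "fragmentation_result")
}

#' @export
print.fragmentation_result <- function(x, ...) {
  cat(sprintf("<fragmentation_result> %.1f / %.1f px fragmented (fraction %.3f)\n",
              x$fragmented_length, x$axis_length, x$fragmented_fraction))
  invisible(x)
}

#' Longest axis of a cell from the injury point
#'
#' The straight segment from the injury point to the boundary point that
#' maximises Euclidean length (for a polygon, always a vertex), rasterised
#' to an ordered pixel path. Distance ties are broken by the smallest angle
#' to the polygon's principal axis.
#'
#' @param roi An [roi_set()] (its cell polygon and injury point are used),
#'   or an n x 2 polygon matrix together with `injury_point`.
#' @param injury_point (row, col); taken from `roi` when omitted.
#' @return m x 2 integer pixel path with attributes `length` (Euclidean,
#'   pixels), `start` and `end`.
#' @export
injury_axis <- function(roi, injury_point = NULL) {
  if (inherits(roi, "roi_set")) {
    poly <- roi$cell_polygon
    injury_point <- injury_point %||% roi$injury_point
  } else {
    poly <- as_polygon(roi, "cell polygon")
  }
  if (is.null(injury_point)) stop("an injury point is required")
  injury_point <- as.numeric(injury_point)
  inside <- point_in_polygon(matrix(injury_point, 1), poly) ||
    polygon_boundary_dist(injury_point, poly) <= 1
  if (!inside) stop("injury point lies outside the cell polygon")

  d <- sqrt((poly[, 1] - injury_point[1])^2 + (poly[, 2] - injury_point[2])^2)
  cand <- which(d >= max(d) - 1e-9)
  if (length(cand) > 1) {
    # tie-break: smallest angle to the principal axis of the vertex cloud
    ctr <- colMeans(poly)
    ev <- eigen(stats::cov(poly))$vectors[, 1]
    ang <- vapply(cand, function(i) {
      v <- poly[i, ] - injury_point
      v <- v / sqrt(sum(v^2))
      acos(min(1, abs(sum(v * ev))))
    }, numeric(1))
    cand <- cand[which.min(ang)]
  }
  far <- poly[cand[1], ]
  path <- rasterize_segment(injury_point, far)
  attr(path, "length") <- sqrt(sum((far - injury_point)^2))
  attr(path, "start") <- injury_point
  attr(path, "end") <- far
  path
}

# per-axis-position texture score profile for one frame.
#
# The score is structure-tensor based: 1 minus the orientation coherence of
# the intensity gradients in the window. Continuous tubules vary only
# across the ridge direction, so their gradients share one orientation
# (coherence near 1, score near 0); puncta produce isotropically
# distributed gradients (coherence near 0, score near 1). The score is
# rotation-invariant and invariant to global intensity scaling.
#
# Returns positions (pixels from the injury point along the axis), scores
# (NA where the window is invalid), and the validity mask.
fragmentation_score_profile <- function(img, axis, window_length,
                                        band_halfwidth, cell_mask,
                                        tubule_scale) {
  p0 <- attr(axis, "start") %||% axis[1, ]
  p1 <- attr(axis, "end") %||% axis[nrow(axis), ]
  L <- attr(axis, "length") %||% sqrt(sum((p1 - p0)^2))
  dvec <- (p1 - p0) / sqrt(sum((p1 - p0)^2))
  d <- dim(img)
  rr <- matrix(seq_len(d[1]), d[1], d[2])
  cc <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
  u <- (rr - p0[1]) * dvec[1] + (cc - p0[2]) * dvec[2]
  w <- -(rr - p0[1]) * dvec[2] + (cc - p0[2]) * dvec[1]
  in_band <- abs(w) <= band_halfwidth & u >= -window_length & u <= L + window_length

  # light pre-smoothing below the tubule scale to suppress pixel noise,
  # then central-difference gradients and structure-tensor components
  sm <- EBImage::gblur(img, sigma = max(0.5, tubule_scale / 6))
  gr <- matrix(0, d[1], d[2])
  gc <- matrix(0, d[1], d[2])
  gr[2:(d[1] - 1), ] <- (sm[3:d[1], ] - sm[1:(d[1] - 2), ]) / 2
  gc[, 2:(d[2] - 1)] <- (sm[, 3:d[2]] - sm[, 1:(d[2] - 2)]) / 2
  jrr <- gr * gr; jcc <- gc * gc; jrc <- gr * gc

  # keep only pixels whose whole gradient stencil is inside the cell mask,
  # so the cell boundary edge does not contaminate the texture statistics
  usable <- in_band
  if (!is.null(cell_mask)) {
    core <- cell_mask
    core[2:(d[1] - 1), ] <- core[2:(d[1] - 1), ] &
      cell_mask[1:(d[1] - 2), ] & cell_mask[3:d[1], ]
    core[, 2:(d[2] - 1)] <- core[, 2:(d[2] - 1)] &
      cell_mask[, 1:(d[2] - 2)] & cell_mask[, 3:d[2]]
    core[c(1, d[1]), ] <- FALSE
    core[, c(1, d[2])] <- FALSE
    usable <- in_band & core
  }

  positions <- seq(0, floor(L))
  half <- window_length / 2
  ub <- u[usable]
  srr <- jrr[usable]; scc <- jcc[usable]; src <- jrc[usable]
  scores <- rep(NA_real_, length(positions))
  counts <- integer(length(positions))
  for (k in seq_along(positions)) {
    sel <- abs(ub - positions[k]) <= half
    counts[k] <- sum(sel)
    if (counts[k] >= 3) {
      a <- sum(srr[sel]); b <- sum(scc[sel]); c <- sum(src[sel])
      tr <- a + b
      if (tr > 1e-12) {
        coherence <- sqrt((a - b)^2 + 4 * c^2) / tr
        scores[k] <- 1 - coherence
      }
    }
  }
  nominal <- max(counts)
  valid <- counts >= 0.5 * nominal & !is.na(scores)
  scores[!valid] <- NA_real_
  list(positions = positions, scores = scores, valid = valid, length = L)
}

# fill NA entries with the nearest valid value
fill_nearest <- function(x, valid) {
  if (!any(valid)) return(x)
  vi <- which(valid)
  for (i in which(!valid)) x[i] <- x[vi[which.min(abs(vi - i))]]
  x
}

#' Score ER fragmentation along the injury axis for one frame
#'
#' A texture score is computed for a sliding window at every pixel position
#' along the axis, from the band of in-mask pixels within `band_halfwidth`
#' of the axis: one minus the structure-tensor orientation coherence of the
#' window's intensity gradients. Continuous tubules have gradients of a
#' single shared orientation and score near 0; punctate ("bead-on-string")
#' texture has isotropic gradients and scores near 1. The score is
#' invariant to rotation and to global intensity scaling. Windows whose
#' band falls outside the cell mask by more than 50% are flagged invalid
#' and inherit the nearest valid classification. The fragmented length is the maximal
#' contiguous run of above-threshold positions starting at the injury
#' point (after light smoothing of the score profile); isolated distal
#' punctate stretches are reported separately.
#'
#' @param stack A [time_lapse_stack()].
#' @param axis Pixel path from [injury_axis()] (or a generator).
#' @param frame 1-based frame index to score.
#' @param er_channel ER channel name or index.
#' @param threshold Score threshold separating tubular from punctate; see
#'   [calibrate_fragmentation_threshold()].
#' @param window_length Window length along the axis, pixels.
#' @param band_halfwidth Band half-width either side of the axis, pixels.
#' @param cell_mask Optional logical in-cell mask restricting the band.
#' @param tubule_scale Tubule spatial period, pixels (band-pass scale).
#' @return A [fragmentation_result()] with per-position scores attached.
#' @export
score_fragmentation <- function(stack, axis, frame, er_channel = "er",
                                threshold, window_length = 9,
                                band_halfwidth = 6, cell_mask = NULL,
                                tubule_scale = 6) {
  stopifnot(inherits(stack, "time_lapse_stack"))
  img <- frame_matrix(stack, frame, er_channel)
  prof <- fragmentation_score_profile(img, axis, window_length,
                                      band_halfwidth, cell_mask,
                                      tubule_scale)
  filled <- fill_nearest(prof$scores, prof$valid)
  smoothed <- gaussian_smooth(filled, window_length / 4)
  punctate <- smoothed >= threshold
  npos <- length(punctate)
  r <- rle(punctate)
  run <- if (r$values[1]) r$lengths[1] else 0L
  frac <- run / npos
  distal <- (sum(punctate) - run) / npos
  fragmentation_result(
    axis_length = prof$length,
    fragmented_length = frac * prof$length,
    fragmented_fraction = frac,
    axis_coordinates = axis,
    per_window_scores = data.frame(position = prof$positions,
                                   score = prof$scores,
                                   smoothed = smoothed,
                                   valid = prof$valid,
                                   punctate = punctate),
    distal_fragmented_length = distal * prof$length)
}

#' Fragmentation time course
#'
#' Scores every requested frame against a fixed axis (cells are assumed
#' stationary over the few-minute acquisitions this targets). Frames are
#' scored independently; there is no temporal smoothing.
#'
#' @inheritParams score_fragmentation
#' @param frames Frame indices to score; defaults to all frames.
#' @return List of [fragmentation_result()], one per frame.
#' @export
fragmentation_timecourse <- function(stack, axis, frames = NULL,
                                     er_channel = "er", threshold,
                                     window_length = 9, band_halfwidth = 6,
                                     cell_mask = NULL, tubule_scale = 6) {
  frames <- frames %||% seq_len(dim(stack$pixels)[1])
  lapply(frames, function(fr)
    score_fragmentation(stack, axis, fr, er_channel = er_channel,
                        threshold = threshold,
                        window_length = window_length,
                        band_halfwidth = band_halfwidth,
                        cell_mask = cell_mask, tubule_scale = tubule_scale))
}

#' Calibrate the tubular/punctate score threshold
#'
#' Generates pure-tubular and pure-punctate calibration fields from the
#' given model (fragmentation fraction 0 and 1) at matched noise, scores
#' all valid windows of each, and returns the midpoint of the two mean
#' scores. Recalibrate whenever the texture parameters change.
#'
#' @param model An [er_field_model()]; its `fragmentation_fraction` is
#'   overridden.
#' @param n_fields Calibration fields per class.
#' @param seed Integer seed.
#' @param window_length,band_halfwidth As in [score_fragmentation()].
#' @return Threshold value, with the two class score means as attributes
#'   `tubular_mean` and `punctate_mean`.
#' @export
calibrate_fragmentation_threshold <- function(model, n_fields = 3, seed = 1,
                                              window_length = 9,
                                              band_halfwidth = 6) {
  stopifnot(inherits(model, "er_field_model"))
  class_scores <- lapply(c(0, 1), function(f) {
    m <- model
    m$fragmentation_fraction <- f
    unlist(lapply(seq_len(n_fields), function(i) {
      gen <- generate_er_stack(m, n_frames = 1, onset_frame = 1,
                               seed = seed + 1000 * f + i)
      img <- frame_matrix(gen$stack, 1, "er")
      prof <- fragmentation_score_profile(img, gen$axis, window_length,
                                          band_halfwidth, gen$mask,
                                          m$tubule_spacing)
      prof$scores[prof$valid]
    }))
  })
  thr <- (mean(class_scores[[1]]) + mean(class_scores[[2]])) / 2
  attr(thr, "tubular_mean") <- mean(class_scores[[1]])
  attr(thr, "punctate_mean") <- mean(class_scores[[2]])
  thr
}
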