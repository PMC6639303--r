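# Synthetic FM-dye influx stacks: the laser-injury membrane-repair assay.
# A repairing cell admits dye linearly from the injury frame until membrane
# resealing stops entry (hard plateau at repair_time); a non-repairing cell
# admits dye without bound until the detector clips.

#' Dye-influx trace model
#'
#' Piecewise-linear model of FM-dye entry after focal laser injury:
#' intensity is flat at `baseline_intensity` before the injury frame, rises
#' at `influx_rate` afterwards, and plateaus `repair_time` seconds after
#' injury when the cell reseals (`repair_time = NULL` means the cell never
#' repairs and the rise is clipped only by `dynamic_range`).
#'
#' Defaults reflect a typical confocal laser-injury acquisition: 2 s frame
#' interval, 90 frames (3 min), injury at frame 10, and a camera model with
#' Poisson shot noise (`photon_scale` AU/photon) plus Gaussian read noise.
#'
#' @param baseline_intensity Pre-injury in-cell intensity, AU.
#' @param influx_rate Dye entry rate, AU per second (>= 0).
#' @param repair_time Seconds after injury at which entry stops; `NULL` for
#'   a non-repairing cell.
#' @param noise_sd Gaussian read noise standard deviation, AU.
#' @param photon_scale AU per photon for Poisson shot noise; 0 disables.
#' @param frame_interval Seconds between frames (> 0).
#' @param n_frames Number of frames (>= injury_frame + 2).
#' @param injury_frame 1-based index of the injury frame.
#' @param background Extracellular intensity, AU.
#' @param dynamic_range Detector clip level, AU (16-bit default).
#' @return Object of class `influx_model`.
#' @export
influx_model <- function(baseline_intensity = 100, influx_rate = 5,
                         repair_time = NULL, noise_sd = 2, photon_scale = 0.5,
                         frame_interval = 2, n_frames = 90, injury_frame = 10,
                         background = 10, dynamic_range = 65535) {
  if (influx_rate < 0) stop("influx_rate must be >= 0")
  if (!is.null(repair_time) && repair_time <= 0)
    stop("repair_time must be > 0 when present")
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  if (noise_sd < 0 || photon_scale < 0)
    stop("noise parameters must be >= 0")
  if (n_frames < injury_frame + 2)
    stop("n_frames must be at least injury_frame + 2")
  structure(list(baseline_intensity = baseline_intensity,
                 influx_rate = influx_rate, repair_time = repair_time,
                 noise_sd = noise_sd, photon_scale = photon_scale,
                 frame_interval = frame_interval, n_frames = n_frames,
                 injury_frame = as.integer(injury_frame),
                 background = background, dynamic_range = dynamic_range),
            class = "influx_model")
}

# noise-free in-cell intensity per frame
influx_truth_values <- function(model) {
  t_rel <- (seq_len(model$n_frames) - model$injury_frame) * model$frame_interval
  cap <- model$repair_time %||% Inf
  v <- model$baseline_intensity +
    model$influx_rate * pmax(0, pmin(t_rel, cap))
  pmin(v, model$dynamic_range)
}

influx_truth_trace <- function(model) {
  t_rel <- (seq_len(model$n_frames) - model$injury_frame) * model$frame_interval
  kinetic_trace(t_rel, influx_truth_values(model), kind = "raw",
                baseline_window = c(1L, model$injury_frame - 1L),
                injury_index = model$injury_frame,
                meta = list(repairing = !is.null(model$repair_time),
                            repair_time = model$repair_time))
}

# default cell footprint for a given image size
default_cell <- function(dim) {
  ellipse_spec(center = c(dim[1] / 2, dim[2] / 2),
               semiaxes = c(0.31 * dim[1], 0.20 * dim[2]),
               angle = 0.4)
}

# small square background region in the first image corner clear of the cell
background_corner <- function(cell_poly, dim) {
  s <- 6
  corners <- list(c(3, 3), c(3, dim[2] - 3 - s), c(dim[1] - 3 - s, 3),
                  c(dim[1] - 3 - s, dim[2] - 3 - s))
  for (p in corners) {
    sq <- rbind(p, p + c(0, s), p + c(s, s), p + c(s, 0))
    if (!polygons_overlap(cell_poly, sq)) return(sq)
  }
  NULL
}

#' Generate a synthetic dye-influx stack with ground truth
#'
#' Renders the [influx_model()] trace uniformly inside an elliptical cell
#' mask on a flat extracellular background, applies the camera noise model,
#' and returns the analytic ground-truth trace alongside (computed from the
#' model, never re-measured from pixels).
#'
#' @param model An [influx_model()].
#' @param cell An [ellipse_spec()] cell footprint; a size-appropriate
#'   default is used when omitted.
#' @param dim Image dimensions c(rows, cols).
#' @param seed Integer seed; identical model + seed gives bit-identical
#'   stacks.
#' @return List with elements `stack` ([time_lapse_stack()]), `truth`
#'   (ground-truth [kinetic_trace()]), `roi` ([roi_set()]: inscribed cell
#'   polygon, boundary injury point, clear background corner), `mask`
#'   (logical in-cell mask), `model`, `cell`, `seed`.
#' @export
generate_influx_stack <- function(model, cell = NULL, dim = c(64, 64),
                                  seed = 1) {
  stopifnot(inherits(model, "influx_model"))
  cell <- cell %||% default_cell(dim)
  stopifnot(inherits(cell, "ellipse_spec"))
  mask <- ellipse_mask(cell, dim)
  if (!any(mask)) stop("degenerate geometry: cell mask is empty")
  v <- influx_truth_values(model)
  nT <- model$n_frames
  px <- array(model$background, c(nT, 1, dim[1], dim[2]))
  for (t in seq_len(nT)) {
    fr <- matrix(model$background, dim[1], dim[2])
    fr[mask] <- v[t]
    px[t, 1, , ] <- fr
  }
  px <- withr::with_seed(seed, {
    array(add_camera_noise(px, model$noise_sd, model$photon_scale,
                           model$dynamic_range), dim(px))
  })
  stack <- time_lapse_stack(px, frame_interval = model$frame_interval,
                            channel_names = "fm_dye",
                            injury_frame = model$injury_frame)
  poly <- ellipse_polygon(cell, 48)
  roi <- roi_set(cell_polygon = poly,
                 injury_point = ellipse_point(cell, 0),
                 background_polygon = background_corner(poly, dim))
  list(stack = stack, truth = influx_truth_trace(model), roi = roi,
       mask = mask, model = model, cell = cell, seed = seed)
}

#' Generate a cohort of dye-influx cells with known repair ground truth
#'
#' Builds `n_cells` influx models sharing the acquisition settings of
#' `model`: a fraction `repair_fraction` repair at times drawn uniformly
#' from `repair_time_range`, the rest never repair. With
#' `as_stacks = TRUE` every cell goes through the full image pipeline
#' (stack rendering, ROI mean extraction); otherwise equivalent traces are
#' simulated directly with the ROI-averaged noise level
#' `sqrt(noise_sd^2 + photon_scale * F) / sqrt(roi_area)`.
#'
#' @param n_cells Number of cells.
#' @param repair_fraction Fraction of repairing cells in [0, 1].
#' @param repair_time_range Range (seconds) for repairing cells.
#' @param model Template [influx_model()]; its `repair_time` is ignored.
#' @param as_stacks Render and extract full image stacks (slower, exercises
#'   the whole pipeline).
#' @param roi_area Effective ROI pixel count for trace-level noise when
#'   `as_stacks = FALSE`.
#' @param dim Image dimensions when `as_stacks = TRUE`.
#' @param seed Integer seed.
#' @return List with `traces` (list of raw [kinetic_trace()]s) and
#'   `repaired` (logical ground truth), plus `repair_times`.
#' @export
generate_repair_cohort <- function(n_cells, repair_fraction,
                                   repair_time_range = c(20, 60),
                                   model = influx_model(), as_stacks = FALSE,
                                   roi_area = 800, dim = c(64, 64), seed = 1) {
  stopifnot(n_cells >= 1, repair_fraction >= 0, repair_fraction <= 1)
  n_rep <- round(repair_fraction * n_cells)
  withr::with_seed(seed, {
    repaired <- sample(rep(c(TRUE, FALSE), c(n_rep, n_cells - n_rep)))
    rts <- ifelse(repaired,
                  stats::runif(n_cells, repair_time_range[1], repair_time_range[2]),
                  NA_real_)
    cell_seeds <- sample.int(.Machine$integer.max - 1L, n_cells)
  })
  traces <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    mi <- model
    mi$repair_time <- if (repaired[i]) rts[i] else NULL
    if (as_stacks) {
      gen <- generate_influx_stack(mi, dim = dim, seed = cell_seeds[i])
      traces[[i]] <- extract_mean_trace(gen$stack, gen$roi)
    } else {
      tr <- influx_truth_trace(mi)
      sd_eff <- sqrt(mi$noise_sd^2 + mi$photon_scale * tr$values) /
        sqrt(roi_area)
      vals <- withr::with_seed(cell_seeds[i],
                               tr$values + stats::rnorm(length(tr$values), 0, sd_eff))
      traces[[i]] <- kinetic_trace(tr$times, vals, kind = "raw",
                                   baseline_window = tr$baseline_window,
                                   injury_index = tr$injury_index)
    }
  }
  list(traces = traces, repaired = repaired, repair_times = rts)
}
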