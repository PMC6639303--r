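# Synthetic two-channel ER morphology stacks: tubular reticulum that turns
# punctate ("beads on a string") over a defined portion of the injury axis.

#' ER field model
#'
#' Describes a two-channel synthetic cell for fragmentation scoring. The ER
#' channel carries parallel sinusoidal ridges (tubules) with period
#' `tubule_spacing`; inside the fragmented region the ridges are replaced by
#' Gaussian spots on the ridge skeleton separated by gaps. The fragmented
#' region is exactly the part of the cell whose projection on the injury
#' axis lies within `fragmentation_fraction` of the axis length from the
#' injury point, so the ground-truth fragmented length along the axis is
#' `fragmentation_fraction * axis_length` to within one pixel.
#'
#' @param cell An [ellipse_spec()] cell footprint.
#' @param injury_theta Boundary parameter (radians) of the injury point on
#'   the ellipse; 0 is the major-axis tip.
#' @param fragmentation_fraction Ground-truth fragmented fraction in [0, 1].
#' @param tubule_spacing Ridge period, pixels; must be at least
#'   `2 * puncta_radius` for the two textures to be distinguishable.
#' @param puncta_radius Gaussian spot radius parameter, pixels.
#' @param spot_pitch Spot spacing along a ridge, pixels; default
#'   `max(5 * puncta_radius, tubule_spacing)`.
#' @param noise_sd Gaussian read noise, AU.
#' @param image_size Image dimensions c(rows, cols).
#' @param base_intensity Dim ER background inside the cell, AU.
#' @param amplitude Ridge/spot peak height above `base_intensity`, AU.
#' @param background Extracellular intensity, AU.
#' @param cyto_intensity Second (cytosolic volume) channel level inside the
#'   cell, AU.
#' @return Object of class `er_field_model`.
#' @export
er_field_model <- function(cell = ellipse_spec(c(56, 56), c(45, 25)),
                           injury_theta = 0, fragmentation_fraction = 0.5,
                           tubule_spacing = 6, puncta_radius = 1.2,
                           spot_pitch = NULL, noise_sd = 4,
                           image_size = c(112, 112), base_intensity = 20,
                           amplitude = 100, background = 8,
                           cyto_intensity = 60) {
  stopifnot(inherits(cell, "ellipse_spec"))
  if (fragmentation_fraction < 0 || fragmentation_fraction > 1)
    stop("fragmentation_fraction must lie in [0, 1]")
  if (tubule_spacing < 2 * puncta_radius)
    stop("tubule_spacing < 2 * puncta_radius: tubular and punctate textures ",
         "would be indistinguishable")
  spot_pitch <- spot_pitch %||% max(5 * puncta_radius, tubule_spacing)
  structure(list(cell = cell, injury_theta = injury_theta,
                 fragmentation_fraction = fragmentation_fraction,
                 tubule_spacing = tubule_spacing,
                 puncta_radius = puncta_radius, spot_pitch = spot_pitch,
                 noise_sd = noise_sd, image_size = image_size,
                 base_intensity = base_intensity, amplitude = amplitude,
                 background = background, cyto_intensity = cyto_intensity),
            class = "er_field_model")
}

# injury point, far boundary point and axis length of the model's cell
er_axis_geometry <- function(model) {
  p0 <- ellipse_point(model$cell, model$injury_theta)
  th <- seq(0, 2 * pi, length.out = 721)[-721]
  bnd <- t(vapply(th, function(x) ellipse_point(model$cell, x), numeric(2)))
  d2 <- (bnd[, 1] - p0[1])^2 + (bnd[, 2] - p0[2])^2
  far <- bnd[which.max(d2), ]
  list(p0 = p0, far = far, length = sqrt(max(d2)))
}

#' Generate a synthetic ER fragmentation stack with ground truth
#'
#' Frames before `onset_frame` are fully tubular; frames at and after it
#' carry the punctate texture over the model's fragmented region. The
#' ground truth (axis length, fragmented length and fraction, plus a
#' per-pixel label mask of the punctate region) is computed from the model
#' specification, never re-measured from pixels.
#'
#' @param model An [er_field_model()].
#' @param n_frames Number of frames (> onset_frame - 1).
#' @param onset_frame 1-based frame at which fragmentation appears.
#' @param seed Integer seed.
#' @return List with `stack` (channels `"er"`, `"cyto"`), `truth`
#'   (ground-truth [fragmentation_result()]), `label_mask` (logical Y x X,
#'   punctate region of post-onset frames), `mask`, `roi`, `axis`
#'   (rasterised injury axis with length attribute), `model`,
#'   `onset_frame`, `seed`.
#' @export
generate_er_stack <- function(model, n_frames = 3, onset_frame = 2, seed = 1) {
  stopifnot(inherits(model, "er_field_model"))
  if (onset_frame > n_frames)
    stop("onset_frame must not exceed n_frames")
  dim <- model$image_size
  mask <- ellipse_mask(model$cell, dim)
  geo <- er_axis_geometry(model)
  dvec <- (geo$far - geo$p0) / geo$length
  rr <- matrix(seq_len(dim[1]), dim[1], dim[2])
  cc <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  u <- (rr - geo$p0[1]) * dvec[1] + (cc - geo$p0[2]) * dvec[2]
  w <- -(rr - geo$p0[1]) * dvec[2] + (cc - geo$p0[2]) * dvec[1]

  f <- model$fragmentation_fraction
  label_mask <- mask & (u <= f * geo$length)
  if (f == 0) label_mask[] <- FALSE

  tubular <- model$base_intensity + model$amplitude * 0.5 *
    (1 + cos(2 * pi * w / model$tubule_spacing))

  stack_px <- withr::with_seed(seed, {
    # gapped spots on the ridge skeleton: ridges sit at w = k * spacing,
    # spots along each ridge at pitch spot_pitch with a per-ridge offset
    k <- round(w / model$tubule_spacing)
    dw <- w - k * model$tubule_spacing
    kmin <- min(k); nk <- max(k) - kmin + 1L
    offs <- stats::runif(nk, 0, model$spot_pitch)
    du <- u - offs[k - kmin + 1L]
    du <- du - round(du / model$spot_pitch) * model$spot_pitch
    punctate <- model$base_intensity + model$amplitude *
      exp(-(dw^2 + du^2) / (2 * model$puncta_radius^2))

    px <- array(0, c(n_frames, 2, dim[1], dim[2]))
    for (t in seq_len(n_frames)) {
      er <- matrix(model$background, dim[1], dim[2])
      er[mask] <- tubular[mask]
      if (t >= onset_frame && any(label_mask))
        er[label_mask] <- punctate[label_mask]
      cyto <- matrix(model$background, dim[1], dim[2])
      cyto[mask] <- model$cyto_intensity
      px[t, 1, , ] <- add_camera_noise(er, model$noise_sd, 0, 65535)
      px[t, 2, , ] <- add_camera_noise(cyto, model$noise_sd, 0, 65535)
    }
    px
  })
  stack <- time_lapse_stack(stack_px, frame_interval = 2,
                            channel_names = c("er", "cyto"),
                            injury_frame = onset_frame)
  axis <- rasterize_segment(geo$p0, geo$far)
  attr(axis, "length") <- geo$length
  attr(axis, "start") <- geo$p0
  attr(axis, "end") <- geo$far
  truth <- fragmentation_result(axis_length = geo$length,
                                fragmented_length = f * geo$length,
                                fragmented_fraction = f,
                                axis_coordinates = axis)
  roi <- roi_set(cell_polygon = ellipse_polygon(model$cell, 64),
                 injury_point = geo$p0)
  list(stack = stack, truth = truth, label_mask = label_mask, mask = mask,
       roi = roi, axis = axis, model = model, onset_frame = onset_frame,
       seed = seed)
}
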