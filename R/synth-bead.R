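# Synthetic two-channel dextran fields for the glass-bead injury assay:
# injured cells carry the green (first) dextran, injured cells that failed
# to repair additionally carry the red (second) dextran.

#' Bead-injury field specification
#'
#' Lays out `n_cells` non-overlapping circular cells; `n_injured` of them
#' are green-labelled and `n_failed` of those are additionally red-labelled
#' (failed to repair). Uninjured cells take up neither dextran and are
#' invisible in both channels.
#'
#' @param n_cells Total cells to place.
#' @param n_injured Green-positive cells (<= n_cells).
#' @param n_failed Green-and-red-positive cells (<= n_injured).
#' @param image_size Image dimensions c(rows, cols).
#' @param cell_radius_range Uniform radius range, pixels.
#' @param intensity Labelled-cell intensity, AU.
#' @param background Background intensity, AU.
#' @param noise_sd Gaussian read noise, AU (0 = noise-free field).
#' @param seed Integer seed.
#' @return Object of class `bead_field_spec`.
#' @export
bead_field_spec <- function(n_cells = 150, n_injured = n_cells,
                            n_failed = 0, image_size = c(384, 384),
                            cell_radius_range = c(5, 9), intensity = 200,
                            background = 10, noise_sd = 0, seed = 1) {
  if (!(n_failed <= n_injured && n_injured <= n_cells))
    stop("need n_failed <= n_injured <= n_cells")
  if (cell_radius_range[1] > cell_radius_range[2] || cell_radius_range[1] <= 0)
    stop("invalid cell_radius_range")
  structure(list(n_cells = as.integer(n_cells),
                 n_injured = as.integer(n_injured),
                 n_failed = as.integer(n_failed),
                 image_size = image_size,
                 cell_radius_range = cell_radius_range,
                 intensity = intensity, background = background,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "bead_field_spec")
}

#' Generate a synthetic bead-injury field with per-cell ground truth
#'
#' Cells are placed by rejection sampling with a minimum clearance of 3 px
#' between disc edges; an infeasible packing aborts with an error naming
#' the constraint.
#'
#' @param spec A [bead_field_spec()].
#' @return List with `stack` (a single-frame two-channel
#'   [time_lapse_stack()], channels `"green"`, `"red"`), `truth` (data frame
#'   with cell id, centre, radius, injured and failed flags), `spec`.
#' @export
generate_bead_field <- function(spec) {
  stopifnot(inherits(spec, "bead_field_spec"))
  dim <- spec$image_size
  withr::with_seed(spec$seed, {
    radii <- stats::runif(spec$n_cells, spec$cell_radius_range[1],
                          spec$cell_radius_range[2])
    centers <- matrix(NA_real_, spec$n_cells, 2)
    tries <- 0L
    max_tries <- 400L * spec$n_cells
    for (i in seq_len(spec$n_cells)) {
      repeat {
        tries <- tries + 1L
        if (tries > max_tries)
          stop(sprintf(paste0("could not place %d non-overlapping cells of ",
                              "radius %.3g-%.3g in a %d x %d image"),
                       spec$n_cells, spec$cell_radius_range[1],
                       spec$cell_radius_range[2], dim[1], dim[2]))
        p <- c(stats::runif(1, radii[i] + 2, dim[1] - radii[i] - 1),
               stats::runif(1, radii[i] + 2, dim[2] - radii[i] - 1))
        if (i == 1) { centers[i, ] <- p; break }
        prev <- seq_len(i - 1)
        dmin <- sqrt((centers[prev, 1] - p[1])^2 +
                       (centers[prev, 2] - p[2])^2)
        if (all(dmin >= radii[prev] + radii[i] + 3)) {
          centers[i, ] <- p; break
        }
      }
    }
    injured <- logical(spec$n_cells)
    injured[sample.int(spec$n_cells, spec$n_injured)] <- TRUE
    failed <- logical(spec$n_cells)
    inj_idx <- which(injured)
    failed[inj_idx[sample.int(length(inj_idx), spec$n_failed)]] <- TRUE

    green <- matrix(spec$background, dim[1], dim[2])
    red <- matrix(spec$background, dim[1], dim[2])
    rr <- matrix(seq_len(dim[1]), dim[1], dim[2])
    cc <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
    for (i in seq_len(spec$n_cells)) {
      if (!injured[i]) next
      disc <- (rr - centers[i, 1])^2 + (cc - centers[i, 2])^2 <= radii[i]^2
      green[disc] <- spec$intensity
      if (failed[i]) red[disc] <- spec$intensity
    }
    px <- array(0, c(1, 2, dim[1], dim[2]))
    px[1, 1, , ] <- add_camera_noise(green, spec$noise_sd, 0, 65535)
    px[1, 2, , ] <- add_camera_noise(red, spec$noise_sd, 0, 65535)
    stack <- time_lapse_stack(px, frame_interval = 1,
                              channel_names = c("green", "red"))
    truth <- data.frame(cell = seq_len(spec$n_cells),
                        row = centers[, 1], col = centers[, 2],
                        radius = radii, injured = injured, failed = failed)
    list(stack = stack, truth = truth, spec = spec, seed = spec$seed)
  })
}
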