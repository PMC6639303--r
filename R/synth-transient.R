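# Synthetic cytosolic Ca2+ transients (Fluo-4-like traces).

#' Calcium transient trace model
#'
#' Difference-of-exponentials transient on a flat baseline:
#' `baseline + A * (exp(-(t - t0)/decay_tau) - exp(-(t - t0)/rise_tau))`,
#' renormalised so the analytic peak equals `peak_amplitude` above baseline.
#' The equal-tau limit `t * exp(-t/tau)` is handled explicitly; a
#' `rise_tau` near zero gives a step-then-exponential-decay transient.
#'
#' Defaults emulate an injury-triggered cytosolic transient sampled at
#' video rate: injury 10 s into the recording, 2 s rise, 20 s decay.
#'
#' @param baseline Resting intensity, AU.
#' @param peak_amplitude Peak height above baseline, AU (>= 0).
#' @param rise_tau,decay_tau Rise and decay time constants, seconds (> 0).
#' @param injury_time Transient onset, seconds from recording start.
#' @param noise_sd Additive Gaussian noise, AU.
#' @return Object of class `transient_model`.
#' @export
transient_model <- function(baseline = 100, peak_amplitude = 50,
                            rise_tau = 2, decay_tau = 20, injury_time = 10,
                            noise_sd = 1) {
  if (rise_tau <= 0 || decay_tau <= 0) stop("time constants must be > 0")
  if (peak_amplitude < 0) stop("peak_amplitude must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(baseline = baseline, peak_amplitude = peak_amplitude,
                 rise_tau = rise_tau, decay_tau = decay_tau,
                 injury_time = injury_time, noise_sd = noise_sd),
            class = "transient_model")
}

# unit-peak transient shape at time t (seconds after onset; 0 before onset)
transient_shape <- function(t, rise_tau, decay_tau) {
  s <- numeric(length(t))
  pos <- t >= 0
  if (abs(decay_tau - rise_tau) < 1e-12 * decay_tau) {
    # limit form t/tau * exp(1 - t/tau), unit peak at t = tau
    s[pos] <- (t[pos] / decay_tau) * exp(1 - t[pos] / decay_tau)
  } else {
    g <- exp(-t[pos] / decay_tau) - exp(-t[pos] / rise_tau)
    tp <- log(decay_tau / rise_tau) * rise_tau * decay_tau /
      (decay_tau - rise_tau)
    gmax <- exp(-tp / decay_tau) - exp(-tp / rise_tau)
    s[pos] <- g / gmax
  }
  s
}

#' Generate a synthetic calcium transient trace
#'
#' @param model A [transient_model()].
#' @param frame_interval Seconds between frames; the 0.2 s default matches
#'   video-rate Fluo-4 imaging at 5 frames/s.
#' @param n_frames Number of frames; the default spans 192 s so a 180 s
#'   post-injury analysis window is fully covered.
#' @param seed Integer seed for the additive noise.
#' @return Raw [kinetic_trace()] with the injury frame annotated and the
#'   noise-free model attached in `meta$truth_values`.
#' @export
generate_transient_trace <- function(model, frame_interval = 0.2,
                                     n_frames = 960, seed = 1) {
  stopifnot(inherits(model, "transient_model"))
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  span <- (n_frames - 1) * frame_interval
  if (span < model$injury_time + 3 * model$decay_tau)
    warning(sprintf(paste0("trace span %.3g s is shorter than injury_time + ",
                           "3 * decay_tau = %.3g s; decay will be truncated"),
                    span, model$injury_time + 3 * model$decay_tau))
  t_abs <- (seq_len(n_frames) - 1) * frame_interval
  truth <- model$baseline + model$peak_amplitude *
    transient_shape(t_abs - model$injury_time, model$rise_tau, model$decay_tau)
  vals <- if (model$noise_sd > 0) {
    withr::with_seed(seed, truth + stats::rnorm(n_frames, 0, model$noise_sd))
  } else truth
  injury_frame <- round(model$injury_time / frame_interval) + 1L
  injury_frame <- min(max(injury_frame, 1L), n_frames)
  kinetic_trace((seq_len(n_frames) - injury_frame) * frame_interval, vals,
                kind = "raw",
                baseline_window = if (injury_frame >= 3) c(1L, injury_frame - 1L),
                injury_index = injury_frame,
                meta = list(truth_values = truth, model = model, seed = seed))
}
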