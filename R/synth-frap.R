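# Synthetic FRAP (fluorescence recovery after photobleaching) traces.

#' Generate a synthetic FRAP trace
#'
#' Pre-bleach frames sit at `baseline`; at the bleach frame the signal drops
#' by `bleach_depth` and then recovers mono-exponentially:
#' `baseline * (1 - bleach_depth + mobile_fraction * bleach_depth *
#' (1 - exp(-t/recovery_tau)))` with `t` the time since the bleach frame.
#' An optional acquisition-bleaching multiplier `exp(-t_abs/acq_bleach_tau)`
#' can be applied to emulate imaging-induced fading, together with a
#' matching whole-cell reference trace for correction.
#'
#' @param mobile_fraction Fraction of bleached signal that recovers, in
#'   [0, 1].
#' @param recovery_tau Recovery time constant, seconds (> 0).
#' @param bleach_depth Fractional drop at the bleach frame, in (0, 1].
#' @param frame_interval Seconds between frames.
#' @param n_frames Total frames.
#' @param noise_sd Additive Gaussian noise as a fraction of `baseline`.
#' @param seed Integer seed.
#' @param baseline Pre-bleach intensity, AU.
#' @param n_prebleach Pre-bleach frames (>= 2).
#' @param acq_bleach_tau Optional acquisition-bleaching time constant,
#'   seconds.
#' @return Raw [kinetic_trace()] with the bleach frame annotated as the
#'   event frame; `meta` carries the generating parameters, the noise-free
#'   values, and (when `acq_bleach_tau` is set) a matching `reference`
#'   trace.
#' @export
generate_frap_trace <- function(mobile_fraction, recovery_tau,
                                bleach_depth = 0.8, frame_interval = 1,
                                n_frames = 100, noise_sd = 0.02, seed = 1,
                                baseline = 1000, n_prebleach = 5,
                                acq_bleach_tau = NULL) {
  if (mobile_fraction < 0 || mobile_fraction > 1)
    stop("mobile_fraction must lie in [0, 1]")
  if (recovery_tau <= 0) stop("recovery_tau must be > 0")
  if (bleach_depth <= 0 || bleach_depth > 1)
    stop("bleach_depth must lie in (0, 1]")
  if (n_prebleach < 2) stop("need at least 2 pre-bleach frames")
  bleach_frame <- n_prebleach + 1L
  if (n_frames < bleach_frame + 10)
    stop("need at least 10 post-bleach frames")
  t_abs <- (seq_len(n_frames) - 1) * frame_interval
  t_post <- (seq_len(n_frames) - bleach_frame) * frame_interval
  v <- rep(baseline, n_frames)
  post <- seq_len(n_frames) >= bleach_frame
  v[post] <- baseline * (1 - bleach_depth + mobile_fraction * bleach_depth *
                           (1 - exp(-t_post[post] / recovery_tau)))
  reference <- NULL
  if (!is.null(acq_bleach_tau)) {
    fade <- exp(-t_abs / acq_bleach_tau)
    v <- v * fade
    reference <- kinetic_trace(t_post, baseline * fade, kind = "raw",
                               injury_index = bleach_frame)
  }
  truth <- v
  if (noise_sd > 0)
    v <- withr::with_seed(seed,
                          v + stats::rnorm(n_frames, 0, noise_sd * baseline))
  kinetic_trace(t_post, v, kind = "raw",
                baseline_window = c(1L, n_prebleach),
                injury_index = bleach_frame,
                meta = list(mobile_fraction = mobile_fraction,
                            recovery_tau = recovery_tau,
                            bleach_depth = bleach_depth,
                            truth_values = truth, reference = reference,
                            seed = seed))
}
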