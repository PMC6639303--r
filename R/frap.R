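# FRAP normalization and mono-exponential recovery fitting.

#' Normalize a FRAP trace
#'
#' Scales the trace so the pre-bleach mean is 1. An optional whole-cell
#' reference trace (same frames) divides out acquisition bleaching: the
#' trace is divided pointwise by the reference after the reference is
#' itself normalized to its pre-bleach mean.
#'
#' @param trace Raw [kinetic_trace()] with the bleach frame annotated as
#'   its event frame (or supplied via `bleach_frame`).
#' @param bleach_frame 1-based index of the first post-bleach frame.
#' @param reference Optional reference [kinetic_trace()] from an unbleached
#'   region/cell.
#' @return Normalized raw [kinetic_trace()]; `meta$normalized = TRUE`,
#'   `meta$flags` may contain `"degenerate-reference"` when the reference
#'   cancels the trace exactly.
#' @export
normalize_frap <- function(trace, bleach_frame = NULL, reference = NULL) {
  stopifnot(inherits(trace, "kinetic_trace"))
  bf <- bleach_frame %||% trace$injury_index
  if (is.null(bf)) stop("bleach_frame is required (trace has no event frame)")
  bf <- as.integer(bf)
  if (bf < 3) stop("need at least 2 pre-bleach frames")
  pre <- trace$values[seq_len(bf - 1)]
  prem <- mean(pre)
  if (prem <= 0) stop("pre-bleach mean must be positive")
  post_early <- mean(trace$values[bf:min(bf + 1, length(trace$values))])
  if (post_early >= prem)
    stop("no bleach detected: post-bleach intensity is not below the ",
         "pre-bleach mean")
  v <- trace$values / prem
  flags <- character(0)
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "kinetic_trace"))
    if (length(reference$values) != length(trace$values))
      stop("reference trace must have the same number of frames")
    refn <- reference$values / mean(reference$values[seq_len(bf - 1)])
    if (any(refn <= 0)) stop("reference trace must stay positive")
    v <- v / refn
    if (stats::sd(v[bf:length(v)]) < 1e-9) {
      flags <- "degenerate-reference"
      warning("reference correction cancelled the trace (reference ",
              "identical to the measured region?)")
    }
  }
  kinetic_trace(trace$times, v, kind = "raw",
                baseline_window = c(1L, bf - 1L), injury_index = bf,
                meta = c(trace$meta,
                         list(normalized = TRUE,
                              reference_corrected = !is.null(reference),
                              flags = flags)))
}

#' Fit mono-exponential FRAP recovery
#'
#' Least-squares fit of `f(t) = y0 + M * (1 - exp(-t / tau))` to the
#' post-bleach points of a normalized trace (`t` = seconds since bleach).
#' The mobile fraction is `M / (1 - y0)`: the recovered fraction of the
#' bleached signal. All three parameters are free in the fit; the mean of
#' the first two post-bleach frames provides the starting value for `y0`
#' and is reported as `post_bleach_level`.
#'
#' @param trace Normalized [kinetic_trace()] from [normalize_frap()] with
#'   at least 10 post-bleach frames.
#' @param bleach_frame Override for the bleach frame index.
#' @return Object of class `frap_fit`: `mobile_fraction`,
#'   `recovery_tau`, `recovery_halftime` (= tau * log 2), `bleach_frame`,
#'   `y0`, `post_bleach_level`, `normalized_trace`, `fit_residual_rms`,
#'   `flags` (`"implausible"` when the mobile fraction leaves
#'   [-0.05, 1.05]; `"no-recovery"` for a flat post-bleach trace).
#' @export
fit_recovery <- function(trace, bleach_frame = NULL) {
  stopifnot(inherits(trace, "kinetic_trace"))
  bf <- as.integer(bleach_frame %||% trace$injury_index)
  if (is.null(bf) || is.na(bf)) stop("bleach_frame is required")
  n <- length(trace$values)
  if (n - bf + 1 < 10) stop("need at least 10 post-bleach frames")
  tp <- trace$times[bf:n] - trace$times[bf]
  y <- trace$values[bf:n]
  y0_start <- mean(y[1:2])

  out <- function(mobile, tau, y0, rms, flags) {
    structure(list(mobile_fraction = mobile, recovery_tau = tau,
                   recovery_halftime = tau * log(2), bleach_frame = bf,
                   y0 = y0, post_bleach_level = y0_start,
                   normalized_trace = trace, fit_residual_rms = rms,
                   flags = flags),
              class = "frap_fit")
  }

  if (stats::sd(y) < 1e-10)
    return(out(0, NA_real_, y[1], 0, "no-recovery"))

  plateau <- mean(utils::tail(y, max(3, length(y) %/% 10)))
  m_start <- max(plateau - y0_start, 1e-3)
  half_idx <- which(y >= y0_start + m_start / 2)[1]
  tau_start <- if (!is.na(half_idx) && tp[half_idx] > 0)
    tp[half_idx] / log(2) else max(tp) / 3
  df <- data.frame(tp = tp, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ y0 + M * (1 - exp(-tp / tau)), data = df,
                      start = list(y0 = y0_start, M = m_start,
                                   tau = tau_start),
                      lower = c(y0 = -0.5, M = 0, tau = 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop(sprintf(paste0("FRAP fit did not converge: %s (starts: y0 = %.3g, ",
                          "M = %.3g, tau = %.3g)"),
                   conditionMessage(e), y0_start, m_start, tau_start)))
  cf <- stats::coef(fit)
  mobile <- unname(cf["M"] / (1 - cf["y0"]))
  flags <- character(0)
  if (mobile > 1.05 || mobile < -0.05) flags <- "implausible"
  rms <- sqrt(mean(stats::resid(fit)^2))
  out(mobile, unname(cf["tau"]), unname(cf["y0"]), rms, flags)
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf("<frap_fit> mobile fraction = %.3f, tau = %.3g s (t1/2 = %.3g s), rms = %.2g\n",
              x$mobile_fraction, x$recovery_tau, x$recovery_halftime,
              x$fit_residual_rms))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
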