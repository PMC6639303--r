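# Repaired/failed classification from dye-entry delta-F/F traces, and
# cohort-level summaries.

#' Fragmentation-free repair call for one injured cell
#'
#' A cell is called repaired when its dye-entry trace plateaus: the
#' Gaussian-smoothed trace has least-squares slope below `slope_epsilon`
#' over some sliding window of `window` seconds starting no later than
#' `horizon` seconds after injury. The plateau onset is then refined by a
#' hinge (ramp-then-flat) least-squares fit over the post-injury trace,
#' which localises the corner to a frame even through the smoothing.
#'
#' The defaults sit between the behaviours expected of repairing cells
#' (entry stops within about a minute) and non-repairing cells (entry
#' continues beyond two minutes): window 20 s, slope threshold 0.5% dF/F
#' per second, horizon 120 s, smoothing sigma 2 frames.
#'
#' @param trace A delta-F/F [kinetic_trace()] covering at least `horizon`
#'   seconds after injury.
#' @param window Sliding-window length, seconds.
#' @param slope_epsilon Plateau slope threshold, dF/F per second.
#' @param horizon Latest allowed plateau onset, seconds after injury.
#' @param smoothing_sigma Gaussian smoothing sigma, frames.
#' @param saturation_dff Optional dF/F level at which the detector is known
#'   to clip; traces reaching it are flagged `"saturated"` and not called
#'   repaired, since clipping mimics a plateau.
#' @return Object of class `repair_result`: fields `trace`, `repaired`,
#'   `plateau_time` (seconds post-injury, present iff repaired),
#'   `final_dff`, `flags`, `params`.
#' @export
classify_repair <- function(trace, window = 20, slope_epsilon = 0.005,
                            horizon = 120, smoothing_sigma = 2,
                            saturation_dff = NULL) {
  stopifnot(inherits(trace, "kinetic_trace"))
  if (trace$kind != "dff") stop("classify_repair needs a delta-F/F trace")
  tmax <- trace$times[length(trace$times)]
  if (tmax < horizon)
    stop(sprintf("insufficient observation: trace ends %.3g s post-injury, horizon is %.3g s",
                 tmax, horizon))
  dt <- trace$frame_interval
  sm <- gaussian_smooth(trace$values, smoothing_sigma)
  flags <- character(0)
  params <- list(window = window, slope_epsilon = slope_epsilon,
                 horizon = horizon, smoothing_sigma = smoothing_sigma,
                 saturation_dff = saturation_dff)

  if (!is.null(saturation_dff) &&
      max(trace$values, sm) >= saturation_dff - 1e-9) {
    return(structure(list(trace = trace, repaired = FALSE,
                          plateau_time = NULL,
                          final_dff = mean(utils::tail(sm, 3)),
                          flags = "saturated", params = params),
                     class = "repair_result"))
  }

  wlen <- max(2L, round(window / dt))
  n <- length(sm)
  starts <- which(trace$times >= 0 & trace$times <= horizon)
  starts <- starts[starts + wlen <= n]
  repaired <- FALSE
  for (i in starts) {
    idx <- i:(i + wlen)
    if (reg_slope(trace$times[idx], sm[idx]) < slope_epsilon) {
      repaired <- TRUE
      break
    }
  }

  plateau_time <- NULL
  if (repaired) {
    post <- which(trace$times >= 0)
    tp <- trace$times[post]
    y <- trace$values[post]
    best <- Inf; best_tc <- tp[1]
    for (tc in tp) {
      x <- pmax(0, tc - tp)
      fit <- stats::lm.fit(cbind(1, x), y)
      sse <- sum(fit$residuals^2)
      if (sse < best - 1e-12) {
        best <- sse
        best_tc <- tc
      }
    }
    plateau_time <- max(0, best_tc)
  }

  structure(list(trace = trace, repaired = repaired,
                 plateau_time = plateau_time,
                 final_dff = mean(utils::tail(sm, 3)),
                 flags = flags, params = params),
            class = "repair_result")
}

#' @export
print.repair_result <- function(x, ...) {
  cat(sprintf("<repair_result> %s%s, final dF/F = %.3g\n",
              if (x$repaired) "repaired" else "failed",
              if (x$repaired) sprintf(" (plateau at %.3g s)", x$plateau_time)
              else "",
              x$final_dff))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Cohort summary of repair results
#'
#' Per-group fraction of repaired cells with counts, and the per-time-point
#' mean and standard error of the dF/F time course (the standard
#' presentation of dye-entry kinetics).
#'
#' @param results List of [classify_repair()] results.
#' @param group_labels Character/factor vector, one label per result.
#' @param resample Allow linear resampling onto a common time grid when
#'   frame intervals differ between cells; without it, mixed intervals are
#'   an error.
#' @return List of class `repair_cohort_summary` with data frames
#'   `fractions` (group, n, n_repaired, fraction_repaired) and `timecourse`
#'   (group, time, mean, sem, n).
#' @export
cohort_repair_summary <- function(results, group_labels, resample = FALSE) {
  stopifnot(length(results) == length(group_labels), length(results) >= 1)
  if (!all(vapply(results, inherits, logical(1), "repair_result")))
    stop("results must be a list of repair_result objects")
  groups <- unique(as.character(group_labels))
  traces <- lapply(results, function(r) r$trace)
  dts <- vapply(traces, function(tr) tr$frame_interval, numeric(1))
  if (max(dts) - min(dts) > 1e-9 * max(dts)) {
    if (!resample)
      stop("traces have mixed frame intervals; set resample = TRUE to ",
           "interpolate onto a common grid")
    grid <- seq(max(vapply(traces, function(tr) tr$times[1], numeric(1))),
                min(vapply(traces, function(tr) max(tr$times), numeric(1))),
                by = max(dts))
    mat <- vapply(traces, function(tr)
      stats::approx(tr$times, tr$values, grid)$y, numeric(length(grid)))
  } else {
    nmin <- min(vapply(traces, function(tr) length(tr$times), integer(1)))
    grid <- traces[[1]]$times[seq_len(nmin)]
    mat <- vapply(traces, function(tr) tr$values[seq_len(nmin)],
                  numeric(nmin))
  }

  fractions <- do.call(rbind, lapply(groups, function(g) {
    sel <- as.character(group_labels) == g
    nr <- sum(vapply(results[sel], function(r) r$repaired, logical(1)))
    data.frame(group = g, n = sum(sel), n_repaired = nr,
               fraction_repaired = nr / sum(sel))
  }))
  timecourse <- do.call(rbind, lapply(groups, function(g) {
    sel <- which(as.character(group_labels) == g)
    sub <- mat[, sel, drop = FALSE]
    data.frame(group = g, time = grid,
               mean = rowMeans(sub),
               sem = apply(sub, 1, sem),
               n = length(sel))
  }))
  structure(list(fractions = fractions, timecourse = timecourse),
            class = "repair_cohort_summary")
}

#' @export
print.repair_cohort_summary <- function(x, ...) {
  cat("<repair_cohort_summary>\n")
  print(x$fractions, row.names = FALSE)
  invisible(x)
}
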