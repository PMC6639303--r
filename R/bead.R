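# Counting injured and failed-to-repair cells in two-channel dextran
# images from the glass-bead injury assay.

# half-maximum automatic threshold: background (median) plus half the
# dynamic range above it. Returns Inf for a featureless channel so that
# nothing is called positive.
half_max_threshold <- function(ch) {
  bg <- stats::median(ch)
  mx <- max(ch)
  if (mx - bg < 1e-9) Inf else bg + 0.5 * (mx - bg)
}

#' Segment labelled cells in a two-channel dextran image
#'
#' Cells are detected as connected components of the per-pixel maximum
#' across the two channels (so a cell bright in either channel is found,
#' and swapping the channels swaps the per-cell flags exactly), filtered by
#' `min_area`. Each cell is then scored positive per channel by comparing
#' its mask-mean intensity with the channel threshold. Automatic
#' thresholds use the half-maximum rule (median + half the range above it),
#' which stays well-defined when a channel has no positive cells at all;
#' both thresholds can be overridden.
#'
#' @param image A single-frame two-channel [time_lapse_stack()] (channels
#'   green, red in that order) or a 2 x Y x X array.
#' @param min_area Minimum component area, pixels.
#' @param green_threshold,red_threshold Optional manual thresholds, AU.
#' @return Data frame with one row per detected cell: `cell`, `row`, `col`
#'   (centroid), `area`, `mean_green`, `mean_red`, `green_positive`,
#'   `red_positive`. Thresholds used are attached as attributes. A blank
#'   image yields an empty table with a warning.
#' @export
segment_labelled_cells <- function(image, min_area = 20,
                                   green_threshold = NULL,
                                   red_threshold = NULL) {
  if (inherits(image, "time_lapse_stack")) {
    if (dim(image$pixels)[1] != 1 || dim(image$pixels)[2] != 2)
      stop("expected a single-frame two-channel stack")
    g <- frame_matrix(image, 1, 1)
    r <- frame_matrix(image, 1, 2)
  } else if (is.array(image) && length(dim(image)) == 3 && dim(image)[1] == 2) {
    g <- matrix(image[1, , ], dim(image)[2], dim(image)[3])
    r <- matrix(image[2, , ], dim(image)[2], dim(image)[3])
  } else {
    stop("image must be a two-channel stack or a 2 x Y x X array")
  }
  gthr <- green_threshold %||% half_max_threshold(g)
  rthr <- red_threshold %||% half_max_threshold(r)
  det <- pmax(g, r)
  mask <- det > min(gthr, rthr)

  empty <- data.frame(cell = integer(0), row = numeric(0), col = numeric(0),
                      area = integer(0), mean_green = numeric(0),
                      mean_red = numeric(0), green_positive = logical(0),
                      red_positive = logical(0))
  attr(empty, "green_threshold") <- gthr
  attr(empty, "red_threshold") <- rthr
  if (!any(mask)) {
    warning("no labelled cells detected")
    return(empty)
  }
  lab <- round(EBImage::bwlabel(mask))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  if (length(keep) == 0) {
    warning("no labelled cells detected above min_area")
    return(empty)
  }
  rr <- matrix(seq_len(nrow(g)), nrow(g), ncol(g))
  cc <- matrix(seq_len(ncol(g)), nrow(g), ncol(g), byrow = TRUE)
  idx <- lab > 0 & matrix(lab %in% keep, nrow(g), ncol(g))
  labv <- lab[idx]
  tab <- data.frame(
    cell = seq_along(keep),
    row = as.numeric(tapply(rr[idx], labv, mean)),
    col = as.numeric(tapply(cc[idx], labv, mean)),
    area = as.integer(tapply(labv, labv, length)),
    mean_green = as.numeric(tapply(g[idx], labv, mean)),
    mean_red = as.numeric(tapply(r[idx], labv, mean)))
  tab$green_positive <- tab$mean_green > gthr
  tab$red_positive <- tab$mean_red > rthr
  attr(tab, "green_threshold") <- gthr
  attr(tab, "red_threshold") <- rthr
  tab
}

#' Failure rate from a per-cell label table
#'
#' Injured cells are the green-positive ones; of those, the red-positive
#' cells failed to repair. The failure rate is the failed count expressed
#' as a percentage of all injured cells. Red-only cells (red without
#' green) are biologically anomalous and counted separately.
#'
#' @param table Data frame from [segment_labelled_cells()].
#' @return Object of class `bead_assay_counts`: `n_injured`, `n_failed`,
#'   `percent_failed` (NA with flag `"no-injured-cells"` when nothing is
#'   green-positive), `n_red_only`, `per_cell_table`.
#' @export
compute_failure_rate <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("green_positive", "red_positive") %in% names(table)))
  n_injured <- sum(table$green_positive)
  n_failed <- sum(table$green_positive & table$red_positive)
  n_red_only <- sum(table$red_positive & !table$green_positive)
  flags <- character(0)
  pct <- if (n_injured > 0) 100 * n_failed / n_injured else {
    flags <- "no-injured-cells"
    NA_real_
  }
  if (n_red_only > 0) flags <- c(flags, "red-only-cells")
  structure(list(n_injured = n_injured, n_failed = n_failed,
                 percent_failed = pct, n_red_only = n_red_only,
                 per_cell_table = table, flags = flags),
            class = "bead_assay_counts")
}

#' @export
print.bead_assay_counts <- function(x, ...) {
  cat(sprintf("<bead_assay_counts> %d injured, %d failed to repair (%s)\n",
              x$n_injured, x$n_failed,
              if (is.na(x$percent_failed)) "percentage undefined"
              else sprintf("%.1f%%", x$percent_failed)))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
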