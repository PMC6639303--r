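# Two-group statistical comparisons and figure-style summaries.

# exact two-sided Mann-Whitney p by complete enumeration of group
# assignments; ties handled with midrank U counting (0.5 per tied pair).
mw_u_statistic <- function(a, b) {
  sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}

mw_exact_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  u_obs <- mw_u_statistic(a, b)
  combs <- utils::combn(length(pooled), na)
  us <- apply(combs, 2, function(ix)
    mw_u_statistic(pooled[ix], pooled[-ix]))
  eps <- 1e-9
  min(1, 2 * min(mean(us <= u_obs + eps), mean(us >= u_obs - eps)))
}

# median-centred Levene (Brown-Forsythe) equal-variance test
levene_median_p <- function(a, b) {
  z <- c(abs(a - stats::median(a)), abs(b - stats::median(b)))
  g <- factor(rep(c("a", "b"), c(length(a), length(b))))
  if (stats::sd(z) < 1e-12) return(1)
  stats::anova(stats::lm(z ~ g))[["Pr(>F)"]][1]
}

#' Compare two groups of measurements
#'
#' Reproduces the standard two-group workflow for reporting cell-level
#' assay summaries: an unpaired Student's t-test when both samples pass a
#' Shapiro-Wilk normality check and a median-centred Levene equal-variance
#' check (both at alpha = 0.05), otherwise the Mann-Whitney rank-sum test.
#' All tests are two-sided. The Mann-Whitney p-value is exact (complete
#' enumeration, midranks for ties) when both groups have at most 8
#' observations, and uses the normal approximation with tie correction
#' otherwise.
#'
#' @param values_a,values_b Numeric samples of size >= 2 (>= 3 each for the
#'   automatic normality check).
#' @param test `"auto"` (default), `"student_t"` or `"mann_whitney"`.
#' @param labels Length-2 character vector naming the groups.
#' @return Object of class `group_comparison`: `test_used`, `statistic`,
#'   `p_value`, `n_a`, `n_b`, `effect_summary` (means, SEMs, medians),
#'   `checks` (normality/equal-variance p-values when auto selection ran).
#' @export
compare_groups <- function(values_a, values_b,
                           test = c("auto", "student_t", "mann_whitney"),
                           labels = c("A", "B")) {
  test <- match.arg(test)
  a <- as.numeric(values_a); b <- as.numeric(values_b)
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 observations")
  checks <- NULL
  out <- function(test_used, statistic, p_value) {
    structure(list(group_a = labels[1], group_b = labels[2],
                   test_used = test_used, statistic = statistic,
                   p_value = p_value, n_a = length(a), n_b = length(b),
                   effect_summary = data.frame(
                     group = labels,
                     mean = c(mean(a), mean(b)),
                     sem = c(sem(a), sem(b)),
                     median = c(stats::median(a), stats::median(b)),
                     n = c(length(a), length(b))),
                   checks = checks),
              class = "group_comparison")
  }

  if (stats::sd(c(a, b)) < 1e-12) {
    warning("both samples are identical constants: zero variance, p = 1")
    return(out("mann_whitney", mw_u_statistic(a, b), 1))
  }

  if (test == "auto") {
    if (length(a) < 3 || length(b) < 3)
      stop("auto test selection needs >= 3 observations per group")
    sh_a <- if (stats::sd(a) < 1e-12) 0 else stats::shapiro.test(a)$p.value
    sh_b <- if (stats::sd(b) < 1e-12) 0 else stats::shapiro.test(b)$p.value
    lev <- levene_median_p(a, b)
    checks <- list(shapiro_a = sh_a, shapiro_b = sh_b, levene = lev)
    test <- if (sh_a > 0.05 && sh_b > 0.05 && lev > 0.05)
      "student_t" else "mann_whitney"
  }

  if (test == "student_t") {
    tt <- stats::t.test(a, b, var.equal = TRUE)
    out("student_t", unname(tt$statistic), tt$p.value)
  } else {
    u <- mw_u_statistic(a, b)
    p <- if (length(a) <= 8 && length(b) <= 8) {
      mw_exact_p(a, b)
    } else {
      suppressWarnings(
        stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
    }
    out("mann_whitney", u, p)
  }
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s vs %s: %s, statistic = %.4g, p = %.4g\n",
              x$group_a, x$group_b,
              if (x$test_used == "student_t") "Student's t (unpaired)"
              else "Mann-Whitney rank sum",
              x$statistic, x$p_value))
  print(x$effect_summary, row.names = FALSE)
  invisible(x)
}

#' Render figure-style summaries of assay outputs
#'
#' Produces the mean +/- SEM presentations used to report these assays,
#' one figure and one tidy CSV per input table, and annotates two-group
#' comparisons with the selected test and p-value.
#'
#' Each table must contain the grouping column. A table with `time` and
#' `value` columns is drawn as a per-group mean +/- SEM time course; a
#' table with a `value` column alone as a group summary (bar of the mean,
#' SEM error bars, jittered per-cell points).
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory (created if needed).
#' @param grouping Name of the grouping column.
#' @param test Test passed to [compare_groups()] for two-group annotation.
#' @return Invisible named list of the per-table summary data frames (the
#'   same numbers written to CSV).
#' @export
render_summary <- function(tables, out_dir, grouping = "group",
                           test = "auto") {
  if (!is.list(tables) || length(tables) == 0 || is.null(names(tables)) ||
      any(names(tables) == ""))
    stop("tables must be a non-empty named list of data frames")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  summaries <- list()
  for (nm in names(tables)) {
    df <- tables[[nm]]
    if (!is.data.frame(df)) stop(sprintf("'%s' is not a data frame", nm))
    for (col in c(grouping, "value"))
      if (!col %in% names(df))
        stop(sprintf("table '%s' is missing required column '%s'", nm, col))
    df[[grouping]] <- as.character(df[[grouping]])
    groups <- unique(df[[grouping]])
    kinetic <- "time" %in% names(df)

    if (kinetic) {
      summ <- do.call(rbind, lapply(groups, function(g) {
        sub <- df[df[[grouping]] == g, ]
        agg <- stats::aggregate(sub$value, by = list(time = sub$time),
                                FUN = function(v) c(mean(v), sem(v), length(v)))
        data.frame(group = g, time = agg$time, mean = agg$x[, 1],
                   sem = agg$x[, 2], n = agg$x[, 3])
      }))
      p <- ggplot2::ggplot(summ, ggplot2::aes(x = time, y = mean,
                                              colour = group,
                                              fill = group)) +
        ggplot2::geom_ribbon(ggplot2::aes(ymin = mean - sem,
                                          ymax = mean + sem),
                             alpha = 0.25, colour = NA) +
        ggplot2::geom_line() +
        ggplot2::labs(x = "time (s)", y = "value (mean ± SEM)",
                      title = nm) +
        ggplot2::theme_classic()
    } else {
      summ <- do.call(rbind, lapply(groups, function(g) {
        v <- df$value[df[[grouping]] == g]
        data.frame(group = g, n = length(v), mean = mean(v), sem = sem(v),
                   median = stats::median(v))
      }))
      subtitle <- NULL
      if (length(groups) == 2) {
        cmp <- compare_groups(df$value[df[[grouping]] == groups[1]],
                              df$value[df[[grouping]] == groups[2]],
                              test = test, labels = groups)
        subtitle <- sprintf("%s p = %.4g",
                            if (cmp$test_used == "student_t")
                              "Student's t" else "Mann-Whitney",
                            cmp$p_value)
        summ$test <- cmp$test_used
        summ$p_value <- cmp$p_value
      }
      p <- ggplot2::ggplot(summ, ggplot2::aes(x = group, y = mean)) +
        ggplot2::geom_col(fill = "grey80", colour = "black", width = 0.6) +
        ggplot2::geom_errorbar(ggplot2::aes(ymin = mean - sem,
                                            ymax = mean + sem),
                               width = 0.2) +
        ggplot2::geom_jitter(data = df,
                             ggplot2::aes(x = .data[[grouping]], y = value),
                             width = 0.1, size = 0.8, alpha = 0.6) +
        ggplot2::labs(x = NULL, y = "value", title = nm,
                      subtitle = subtitle) +
        ggplot2::theme_classic()
    }
    utils::write.csv(summ, file.path(out_dir, paste0(nm, "_summary.csv")),
                     row.names = FALSE)
    ggplot2::ggsave(file.path(out_dir, paste0(nm, ".png")), p,
                    width = 5, height = 4, dpi = 150)
    summaries[[nm]] <- summ
  }
  invisible(summaries)
}
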