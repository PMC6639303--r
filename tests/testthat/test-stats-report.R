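# Two-group comparisons and summary rendering.

test_that("exact Mann-Whitney matches a brute-force enumeration oracle", {
  a <- 1:5; b <- 6:10
  cmp <- compare_groups(a, b, test = "mann_whitney")
  expect_equal(cmp$statistic, 0)
  # frozen analytic value: U = 0 is the single most extreme of the
  # choose(10, 5) = 252 equally likely assignments; two-sided p = 2/252
  expect_equal(cmp$p_value, 2 / 252, tolerance = 1e-12)

  # independent enumeration oracle over all assignments of the pooled
  # sample, using rank sums
  pooled <- c(a, b)
  combs <- utils::combn(10, 5)
  r <- rank(pooled)
  u_all <- apply(combs, 2, function(ix) sum(r[ix]) - 5 * 6 / 2)
  u_obs <- sum(rank(pooled)[1:5]) - 15
  p_oracle <- min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
  expect_equal(cmp$p_value, p_oracle)

  # cross-check against the standard exact implementation
  expect_equal(cmp$p_value,
               stats::wilcox.test(a, b, exact = TRUE)$p.value)
})

test_that("degenerate and tied samples are handled", {
  expect_warning(cmp <- compare_groups(c(3, 3, 3), c(3, 3, 3)),
                 "zero variance")
  expect_equal(cmp$p_value, 1)

  # identical (non-constant) samples: p = 1 by symmetry
  cmp2 <- compare_groups(c(1, 2, 5), c(1, 2, 5), test = "mann_whitney")
  expect_equal(cmp2$p_value, 1)

  # exact p is symmetric in the group order
  a <- c(1, 4, 4, 7); b <- c(2, 4, 9, 12)
  expect_equal(compare_groups(a, b, test = "mann_whitney")$p_value,
               compare_groups(b, a, test = "mann_whitney")$p_value)

  expect_error(compare_groups(1, 1:5), "at least 2")
  expect_error(compare_groups(c(1, 2), c(3, 4), test = "auto"), ">= 3")
})

test_that("auto selection picks the t-test for clean normal data and the
          rank test otherwise", {
  withr::with_seed(13, {
    a <- stats::rnorm(15); b <- stats::rnorm(15, 0.5)
  })
  cmp <- compare_groups(a, b)
  expect_identical(cmp$test_used, "student_t")
  expect_true(all(unlist(cmp$checks) > 0.05))

  # grossly unequal variances fail the Levene check
  withr::with_seed(6, {
    a2 <- stats::rnorm(20, sd = 0.1); b2 <- stats::rnorm(20, sd = 10)
  })
  cmp2 <- compare_groups(a2, b2)
  expect_identical(cmp2$test_used, "mann_whitney")

  # strongly skewed data fail the normality check
  withr::with_seed(7, {
    a3 <- stats::rexp(20)^3; b3 <- stats::rexp(20)^3
  })
  cmp3 <- compare_groups(a3, b3)
  expect_identical(cmp3$test_used, "mann_whitney")
})

test_that("large-sample Mann-Whitney uses the tie-corrected approximation", {
  withr::with_seed(8, {
    a <- sample(1:5, 30, TRUE); b <- sample(2:6, 30, TRUE)
  })
  cmp <- compare_groups(a, b, test = "mann_whitney")
  expect_equal(cmp$p_value,
               suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                                   correct = TRUE)$p.value))
})

test_that("render_summary writes figures and CSVs that match the cohort
          numbers", {
  out <- withr::local_tempdir()
  coh_a <- generate_repair_cohort(8, 0.75, model = quiet_influx(), seed = 31)
  coh_b <- generate_repair_cohort(8, 0.25, model = quiet_influx(), seed = 32)
  results <- lapply(c(coh_a$traces, coh_b$traces), function(tr)
    classify_repair(to_delta_f_over_f(tr)))
  groups <- rep(c("healthy", "patient"), each = 8)
  summ <- cohort_repair_summary(results, groups)

  tabs <- list(
    fraction_repaired = data.frame(
      group = groups,
      value = as.numeric(vapply(results, function(r) r$repaired, logical(1)))),
    dye_entry = do.call(rbind, lapply(seq_along(results), function(i)
      data.frame(group = groups[i],
                 time = results[[i]]$trace$times,
                 value = results[[i]]$trace$values))))
  rendered <- render_summary(tabs, out_dir = out)
  expect_true(file.exists(file.path(out, "fraction_repaired.png")))
  expect_true(file.exists(file.path(out, "fraction_repaired_summary.csv")))
  expect_true(file.exists(file.path(out, "dye_entry.png")))
  # the rendered means are the cohort fractions
  fr <- rendered$fraction_repaired
  expect_equal(fr$mean[match(c("healthy", "patient"), fr$group)],
               summ$fractions$fraction_repaired[
                 match(c("healthy", "patient"), summ$fractions$group)])
  expect_true(all(c("test", "p_value") %in% names(fr)))

  # a single-group table renders without a test annotation
  one <- render_summary(list(peak = data.frame(group = "g",
                                               value = stats::rnorm(5))),
                        out_dir = out)
  expect_false("p_value" %in% names(one$peak))

  expect_error(render_summary(list(), out_dir = out), "non-empty")
  expect_error(render_summary(list(x = data.frame(g = 1, value = 2)),
                              out_dir = out),
               "missing required column 'group'")
})
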