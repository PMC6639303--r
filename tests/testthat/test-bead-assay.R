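# Two-channel bead-injury counting.

test_that("a blank field yields an empty table with a warning, not an error", {
  px <- array(10, c(1, 2, 64, 64))
  st <- time_lapse_stack(px, 1, c("green", "red"))
  expect_warning(tab <- segment_labelled_cells(st), "no labelled cells")
  expect_equal(nrow(tab), 0)
  counts <- compute_failure_rate(tab)
  expect_true(is.na(counts$percent_failed))
  expect_true("no-injured-cells" %in% counts$flags)
})

test_that("counts are exact on a noise-free 150/30 field", {
  g <- generate_bead_field(bead_field_spec(n_cells = 150, n_injured = 150,
                                           n_failed = 30, seed = 12))
  tab <- segment_labelled_cells(g$stack)
  counts <- compute_failure_rate(tab)
  expect_equal(counts$n_injured, 150)
  expect_equal(counts$n_failed, 30)
  expect_equal(counts$percent_failed, 20)
  expect_equal(counts$n_red_only, 0)
})

test_that("swapping the channels swaps the per-cell flags exactly", {
  g <- generate_bead_field(bead_field_spec(n_cells = 60, n_injured = 40,
                                           n_failed = 15, seed = 13,
                                           image_size = c(256, 256)))
  tab <- segment_labelled_cells(g$stack)
  swapped <- time_lapse_stack(g$stack$pixels[, 2:1, , , drop = FALSE], 1,
                              c("green", "red"))
  tab2 <- segment_labelled_cells(swapped)
  expect_equal(nrow(tab), nrow(tab2))
  expect_identical(tab$green_positive, tab2$red_positive)
  expect_identical(tab$red_positive, tab2$green_positive)
  # red-only cells (the swapped non-failed injured ones) are anomalies
  counts2 <- compute_failure_rate(tab2)
  expect_equal(counts2$n_red_only, 25)
  expect_true("red-only-cells" %in% counts2$flags)
})

test_that("failure percentage is exact arithmetic on the counts", {
  tab <- data.frame(green_positive = rep(TRUE, 150),
                    red_positive = rep(c(TRUE, FALSE), c(30, 120)))
  expect_equal(compute_failure_rate(tab)$percent_failed, 20)
  tab0 <- data.frame(green_positive = rep(TRUE, 10),
                     red_positive = rep(FALSE, 10))
  expect_equal(compute_failure_rate(tab0)$percent_failed, 0)
})

test_that("counts are exact over randomized feasible specs", {
  withr::with_seed(77, {
    for (i in 1:10) {
      n <- sample(20:50, 1)
      ni <- sample(0:n, 1)
      nf <- sample(0:ni, 1)
      spec <- bead_field_spec(n_cells = n, n_injured = ni, n_failed = nf,
                              image_size = c(256, 256),
                              cell_radius_range = c(4, 7),
                              seed = sample.int(1e6, 1))
      g <- generate_bead_field(spec)
      counts <- suppressWarnings(
        compute_failure_rate(segment_labelled_cells(g$stack)))
      expect_equal(counts$n_injured, ni)
      expect_equal(counts$n_failed, nf)
    }
  })
})

test_that("percent failed is invariant to translation and 90-degree rotation", {
  g <- generate_bead_field(bead_field_spec(n_cells = 40, n_injured = 30,
                                           n_failed = 10, seed = 14,
                                           image_size = c(256, 256)))
  base <- compute_failure_rate(segment_labelled_cells(g$stack))
  # circular shift by (7, 11): cells sit away from borders, so counts hold
  shift <- function(m, dr, dc) {
    m[((seq_len(nrow(m)) - 1 - dr) %% nrow(m)) + 1,
      ((seq_len(ncol(m)) - 1 - dc) %% ncol(m)) + 1]
  }
  px <- g$stack$pixels
  for (ch in 1:2) px[1, ch, , ] <- shift(matrix(px[1, ch, , ], 256), 7, 11)
  shifted <- compute_failure_rate(
    segment_labelled_cells(time_lapse_stack(px, 1, c("green", "red"))))
  expect_equal(shifted$percent_failed, base$percent_failed)

  px2 <- array(0, c(1, 2, 256, 256))
  for (ch in 1:2) px2[1, ch, , ] <- rot90_mat(matrix(g$stack$pixels[1, ch, , ], 256))
  rotated <- compute_failure_rate(
    segment_labelled_cells(time_lapse_stack(px2, 1, c("green", "red"))))
  expect_equal(rotated$percent_failed, base$percent_failed)
})
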