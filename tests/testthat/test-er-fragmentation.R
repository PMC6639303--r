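# Injury-axis computation and ER fragmentation scoring.

er_threshold <- function(model) {
  calibrate_fragmentation_threshold(model, n_fields = 2, seed = 99)
}

test_that("injury axis matches elementary geometry", {
  # circle of radius r with the injury on the boundary: axis = diameter
  circ <- ellipse_spec(c(50, 50), c(20, 20))
  ax <- injury_axis(ellipse_polygon(circ, 128), injury_point = c(30, 50))
  expect_lt(abs(attr(ax, "length") - 40), 1)

  # injury at a square corner: axis to the opposite corner, length side*sqrt(2)
  sq <- rbind(c(0, 0), c(0, 10), c(10, 10), c(10, 0))
  ax2 <- injury_axis(sq, injury_point = c(0, 0))
  expect_lt(abs(attr(ax2, "length") - 10 * sqrt(2)), 1)
  expect_equal(attr(ax2, "end"), c(10, 10))

  # synthetic field: endpoint matches the generator's far point within 1 px
  g <- generate_er_stack(er_field_model(noise_sd = 0), n_frames = 1,
                         onset_frame = 1, seed = 2)
  ax3 <- injury_axis(g$roi)
  expect_lt(sqrt(sum((attr(ax3, "end") - attr(g$axis, "end"))^2)), 1)
  expect_lt(abs(attr(ax3, "length") - attr(g$axis, "length")), 1)

  expect_error(injury_axis(sq, injury_point = c(50, 50)), "outside")
})

test_that("pure fields score 0 and 1 and mixtures recover the truth", {
  mod <- er_field_model(noise_sd = 0)
  thr <- er_threshold(mod)
  rec <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(f) {
    m <- er_field_model(fragmentation_fraction = f, noise_sd = 0)
    g <- generate_er_stack(m, n_frames = 1, onset_frame = 1,
                           seed = 31 + round(100 * f))
    score_fragmentation(g$stack, g$axis, 1, threshold = thr,
                        cell_mask = g$mask)$fragmented_fraction
  }, numeric(1))
  expect_equal(rec[1], 0)
  expect_equal(rec[5], 1)
  expect_true(all(abs(rec - c(0, 0.25, 0.5, 0.75, 1)) <= 0.05))
  # monotone in the ground truth
  expect_true(all(diff(rec) >= -0.05))
})

test_that("the score is invariant to global intensity scaling", {
  mod <- er_field_model(fragmentation_fraction = 0.5, noise_sd = 0)
  thr <- er_threshold(er_field_model(noise_sd = 0))
  g <- generate_er_stack(mod, n_frames = 1, onset_frame = 1, seed = 8)
  r1 <- score_fragmentation(g$stack, g$axis, 1, threshold = thr,
                            cell_mask = g$mask)
  px <- g$stack$pixels * 3
  st3 <- time_lapse_stack(px, 2, c("er", "cyto"))
  r3 <- score_fragmentation(st3, g$axis, 1, threshold = thr,
                            cell_mask = g$mask)
  expect_equal(r3$fragmented_fraction, r1$fragmented_fraction,
               tolerance = 1e-9)
})

test_that("rotating the field by 90 degrees leaves the fraction unchanged", {
  mod <- er_field_model(fragmentation_fraction = 0.5, noise_sd = 0)
  thr <- er_threshold(er_field_model(noise_sd = 0))
  g <- generate_er_stack(mod, n_frames = 1, onset_frame = 1, seed = 9)
  r1 <- score_fragmentation(g$stack, g$axis, 1, threshold = thr,
                            cell_mask = g$mask)
  n_rows <- dim(g$stack$pixels)[3]
  er_rot <- rot90_mat(matrix(g$stack$pixels[1, 1, , ], n_rows))
  px <- array(0, c(1, 1, dim(er_rot)))
  px[1, 1, , ] <- er_rot
  st <- time_lapse_stack(px, 2, "er")
  ax <- rasterize_segment(rot90_pt(attr(g$axis, "start"), n_rows),
                          rot90_pt(attr(g$axis, "end"), n_rows))
  attr(ax, "length") <- attr(g$axis, "length")
  attr(ax, "start") <- rot90_pt(attr(g$axis, "start"), n_rows)
  attr(ax, "end") <- rot90_pt(attr(g$axis, "end"), n_rows)
  r2 <- score_fragmentation(st, ax, 1, er_channel = "er", threshold = thr,
                            cell_mask = rot90_mat(g$mask))
  expect_lt(abs(r2$fragmented_fraction - r1$fragmented_fraction), 0.05)
})

test_that("the time course turns on at the onset frame and has no memory", {
  mod <- er_field_model(fragmentation_fraction = 0.6, noise_sd = 0)
  thr <- er_threshold(er_field_model(noise_sd = 0))
  g <- generate_er_stack(mod, n_frames = 4, onset_frame = 3, seed = 10)
  tc <- fragmentation_timecourse(g$stack, g$axis, threshold = thr,
                                 cell_mask = g$mask)
  fr <- vapply(tc, function(x) x$fragmented_fraction, numeric(1))
  expect_true(all(fr[1:2] == 0))
  expect_true(all(abs(fr[3:4] - 0.6) <= 0.05))

  # constant tubular stack: all-zero series
  g0 <- generate_er_stack(er_field_model(fragmentation_fraction = 0,
                                         noise_sd = 0),
                          n_frames = 3, onset_frame = 1, seed = 11)
  tc0 <- fragmentation_timecourse(g0$stack, g0$axis, threshold = thr,
                                  cell_mask = g0$mask)
  expect_true(all(vapply(tc0, function(x) x$fragmented_fraction,
                         numeric(1)) == 0))

  # frames are scored independently: a reversed frame order reverses the
  # series
  rev_tc <- fragmentation_timecourse(g$stack, g$axis, frames = 4:1,
                                     threshold = thr, cell_mask = g$mask)
  expect_equal(rev(vapply(rev_tc, function(x) x$fragmented_fraction,
                          numeric(1))), fr)
})
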