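# Ground-truth generators: analytic correctness, determinism, parameter
# validation.

test_that("influx stack with no dynamics and no noise is a constant movie", {
  m <- quiet_influx(influx_rate = 0, n_frames = 20, injury_frame = 5)
  g <- generate_influx_stack(m, seed = 1)
  base <- g$stack$pixels[1, 1, , ]
  for (t in 2:20) expect_identical(g$stack$pixels[t, 1, , ], base)
  expect_true(all(g$truth$values == m$baseline_intensity))
})

test_that("noise-free repairing stack plateaus after repair_time in-mask", {
  m <- quiet_influx(repair_time = 30, frame_interval = 2, n_frames = 40,
                    injury_frame = 10)
  g <- generate_influx_stack(m, seed = 2)
  # in-mask means measured directly from the generated pixels
  means <- vapply(seq_len(40), function(t) {
    fr <- matrix(g$stack$pixels[t, 1, , ], 64, 64)
    mean(fr[g$mask])
  }, numeric(1))
  plateau_frames <- (m$injury_frame + 15):40   # t >= 30 s post-injury
  expect_equal(diff(range(means[plateau_frames])), 0)
  # and the rise is linear at influx_rate before that
  rising <- means[m$injury_frame:(m$injury_frame + 15)]
  expect_equal(unique(round(diff(rising), 10)),
               m$influx_rate * m$frame_interval)
})

test_that("all generators are bit-deterministic for identical spec + seed", {
  g1 <- generate_influx_stack(influx_model(), seed = 9)
  g2 <- generate_influx_stack(influx_model(), seed = 9)
  expect_identical(g1$stack$pixels, g2$stack$pixels)

  e1 <- generate_er_stack(er_field_model(), seed = 9)
  e2 <- generate_er_stack(er_field_model(), seed = 9)
  expect_identical(e1$stack$pixels, e2$stack$pixels)
  expect_identical(e1$label_mask, e2$label_mask)

  b1 <- generate_bead_field(bead_field_spec(n_cells = 30, n_injured = 20,
                                            n_failed = 5, seed = 9))
  b2 <- generate_bead_field(bead_field_spec(n_cells = 30, n_injured = 20,
                                            n_failed = 5, seed = 9))
  expect_identical(b1$stack$pixels, b2$stack$pixels)
  expect_identical(b1$truth, b2$truth)

  f1 <- generate_frap_trace(0.6, 12, seed = 9)
  f2 <- generate_frap_trace(0.6, 12, seed = 9)
  expect_identical(f1$values, f2$values)

  t1 <- generate_transient_trace(transient_model(), seed = 9)
  t2 <- generate_transient_trace(transient_model(), seed = 9)
  expect_identical(t1$values, t2$values)
})

test_that("influx model rejects degenerate parameters", {
  expect_error(influx_model(frame_interval = 0), "frame_interval")
  expect_error(influx_model(influx_rate = -1), "influx_rate")
  expect_error(influx_model(repair_time = 0), "repair_time")
  expect_error(influx_model(n_frames = 5, injury_frame = 5), "n_frames")
  expect_error(ellipse_spec(c(10, 10), c(0, 5)), "degenerate")
})

test_that("transient trace follows the analytic model", {
  # zero amplitude: flat at baseline
  m0 <- transient_model(peak_amplitude = 0, noise_sd = 0)
  tr0 <- generate_transient_trace(m0, n_frames = 600)
  expect_true(all(tr0$values == m0$baseline))

  # rise_tau -> 0 limit: step then pure exponential decay
  m <- transient_model(baseline = 100, peak_amplitude = 50,
                       rise_tau = 1e-9, decay_tau = 20, injury_time = 10,
                       noise_sd = 0)
  tr <- generate_transient_trace(m, frame_interval = 0.2, n_frames = 960)
  post <- tr$times > 0
  expect_equal(tr$values[post],
               100 + 50 * exp(-tr$times[post] / 20), tolerance = 1e-9)
  expect_true(all(tr$values[tr$times < 0] == 100))
})

test_that("25%-of-peak crossing matches a bisection root of the closed form", {
  rise <- 2; decay <- 20
  m <- transient_model(baseline = 100, peak_amplitude = 50, rise_tau = rise,
                       decay_tau = decay, injury_time = 10, noise_sd = 0)
  tr <- generate_transient_trace(m, frame_interval = 0.2, n_frames = 960)

  # independent closed form, unit peak
  tp <- log(decay / rise) * rise * decay / (decay - rise)
  g <- function(t) (exp(-t / decay) - exp(-t / rise)) /
    (exp(-tp / decay) - exp(-tp / rise))
  # bisection for g(t) = 0.25 after the peak
  lo <- tp; hi <- 200
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0.25) lo <- mid else hi <- mid
  }
  t_oracle <- (lo + hi) / 2

  # crossing of the generated samples (linear interpolation), relative to
  # transient onset
  thr <- 100 + 0.25 * 50
  post <- which(tr$times >= 0)
  v <- tr$values[post]; tt <- tr$times[post]
  i <- which(v <= thr & tt > tp)[1]
  t_cross <- tt[i - 1] + (thr - v[i - 1]) / (v[i] - v[i - 1]) *
    (tt[i] - tt[i - 1])
  expect_lt(abs(t_cross - t_oracle), 0.2)   # within one frame interval
})

test_that("ER generator ground truth labels obey the fragmentation fraction", {
  # f = 0: no punctate labels, pre- and post-onset frames identical texture
  g0 <- generate_er_stack(er_field_model(fragmentation_fraction = 0,
                                         noise_sd = 0),
                          n_frames = 2, onset_frame = 2, seed = 3)
  expect_false(any(g0$label_mask))
  expect_identical(g0$stack$pixels[1, 1, , ], g0$stack$pixels[2, 1, , ])

  # f = 1: labels cover the whole cell
  g1 <- generate_er_stack(er_field_model(fragmentation_fraction = 1,
                                         noise_sd = 0),
                          n_frames = 1, onset_frame = 1, seed = 3)
  expect_identical(g1$label_mask, g1$mask)

  # f = 0.5: labelled pixels along the axis span half its length +/- 1 px
  gh <- generate_er_stack(er_field_model(fragmentation_fraction = 0.5,
                                         noise_sd = 0),
                          n_frames = 1, onset_frame = 1, seed = 3)
  ax <- gh$axis
  on_axis <- gh$label_mask[cbind(ax[, 1], ax[, 2])]
  run <- rle(on_axis)
  labelled_px <- if (run$values[1]) run$lengths[1] else 0
  expect_lt(abs(labelled_px - 0.5 * attr(ax, "length")), 1.5)
})

test_that("ER generator rejects indistinguishable texture scales", {
  expect_error(er_field_model(tubule_spacing = 2, puncta_radius = 1.5),
               "indistinguishable")
})

test_that("bead fields honour their spec exactly", {
  # no injured cells: both channels flat at background
  b0 <- generate_bead_field(bead_field_spec(n_cells = 10, n_injured = 0,
                                            image_size = c(128, 128),
                                            seed = 5))
  expect_true(all(b0$stack$pixels == 10))
  expect_equal(sum(b0$truth$injured), 0)

  # ground-truth failure percentage is pure arithmetic on the spec
  b <- generate_bead_field(bead_field_spec(n_cells = 150, n_injured = 150,
                                           n_failed = 30, seed = 5))
  expect_equal(100 * sum(b$truth$failed) / sum(b$truth$injured), 20)

  # cells do not overlap
  d <- as.matrix(stats::dist(b$truth[, c("row", "col")]))
  diag(d) <- Inf
  rsum <- outer(b$truth$radius, b$truth$radius, "+")
  expect_true(all(d > rsum))

  expect_error(bead_field_spec(n_cells = 10, n_injured = 5, n_failed = 6),
               "n_failed")
  expect_error(
    generate_bead_field(bead_field_spec(n_cells = 400, image_size = c(64, 64),
                                        seed = 1)),
    "non-overlapping")
})

test_that("FRAP traces follow the closed-form recovery", {
  # immobile: flat at the bleached level
  f0 <- generate_frap_trace(0, 15, bleach_depth = 0.8, noise_sd = 0)
  post <- f0$times >= 0
  expect_equal(f0$values[post], rep(1000 * 0.2, sum(post)))

  # fully mobile at t = tau * ln 2: recovered half the bleached depth
  f1 <- generate_frap_trace(1, recovery_tau = 15, bleach_depth = 0.8,
                            frame_interval = 15 * log(2), n_frames = 30,
                            noise_sd = 0)
  i <- which(f1$times == 15 * log(2))
  expect_equal(f1$values[i], 1000 * (0.2 + 0.8 / 2))

  # every frame matches the closed form
  fm <- generate_frap_trace(0.7, 15, bleach_depth = 0.8, noise_sd = 0)
  tpost <- fm$times[fm$times >= 0]
  expect_equal(fm$values[fm$times >= 0],
               1000 * (0.2 + 0.7 * 0.8 * (1 - exp(-tpost / 15))),
               tolerance = 1e-12)
  expect_error(generate_frap_trace(1.2, 15), "mobile_fraction")
})
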