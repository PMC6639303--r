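# TIFF and ROI-JSON round trips and validation.

test_that("a single-page grayscale TIFF loads as a 1-frame 1-channel stack", {
  path <- withr::local_tempfile(fileext = ".tif")
  img <- matrix(sample(0:65535, 32 * 24, TRUE), 32, 24)
  tiff::writeTIFF(img / 65535, path, bits.per.sample = 16L)
  st <- read_stack(path, frame_interval = 1)
  expect_equal(dim(st$pixels), c(1, 1, 32, 24))
  expect_identical(as.numeric(st$pixels[1, 1, , ]), as.numeric(img))
})

test_that("write/read round trip is pixel-identical for generator stacks", {
  path <- withr::local_tempfile(fileext = ".tif")
  g <- generate_influx_stack(influx_model(n_frames = 15), seed = 3)
  write_stack(g$stack, path)
  back <- read_stack(path, frame_interval = 2, channel_names = "fm_dye",
                     injury_frame = 10)
  expect_equal(back$pixels, g$stack$pixels)
  expect_identical(back$channel_names, "fm_dye")
})

test_that("two-channel ER stacks round trip with channels preserved", {
  path <- withr::local_tempfile(fileext = ".tif")
  g <- generate_er_stack(er_field_model(), n_frames = 4, onset_frame = 2,
                         seed = 4)
  write_stack(g$stack, path)
  back <- read_stack(path, frame_interval = 2,
                     channel_names = c("er", "cyto"), injury_frame = 2)
  expect_equal(dim(back$pixels), c(4, 2, 112, 112))
  expect_equal(back$pixels, g$stack$pixels)
  expect_identical(back$channel_names, c("er", "cyto"))
  # channel count is mandatory for multi-channel files: a wrong count that
  # does not divide the page count is an error
  expect_error(read_stack(path, 2, channel_names = c("a", "b", "c")),
               "page count")
})

test_that("ROI JSON round trip is lossless and validated", {
  path <- withr::local_tempfile(fileext = ".json")
  cell <- ellipse_polygon(ellipse_spec(c(30, 30), c(20, 12), 0.7), 48)
  roi <- roi_set(cell_polygon = cell,
                 injury_point = ellipse_point(ellipse_spec(c(30, 30),
                                                           c(20, 12), 0.7), 0),
                 background_polygon = rbind(c(2, 2), c(2, 6), c(6, 6), c(6, 2)),
                 bleach_region = rbind(c(28, 28), c(28, 32), c(32, 32),
                                       c(32, 28)))
  write_roiset(roi, path)
  back <- read_roiset(path)
  expect_equal(back$cell_polygon, roi$cell_polygon)
  expect_equal(back$injury_point, roi$injury_point)
  expect_equal(back$background_polygon, roi$background_polygon)
  expect_equal(back$bleach_region, roi$bleach_region)
})

test_that("invalid ROI sets are rejected with informative errors", {
  square <- rbind(c(0, 0), c(0, 10), c(10, 10), c(10, 0))
  # square cell with a corner injury point is fine
  expect_s3_class(roi_set(square, injury_point = c(0, 0)), "roi_set")
  # bow-tie polygon self-intersects; the error names the offending edges
  bowtie <- rbind(c(0, 0), c(10, 10), c(0, 10), c(10, 0))
  expect_error(roi_set(bowtie), "self-intersecting.*edges")
  # background overlapping the cell is rejected
  expect_error(roi_set(square, background_polygon = square + 5), "overlaps")
  # injury point outside the cell is rejected
  expect_error(roi_set(square, injury_point = c(50, 50)), "outside")
})

test_that("missing files and malformed stacks raise errors", {
  expect_error(read_stack(file.path(tempdir(), "nope.tif"), 1), "no such file")
  expect_error(read_roiset(file.path(tempdir(), "nope.json")), "no such file")
})

test_that("write_synthetic emits stack, ROI and truth sidecars", {
  dir <- withr::local_tempdir()
  g <- generate_influx_stack(influx_model(n_frames = 15), seed = 3)
  files <- write_synthetic(g, dir, "cell01")
  expect_true(all(file.exists(files)))
  truth <- jsonlite::read_json(files[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$trace$values, g$truth$values)
  expect_equal(truth$seed, 3)
})
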