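test_that("thermal CSV stacks round-trip with gap and dialect checks", {
  th <- generate_thermal_scene(n_frames = 5, noise_sd_c = 0.2, seed = 2)
  dir <- withr::local_tempdir()
  write_thermal_stack(th$stack, dir)
  back <- read_thermal_stack(dir)
  expect_equal(back$fps, 9)
  expect_equal(back$frames, th$stack$frames, tolerance = 1e-12)
  file.remove(file.path(dir, "frame_000002.csv"))
  expect_error(read_thermal_stack(dir), "missing thermal frame")
})

test_that("ragged matrices and decimal commas are rejected with pointers", {
  dir <- withr::local_tempdir()
  writeLines(c("20.1,20.2", "20.3"), file.path(dir, "frame_000000.csv"))
  expect_error(read_thermal_stack(dir), "ragged")
  dir2 <- withr::local_tempdir()
  writeLines(c("20,1;20,2", "20,3;20,4"), file.path(dir2, "frame_000000.csv"))
  expect_error(read_thermal_stack(dir2), "decimal")
})

test_that("ROI statistics match the planted hotspot arithmetic", {
  tr <- seq(35, 40, length.out = 540)
  th <- generate_thermal_scene(n_frames = 540, hotspot_peak_c = tr, noise_sd_c = 0)
  stats <- roi_temperature_stats(th$stack, tracked_roi(th$truth$roi, "label-file"))
  expect_equal(stats$aggregate$mean_of_max, 37.5)
  expect_equal(stats$aggregate$max_of_max, 40)
  expect_equal(nrow(stats$per_frame), 540)
  # constant hotspot: per-frame max exact, zero dispersion of maxima
  th2 <- generate_thermal_scene(n_frames = 12, hotspot_peak_c = 38.5, noise_sd_c = 0)
  s2 <- roi_temperature_stats(th2$stack, tracked_roi(th2$truth$roi, "label-file"))
  expect_equal(s2$per_frame$max_c, rep(38.5, 12))
  expect_equal(s2$aggregate$sd_of_max, 0)
  expect_equal(s2$aggregate$mode_of_max, 38.5)
})

test_that("a single-pixel ROI collapses max, mode and SD", {
  st <- frame_stack(list(matrix(c(36.24, 37, 38, 39), 2, 2)), fps = 9)
  roi <- tracked_roi(tibble::tibble(frame = 0, x = 0, y = 0, w = 1, h = 1), "label-file")
  s <- roi_temperature_stats(st, roi)
  expect_equal(s$per_frame$max_c, 36.24)
  expect_equal(s$per_frame$mode_c, 36.2) # centre of its 0.1-degree bin
  expect_equal(s$per_frame$sd_c, 0)
})

test_that("enlarging the ROI never decreases the per-frame maximum", {
  th <- generate_thermal_scene(n_frames = 6, noise_sd_c = 0.3, seed = 5)
  small <- tracked_roi(tibble::tibble(frame = 0:5, x = 18, y = 12, w = 10, h = 8), "label-file")
  big <- tracked_roi(tibble::tibble(frame = 0:5, x = 10, y = 6, w = 30, h = 24), "label-file")
  s_small <- roi_temperature_stats(th$stack, small)
  s_big <- roi_temperature_stats(th$stack, big)
  expect_true(all(s_big$per_frame$max_c >= s_small$per_frame$max_c))
})

test_that("a cold bar across part of the ROI leaves the maximum unchanged", {
  th <- generate_thermal_scene(n_frames = 4, hotspot_peak_c = 38.5, noise_sd_c = 0)
  occluded <- lapply(th$stack$frames, function(f) { f[, 17:22] <- 15; f })
  # bar covers 6 of 24 ROI columns but misses the hotspot centre
  s0 <- roi_temperature_stats(th$stack, tracked_roi(th$truth$roi[1:4, ], "label-file"))
  s1 <- roi_temperature_stats(frame_stack(occluded, fps = 9),
                              tracked_roi(th$truth$roi[1:4, ], "label-file"))
  expect_equal(s1$per_frame$max_c, s0$per_frame$max_c)
})

test_that("invalid tracked frames are excluded from aggregates", {
  tr <- c(36, 36, 44, 36)
  th <- generate_thermal_scene(n_frames = 4, hotspot_peak_c = tr, noise_sd_c = 0)
  boxes <- th$truth$roi; boxes$valid <- c(TRUE, TRUE, FALSE, TRUE)
  s <- roi_temperature_stats(th$stack, tracked_roi(boxes, "label-file"))
  expect_equal(s$aggregate$n_valid, 3L)
  expect_equal(s$aggregate$max_of_max, 36)
})
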