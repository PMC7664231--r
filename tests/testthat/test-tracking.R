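test_that("corner detection localizes a high-contrast square", {
  fr <- array(60, c(48, 48, 3))
  fr[20:29, 20:29, ] <- 220 # square with corners at (19,19) .. (29,29), 0-based
  feats <- detect_corner_features(fr, c(10, 10, 30, 30))
  expect_gte(nrow(feats), 4)
  corners <- rbind(c(19, 19), c(19, 28.5), c(28.5, 19), c(28.5, 28.5))
  top4 <- as.matrix(feats[1:4, c("x", "y")])
  for (i in 1:4) {
    d <- sqrt(min(rowSums(sweep(corners, 2, top4[i, ])^2)))
    expect_lt(d, 2.5)
  }
})

test_that("textureless regions raise a no-features error; points stay in frame", {
  fr <- array(128, c(40, 40, 3))
  expect_error(detect_corner_features(fr, c(5, 5, 20, 20)), "no trackable features")
  sc <- generate_rgb_scene(small_scene(n_frames = 2, noise_sd = 0))
  f1 <- sc$stack$frames[[1]]
  feats <- detect_corner_features(f1, c(0, 0, 32, 32))
  expect_true(all(feats$x >= 0 & feats$x < 32))
  expect_true(all(feats$y >= 0 & feats$y < 32))
  expect_error(detect_corner_features(f1, c(30, 30, 10, 10)), "outside")
})

test_that("a static scene tracks to an identical box on every frame", {
  sc <- generate_rgb_scene(small_scene(n_frames = 20, noise_sd = 0))
  tr <- track_roi(sc$stack, c(8, 8, 16, 16))
  expect_true(all(tr$valid))
  expect_true(all(abs(tr$x - 8) < 0.2))
  expect_true(all(abs(tr$y - 8) < 0.2))
})

test_that("pure translation is recovered within a pixel", {
  sp <- scene_spec(width = 120, height = 48, n_frames = 60, fps = 30,
                   roi = c(10, 12, 24, 24), motion = c(1, 0),
                   amp_hr = 0, amp_rr = 0, noise_sd = 1, seed = 13)
  sc <- generate_rgb_scene(sp)
  tr <- track_roi(sc$stack, c(10, 12, 24, 24))
  err <- sqrt((tr$x - sc$truth$roi$x)^2 + (tr$y - sc$truth$roi$y)^2)
  expect_lt(max(err), 1)
})

test_that("tracking errors are explicit for bad seeds and empty stacks", {
  sc <- generate_rgb_scene(small_scene(n_frames = 3))
  expect_error(track_roi(sc$stack, c(40, 2, 16, 16)), "outside")
})

test_that("label files round-trip losslessly, including validity flags", {
  tr <- tracked_roi(tibble::tibble(frame = 0:9, x = 1:10, y = 2, w = 8, h = 6,
                                   valid = rep(c(TRUE, FALSE), 5)), "manual-seed")
  path <- withr::local_tempfile(fileext = ".csv")
  write_label_file(tr, path)
  back <- read_label_file(path)
  cols <- c("frame", "x", "y", "w", "h", "valid")
  expect_equal(as.data.frame(back)[cols], as.data.frame(tr)[cols])
  expect_identical(attr(back, "source"), "label-file")
})

test_that("label files with gaps or 1-based indices are handled", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame,x,y,w,h", "0,1,1,4,4", "1,1,1,4,4", "3,1,1,4,4"), path)
  expect_error(read_label_file(path), "2")
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# index_base: 1", "frame,x,y,w,h", "1,5,6,4,4", "2,5,6,4,4"), path2)
  tr <- read_label_file(path2)
  expect_equal(tr$frame, c(0L, 1L))
  expect_equal(tr$x, c(5, 5))
})

test_that("static crops are pixel-identical sub-arrays", {
  sc <- generate_rgb_scene(small_scene(n_frames = 6, noise_sd = 1, seed = 4))
  tr <- tracked_roi(sc$truth$roi, "label-file")
  crop <- crop_stack(sc$stack, tr)
  expect_identical(crop$frames[[3]], sc$stack$frames[[3]][9:24, 9:24, , drop = FALSE])
})

test_that("moving crops register the planted ROI content", {
  sp <- scene_spec(width = 100, height = 40, n_frames = 40, fps = 30,
                   roi = c(6, 8, 20, 20), motion = c(1, 0),
                   amp_hr = 0, amp_rr = 0, noise_sd = 0, seed = 6)
  sc <- generate_rgb_scene(sp)
  crop <- crop_stack(sc$stack, truth_track(sc))
  # content is static in crop coordinates: all cropped frames identical
  for (f in c(10, 25, 40)) expect_identical(crop$frames[[f]], crop$frames[[1]])
})

test_that("crops from a label file equal crops from the same boxes in memory", {
  sc <- generate_rgb_scene(small_scene(n_frames = 5, noise_sd = 1, seed = 8))
  tr <- truth_track(sc)
  path <- withr::local_tempfile(fileext = ".csv")
  write_label_file(tr, path)
  c1 <- crop_stack(sc$stack, tr)
  c2 <- crop_stack(sc$stack, read_label_file(path))
  expect_identical(c1$frames, c2$frames)
})
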