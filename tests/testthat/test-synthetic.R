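test_that("a silent noise-free static scene has identical frames", {
  sp <- small_scene(amp_hr = 0, amp_rr = 0, noise_sd = 0, n_frames = 30)
  sc <- generate_rgb_scene(sp)
  for (f in 2:30) expect_identical(sc$stack$frames[[f]], sc$stack$frames[[1]])
})

test_that("generation is bit-identical under identical spec and seed", {
  sp <- small_scene(noise_sd = 1.5, n_frames = 40)
  s1 <- generate_rgb_scene(sp)
  s2 <- generate_rgb_scene(sp)
  expect_identical(s1$stack$frames, s2$stack$frames)
  expect_identical(s1$truth, s2$truth)
})

test_that("the planted cardiac frequency dominates the green ROI mean", {
  sp <- small_scene(hr_hz = 1.5, amp_hr = 2, amp_rr = 0, noise_sd = 0, n_frames = 1800)
  sc <- generate_rgb_scene(sp)
  # independent oracle: direct ROI-mean series + raw periodogram argmax
  series <- vapply(sc$stack$frames, function(f) mean(f[9:24, 9:24, 2]), numeric(1))
  expect_true(abs(oracle_peak_hz(series, 30) - 1.5) < 30 / 1800 + 1e-9)
})

test_that("Nyquist violations are rejected naming the frequency", {
  expect_error(scene_spec(fps = 5, hr_hz = 2.6), "2.6 Hz")
  expect_error(scene_spec(fps = 30, roi = c(28, 28, 16, 16), width = 32, height = 32),
               "bounds")
})

test_that("occluder bars overwrite pixels and are book-kept per frame", {
  sp <- small_scene(n_frames = 10, occluders = list(c(10, 5)), noise_sd = 0)
  sc <- generate_rgb_scene(sp)
  # bar columns are constant at the occluder value
  expect_true(all(sc$stack$frames[[3]][, 11:15, ] == sp$occluder_value))
  # roi spans columns 8..24 zero-based; bar covers 10..14 => 5/16 of roi width
  expect_equal(sc$truth$occluded_frac, rep(5 / 16, 10))
})

test_that("sub-unit amplitudes survive quantization through noise dithering", {
  sp <- small_scene(amp_hr = 1, amp_rr = 0, noise_sd = 0.5, n_frames = 1800, seed = 21)
  sig <- scene_signals(sp)
  sp_g <- fft_spectrum(sig$g)
  peak <- dominant_frequency(sp_g, band_spec("HR"))
  off <- sp_g$magnitude[sp_g$frequency > 3.5]
  expect_true(abs(peak$f_peak - sp$hr_hz) < 0.02)
  expect_gt(peak$amplitude / median(off), 10)
})

test_that("thermal scenes expose the exact hotspot trajectory", {
  # constant peak, zero noise: per-frame ROI max is exact
  th <- generate_thermal_scene(n_frames = 8, hotspot_peak_c = 38.5, noise_sd_c = 0)
  mx <- vapply(th$stack$frames, function(f) max(f[11:30, 17:40]), numeric(1))
  expect_equal(mx, rep(38.5, 8))
  # linear 35 -> 40 trajectory: mean of maxima is the trajectory mean
  tr <- seq(35, 40, length.out = 540)
  th2 <- generate_thermal_scene(n_frames = 540, hotspot_peak_c = tr, noise_sd_c = 0)
  mx2 <- vapply(th2$stack$frames, max, numeric(1))
  expect_equal(mean(mx2), 37.5)
  expect_equal(max(mx2), 40)
  # background-only ROI: max bounded by the noise order statistic
  th3 <- generate_thermal_scene(n_frames = 40, background_c = 20, hotspot_sigma = 0,
                                hotspot_peak_c = 20, noise_sd_c = 0.05, seed = 3)
  mx3 <- vapply(th3$stack$frames, function(f) max(f[11:30, 17:40]), numeric(1))
  # extreme-value bound for ~2e4 Gaussian draws across the 40 frames
  expect_true(all(abs(mx3 - 20) < 5 * 0.05))
  expect_error(generate_thermal_scene(background_c = 39, hotspot_peak_c = 38),
               "exceed")
  expect_error(generate_thermal_scene(roi = c(100, 2, 10, 10)), "outside")
})

test_that("cohorts are balanced with labels in range and per-minute units", {
  coh <- generate_cohort(134, seed = 1)
  expect_equal(nrow(coh), 134)
  expect_true(max(table(coh$band)) - min(table(coh$band)) <= 1)
  expect_true(all(coh$rr_hz >= 0.2 & coh$rr_hz <= 3.2))
  expect_true(all(coh$hr_hz >= 1.05 & coh$hr_hz <= 2.2))
  expect_equal(coh$rr_brpm, 60 * coh$rr_hz)
  expect_equal(coh$hr_bpm, 60 * coh$hr_hz)
  # band labels agree with the half-open band convention
  lims <- list(low = c(0.2, 1.2), medium = c(1.2, 2.2), high = c(2.2, 3.2))
  for (b in names(lims)) {
    v <- coh$rr_hz[coh$band == b]
    expect_true(all(v > lims[[b]][1] - 1e-12 & v <= lims[[b]][2]))
  }
  expect_error(generate_cohort(10, band_mix = c(0.5, 0.2, 0.2)), "sum to 1")
  expect_identical(generate_cohort(12, seed = 9)$rr_hz, generate_cohort(12, seed = 9)$rr_hz)
})

test_that("frame stacks round-trip through PNG directories", {
  sp <- small_scene(n_frames = 5, noise_sd = 1, seed = 11)
  sc <- generate_rgb_scene(sp)
  dir <- withr::local_tempdir()
  write_frame_stack(sc$stack, dir)
  back <- read_frame_stack(dir)
  expect_equal(back$fps, 30)
  expect_identical(back$frames, sc$stack$frames)
  file.remove(file.path(dir, "frame_000002.png"))
  expect_error(read_frame_stack(dir), "missing frame")
})
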