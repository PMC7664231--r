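test_that("canonical band definitions are exposed", {
  expect_equal(band_spec("HR")[c("lo", "hi")], list(lo = 0.83, hi = 3.00))
  expect_equal(band_spec("RR-wide")[c("lo", "hi")], list(lo = 0.33, hi = 3.10))
  expect_equal(band_spec("RR-low")[c("lo", "hi")], list(lo = 0.20, hi = 1.20))
  expect_equal(band_spec("RR-medium")[c("lo", "hi")], list(lo = 1.20, hi = 2.20))
  expect_equal(band_spec("RR-high")[c("lo", "hi")], list(lo = 2.20, hi = 3.20))
  expect_error(band_spec("custom", lo = 2, hi = 1), "lo < hi")
  expect_error(rr_band_for("weird"), "unknown")
})

test_that("band-pass preserves in-band amplitude and halves it at cutoff", {
  # centre of the cardiac band: |H|^2 ~ 1 after the bidirectional pass
  centre <- sqrt(0.83 * 3.0) # geometric centre of a band-pass
  x <- sine_signal(centre, n = 1800)
  y <- butterworth_bandpass(x, band_spec("HR"))
  mid <- 300:1500
  gain <- sqrt(mean(y$value[mid]^2) / mean(x$value[mid]^2))
  expect_true(abs(gain - 1) < 0.02)
  # at the cutoff: -3 dB per pass, -6 dB total => amplitude ratio 0.5
  xc <- sine_signal(0.83, n = 1800)
  yc <- butterworth_bandpass(xc, band_spec("HR"))
  gc <- sqrt(mean(yc$value[mid]^2) / mean(xc$value[mid]^2))
  expect_true(abs(gc - 0.5) < 0.025)
  # zero in, zero out
  z <- channel_signal(rep(0, 256), 30)
  expect_equal(butterworth_bandpass(z, band_spec("HR"))$value, rep(0, 256))
})

test_that("band at or above Nyquist is rejected naming the rate", {
  x <- sine_signal(1, fs = 6, n = 128)
  expect_error(butterworth_bandpass(x, band_spec("RR-high")), "fs = 6")
})

test_that("zero-phase: no lag between input and filtered sinusoid", {
  x <- sine_signal(1.5, n = 900)
  y <- butterworth_bandpass(x, band_spec("HR"))
  cc <- stats::ccf(y$value[100:800], x$value[100:800], lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("spectrum of a unit sinusoid at a bin centre peaks at magnitude 1", {
  fs <- 32; n <- 512
  nfft <- 2^ceiling(log2(4 * n))
  f0 <- 64 * fs / nfft # exact zero-padded-grid bin
  x <- channel_signal(sin(2 * pi * f0 * (0:(n - 1)) / fs), fs)
  sp <- fft_spectrum(x)
  expect_true(abs(max(sp$magnitude) - 1) < 0.01)
  expect_equal(sp$frequency[which.max(sp$magnitude)], f0)
  # DC-free: detrended input leaves nothing above bin 1
  d <- channel_signal(detrend_linear(rep(5, 64)), fs)
  expect_true(all(fft_spectrum(d)$magnitude < 1e-9))
})

test_that("two-tone spectrum keeps the 2:1 magnitude ratio", {
  fs <- 30; n <- 1800; t <- (0:(n - 1)) / fs
  x <- channel_signal(2 * sin(2 * pi * 0.9 * t) + sin(2 * pi * 2.5 * t), fs)
  sp <- fft_spectrum(x)
  p1 <- dominant_frequency(sp, band_spec("custom", lo = 0.7, hi = 1.1))
  p2 <- dominant_frequency(sp, band_spec("custom", lo = 2.3, hi = 2.7))
  expect_true(abs(p1$f_peak - 0.9) < 0.01)
  expect_true(abs(p2$f_peak - 2.5) < 0.01)
  expect_true(abs(p1$amplitude / p2$amplitude - 2) < 0.1)
})

test_that("dominant frequency pins and flags out-of-band peaks", {
  # truth above the band: the estimate never leaves the band
  x <- sine_signal(3.5, n = 1800)
  est <- dominant_frequency(fft_spectrum(x), band_spec("RR-high"))
  expect_true(est$f_peak <= 3.2)
  # a spectrum rising monotonically into the upper boundary pins and flags
  sp <- tibble::tibble(frequency = seq(0, 15, by = 0.1),
                       magnitude = seq(0, 15, by = 0.1))
  est_edge <- dominant_frequency(sp, band_spec("RR-high"))
  expect_equal(est_edge$f_peak, 3.2)
  expect_true(est_edge$edge_peak)
  # in-band peak is refined below the raw grid resolution
  y <- sine_signal(1.5, n = 1800)
  est2 <- dominant_frequency(fft_spectrum(y), band_spec("HR"))
  expect_true(abs(est2$f_peak - 1.5) < 0.01)
  expect_false(est2$edge_peak)
  # a band falling between the grid points of a coarse spectrum errors
  coarse <- fft_spectrum(channel_signal(rnorm(8), 30))
  expect_error(dominant_frequency(coarse, band_spec("custom", lo = 1.0, hi = 1.5)),
               "overlap")
})

test_that("white-noise spectra yield in-band peaks without failures", {
  set.seed(8)
  peaks <- replicate(20, {
    x <- channel_signal(rnorm(512), 30)
    dominant_frequency(fft_spectrum(x), band_spec("RR-wide"))$f_peak
  })
  expect_true(all(peaks >= 0.33 & peaks <= 3.1))
  expect_true(sd(peaks) > 0.3) # spread over the band, not stuck at one bin
})

test_that("rates convert to per-minute units", {
  expect_equal(to_bpm(1.5), 90)
  expect_equal(to_bpm(0.45), 27)
  expect_equal(to_bpm(4.0), 240)
  est <- dominant_frequency(fft_spectrum(sine_signal(1.5, n = 512)), band_spec("HR"))
  expect_equal(to_bpm(est), 60 * est$f_peak)
})

test_that("bidirectional filter equals the |H|^2 frequency-domain oracle", {
  # transients decay as max|pole|^k from each edge, so the comparison uses a
  # wide fast-decaying band and the middle 16 of 64 samples
  fs <- 30; n <- 64
  band <- band_spec("custom", lo = 0.25 * fs / 2, hi = 0.75 * fs / 2)
  co <- signal::butter(2, c(band$lo, band$hi) / (fs / 2), type = "pass")
  hmag2 <- function(fr) { # digital transfer function magnitude squared
    e <- exp(-1i * 2 * pi * fr / fs * (0:(length(co$b) - 1)))
    Mod(sum(co$b * e) / sum(co$a * e))^2
  }
  h2 <- vapply((0:(n - 1)) * fs / n, hmag2, numeric(1))
  worst <- 0
  for (s in 1:10) {
    set.seed(s)
    t <- 0:(n - 1)
    x <- rowSums(sapply(1:3, function(k) rnorm(1) * sin(2 * pi * k * t / n + runif(1, 0, 2 * pi))))
    x <- x / sqrt(mean(x^2))
    oracle <- Re(stats::fft(stats::fft(x) * h2, inverse = TRUE)) / n
    y <- butterworth_bandpass(x, band, fs = fs)
    idx <- 25:40
    worst <- max(worst, sqrt(mean((y[idx] - oracle[idx])^2)))
  }
  expect_lt(worst, 1e-6)
})
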