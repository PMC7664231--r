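# shared fixtures, all generated in code

# a bare sinusoid wrapped as a channel signal (detrended like extract_series output)
sine_signal <- function(f_hz, fs = 30, n = 1800, amp = 1, phase = 0, channel = "G") {
  t <- (seq_len(n) - 1) / fs
  channel_signal(amp * sin(2 * pi * f_hz * t + phase) |> (\(x) x - mean(x))(),
                 fs = fs, channel = channel)
}

# small fast scene spec used across tests; ... overrides any default
small_scene <- function(...) {
  args <- list(width = 32, height = 32, n_frames = 600, fps = 30,
               roi = c(8, 8, 16, 16), hr_hz = 1.5, rr_hz = 0.8,
               amp_hr = 2, amp_rr = 2, noise_sd = 0, seed = 7)
  over <- list(...)
  args[names(over)] <- over
  do.call(scene_spec, args)
}

# independent spectral oracle: raw periodogram argmax of a numeric series,
# deliberately avoiding the package's windowed/interpolated estimator
oracle_peak_hz <- function(x, fs) {
  x <- x - mean(x)
  n <- length(x)
  p <- Mod(stats::fft(x))[1:(n %/% 2 + 1)]
  p[1] <- 0
  (which.max(p) - 1) * fs / n
}
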