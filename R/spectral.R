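#' Physiological frequency bands
#'
#' Named band-pass specifications used by the raw video analysis: the cardiac
#' band (`"HR"`, 0.83-3.00 Hz), the single wide respiratory band used for the
#' first-pass analysis feeding the band classifier (`"RR-wide"`, 0.33-3.1 Hz),
#' and the three class-specific respiratory bands used for re-analysis
#' (`"RR-low"` 0.2-1.2, `"RR-medium"` 1.2-2.2, `"RR-high"` 2.2-3.2 Hz).
#' Custom bands can be built by passing `lo` and `hi` directly.
#'
#' @param name one of `"HR"`, `"RR-wide"`, `"RR-low"`, `"RR-medium"`,
#'   `"RR-high"`, or `"custom"`.
#' @param lo,hi cutoff frequencies in Hz (required for `"custom"`).
#' @return a `band_spec` list with `lo`, `hi`, `name`.
#' @export
band_spec <- function(name = c("HR", "RR-wide", "RR-low", "RR-medium", "RR-high", "custom"),
                      lo = NULL, hi = NULL) {
  name <- match.arg(name)
  canon <- list(
    "HR"        = c(0.83, 3.00),
    "RR-wide"   = c(0.33, 3.10),
    "RR-low"    = c(0.20, 1.20),
    "RR-medium" = c(1.20, 2.20),
    "RR-high"   = c(2.20, 3.20)
  )
  if (name != "custom") {
    lo <- canon[[name]][1]; hi <- canon[[name]][2]
  }
  stopifnot(is_number(lo), is_number(hi))
  if (!(lo > 0 && lo < hi)) abort("band must satisfy 0 < lo < hi")
  structure(list(lo = lo, hi = hi, name = name), class = "band_spec")
}

#' Map a respiration class label to its re-analysis band
#'
#' @param label `"low"`, `"medium"` or `"high"`.
#' @return a [band_spec()].
#' @export
rr_band_for <- function(label) {
  band_spec(switch(as.character(label),
                   low = "RR-low", medium = "RR-medium", high = "RR-high",
                   abort(sprintf("unknown respiration class '%s'", label))))
}

# steady-state initial conditions of the direct-form-II-transposed filter for
# a unit-step input (removes startup transients in the zero-phase pass)
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b))); a <- c(a, rep(0, n - length(a)))
  b <- b / a[1]; a <- a / a[1]
  A <- matrix(0, n - 1, n - 1)
  A[, 1] <- -a[-1]
  if (n > 2) A[1:(n - 2), 2:(n - 1)] <- diag(n - 2)
  B <- b[-1] - a[-1] * b[1]
  solve(diag(n - 1) - A, B)
}

# direct-form-II-transposed IIR filter with initial state
iir_filter <- function(b, a, x, zi) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b))) / a[1]
  a <- c(a, rep(0, n - length(a))) / a[1]
  z <- zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    for (k in 1:(n - 2)) z[k] <- b[k + 1] * xi + z[k + 1] - a[k + 1] * yi
    z[n - 1] <- b[n] * xi - a[n] * yi
    y[i] <- yi
  }
  y
}

butter_coefs <- function(band, fs) {
  ny <- fs / 2
  if (band$hi >= ny) {
    abort(sprintf("band [%g, %g] Hz reaches the Nyquist frequency of fs = %g Hz",
                  band$lo, band$hi, fs))
  }
  bt <- signal::butter(2, c(band$lo, band$hi) / ny, type = "pass")
  list(b = bt$b, a = bt$a)
}

#' Zero-phase second-order Butterworth band-pass
#'
#' An order-2 Butterworth prototype is mapped to a band-pass (4 poles in
#' total) by the bilinear transform with frequency pre-warping, and applied
#' forward then backward for zero phase. Edges are handled by odd reflection
#' padding (3 x (filter length - 1) samples) plus steady-state initial
#' conditions, so a single pass attenuates a cutoff-frequency sinusoid by
#' 3 dB and the bidirectional pass by 6 dB.
#'
#' @param sig a [channel_signal()] (or numeric vector with `fs` given).
#' @param band a [band_spec()]; must lie below Nyquist.
#' @param fs sampling rate, only needed when `sig` is a bare numeric vector.
#' @param padlen reflection padding length (default `3 * (ntaps - 1)`).
#' @return filtered signal of the same type and length as the input.
#' @export
butterworth_bandpass <- function(sig, band, fs = NULL, padlen = NULL) {
  is_cs <- inherits(sig, "channel_signal")
  x <- if (is_cs) sig$value else sig
  fs <- if (is_cs) signal_fs(sig) else fs
  if (is.null(fs)) abort("fs is required when filtering a bare numeric vector")
  co <- butter_coefs(band, fs)
  ntaps <- max(length(co$a), length(co$b))
  if (length(x) < 3 * ntaps) abort("signal too short for the band-pass filter")
  padlen <- padlen %||% (3 * (ntaps - 1))
  padlen <- min(padlen, length(x) - 1)
  n <- length(x)
  pre <- 2 * x[1] - x[(padlen + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - padlen)]
  ext <- c(pre, x, post)
  zi <- lfilter_zi(co$b, co$a)
  y <- iir_filter(co$b, co$a, ext, zi * ext[1])
  y <- rev(iir_filter(co$b, co$a, rev(y), zi * y[length(y)]))
  y <- y[(padlen + 1):(padlen + n)]
  if (is_cs) reclass_signal(y, sig) else y
}

#' One-sided amplitude spectrum
#'
#' Hann-windowed, zero-padded FFT magnitude spectrum, scaled so that a
#' unit-amplitude sinusoid at a bin centre yields magnitude 1.0. The FFT
#' length is the next power of two at least `4 * n` (4x zero-padding), giving
#' enough grid density for parabolic peak interpolation to resolve well below
#' the raw 1/60 Hz resolution of a one-minute record.
#'
#' @param sig a [channel_signal()] or numeric vector.
#' @param fs sampling rate, needed for bare numeric input.
#' @return tibble with columns `frequency` (Hz, 0 to fs/2) and `magnitude`,
#'   with the sampling rate in attribute `fs`.
#' @export
fft_spectrum <- function(sig, fs = NULL) {
  is_cs <- inherits(sig, "channel_signal")
  x <- if (is_cs) sig$value else sig
  fs <- if (is_cs) signal_fs(sig) else fs
  if (is.null(fs)) abort("fs is required for bare numeric input")
  n <- length(x)
  if (n < 8) abort("need at least 8 samples for a spectrum")
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1)) # Hann
  nfft <- 2^ceiling(log2(4 * n))
  xw <- c(x * w, rep(0, nfft - n))
  mag <- Mod(fft(xw))[1:(nfft / 2 + 1)] * 2 / sum(w)
  out <- tibble(frequency = (0:(nfft / 2)) * fs / nfft, magnitude = mag)
  attr(out, "fs") <- fs
  out
}

#' Dominant in-band frequency with parabolic refinement
#'
#' Restricts the spectrum to `[lo, hi]`, takes the magnitude argmax, and
#' refines peak frequency and amplitude by three-point parabolic
#' interpolation. When the argmax sits on the band boundary the estimate is
#' pinned to the boundary bin and flagged `edge_peak`.
#'
#' @param spectrum output of [fft_spectrum()].
#' @param band a [band_spec()].
#' @return a `spectral_estimate`: list with `f_peak` (Hz), `amplitude`,
#'   `band`, `edge_peak`, and the restricted `spectrum`.
#' @export
dominant_frequency <- function(spectrum, band) {
  f <- spectrum$frequency; m <- spectrum$magnitude
  sel <- which(f >= band$lo & f <= band$hi)
  if (length(sel) == 0) abort("band does not overlap the spectrum grid")
  i <- sel[which.max(m[sel])]
  edge <- i == sel[1] || i == sel[length(sel)] || i == 1L || i == length(f)
  if (!edge) {
    den <- m[i - 1] - 2 * m[i] + m[i + 1]
    delta <- if (den != 0) 0.5 * (m[i - 1] - m[i + 1]) / den else 0
    delta <- clamp(delta, -0.5, 0.5)
    df <- f[2] - f[1]
    f_peak <- f[i] + delta * df
    amp <- m[i] - 0.25 * (m[i - 1] - m[i + 1]) * delta
  } else {
    f_peak <- f[i]
    amp <- m[i]
  }
  f_peak <- clamp(f_peak, band$lo, band$hi)
  structure(
    list(f_peak = f_peak, amplitude = amp, band = band, edge_peak = edge,
         spectrum = spectrum[sel, ]),
    class = "spectral_estimate"
  )
}

#' @export
print.spectral_estimate <- function(x, ...) {
  cat(sprintf("<spectral_estimate: %.4f Hz (%.1f per minute), amplitude %.4g, band %s [%g, %g] Hz%s>\n",
              x$f_peak, 60 * x$f_peak, x$amplitude, x$band$name, x$band$lo,
              x$band$hi, if (x$edge_peak) ", edge peak" else ""))
  invisible(x)
}

#' Convert a spectral estimate to beats/breaths per minute
#'
#' @param estimate a `spectral_estimate` (or frequency in Hz).
#' @return rate in per-minute units (`60 * f_peak`).
#' @export
to_bpm <- function(estimate) {
  f <- if (inherits(estimate, "spectral_estimate")) estimate$f_peak else estimate
  60 * f
}

#' Band-pass, spectrum and peak in one step
#'
#' The raw-video-analysis core: band-filters the series, computes the
#' windowed spectrum of the filtered series, and returns the dominant in-band
#' frequency estimate.
#'
#' @param sig a [channel_signal()].
#' @param band a [band_spec()].
#' @return a list with `estimate` (class `spectral_estimate`) and `filtered`
#'   (the band-passed [channel_signal()]).
#' @export
analyze_band <- function(sig, band) {
  filtered <- butterworth_bandpass(sig, band)
  est <- dominant_frequency(fft_spectrum(filtered), band)
  list(estimate = est, filtered = filtered)
}
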