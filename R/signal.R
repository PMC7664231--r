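#' Channel signals
#'
#' A `channel_signal` is a one-dimensional luminosity time series extracted
#' from a cropped frame stack: a tibble with columns `t_sec`, `value` and
#' `valid`, carrying the sampling rate (`fs`, the stack frame rate) and the
#' channel name (`"G"` for the green channel, `"a"` for CIELAB a*) as
#' attributes.
#'
#' @param values numeric vector.
#' @param fs sampling rate in Hz.
#' @param channel channel tag, typically `"G"` or `"a"`.
#' @param valid per-sample logical (defaults to all `TRUE`).
#' @return a `channel_signal` tibble.
#' @export
channel_signal <- function(values, fs, channel = "G", valid = NULL) {
  stopifnot(is.numeric(values), is_number(fs), fs > 0)
  if (!all(is.finite(values))) abort("channel signal values must be finite")
  n <- length(values)
  valid <- valid %||% rep(TRUE, n)
  out <- tibble(t_sec = (seq_len(n) - 1) / fs, value = values, valid = valid)
  class(out) <- c("channel_signal", class(out))
  attr(out, "fs") <- fs
  attr(out, "channel") <- channel
  out
}

signal_fs <- function(sig) attr(sig, "fs")
signal_values <- function(sig) sig$value

# keep channel_signal class + attrs through dplyr-style copies
reclass_signal <- function(values, template, valid = NULL) {
  channel_signal(values, fs = attr(template, "fs"),
                 channel = attr(template, "channel"),
                 valid = valid %||% template$valid)
}

#' Convert an 8-bit sRGB frame to CIELAB
#'
#' Standard colourimetric path: IEC 61966-2-1 de-gamma to linear RGB, linear
#' map to CIE XYZ under the D65 white point, then the CIE L*a*b* functions
#' (D65 reference white). `a*` is the green-to-red opponent axis used as the
#' respiration-sensitive channel.
#'
#' @param frame `H x W x 3` numeric array of 8-bit values (0-255).
#' @return `H x W x 3` numeric array with L*, a*, b* slices.
#' @export
rgb_to_lab <- function(frame) {
  d <- dim(frame)
  if (length(d) != 3L || d[3] != 3L) abort("rgb_to_lab expects an H x W x 3 array")
  v <- frame / 255
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  R <- lin[, , 1]; G <- lin[, , 2]; B <- lin[, , 3]
  # reference white = matrix * (1,1,1), so neutral inputs give a* = b* = 0 exactly
  X <- (0.4124564 * R + 0.3575761 * G + 0.1804375 * B) / 0.9504700
  Y <- (0.2126729 * R + 0.7151522 * G + 0.0721750 * B) / 1.0000001
  Z <- (0.0193339 * R + 0.1191920 * G + 0.9503041 * B) / 1.0888300
  eps <- 216 / 24389; kap <- 24389 / 27
  f <- function(t) ifelse(t > eps, t^(1 / 3), (kap * t + 16) / 116)
  fx <- f(X); fy <- f(Y); fz <- f(Z)
  out <- array(0, d)
  out[, , 1] <- 116 * fy - 16
  out[, , 2] <- 500 * (fx - fy)
  out[, , 3] <- 200 * (fy - fz)
  out
}

srgb_degamma <- function(v) ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)

# 8-bit de-gamma lookup (frames hold quantized 0..255 values)
.srgb_lut <- srgb_degamma((0:255) / 255)

# a* slice only; uses the LUT when the frame is 8-bit quantized
a_star <- function(frame) {
  if (all(frame == floor(frame)) && min(frame) >= 0 && max(frame) <= 255) {
    lin <- .srgb_lut[frame + 1L]
    dim(lin) <- dim(frame)
  } else {
    lin <- srgb_degamma(frame / 255)
  }
  R <- lin[, , 1]; G <- lin[, , 2]; B <- lin[, , 3]
  X <- (0.4124564 * R + 0.3575761 * G + 0.1804375 * B) / 0.9504700
  Y <- (0.2126729 * R + 0.7151522 * G + 0.0721750 * B) / 1.0000001
  eps <- 216 / 24389; kap <- 24389 / 27
  f <- function(t) ifelse(t > eps, t^(1 / 3), (kap * t + 16) / 116)
  500 * (f(X) - f(Y))
}

# per-frame spatial mean of a*, vectorized across the whole stack
a_star_means <- function(frames) {
  npx <- prod(dim(frames[[1]])[1:2])
  quant <- all(vapply(frames[1], function(f) all(f == floor(f)) && min(f) >= 0 && max(f) <= 255,
                      logical(1)))
  chan <- function(k) vapply(frames, function(f) as.vector(f[, , k]), numeric(npx))
  lin <- function(m) if (quant) matrix(.srgb_lut[m + 1L], nrow(m), ncol(m)) else srgb_degamma(m / 255)
  R <- lin(chan(1)); G <- lin(chan(2)); B <- lin(chan(3))
  X <- (0.4124564 * R + 0.3575761 * G + 0.1804375 * B) / 0.9504700
  Y <- (0.2126729 * R + 0.7151522 * G + 0.0721750 * B) / 1.0000001
  eps <- 216 / 24389; kap <- 24389 / 27
  f3 <- function(t) {
    out <- t^(1 / 3)
    low <- t <= eps
    if (any(low)) out[low] <- (kap * t[low] + 16) / 116
    out
  }
  a <- 500 * (f3(X) - f3(Y))
  colMeans(matrix(a, npx))
}

#' Extract a per-frame luminosity series from a cropped stack
#'
#' The "luminosity" of a channel in a frame is its spatial mean over all crop
#' pixels. Frames flagged invalid by tracking are filled by linear
#' interpolation between valid neighbours (never zero-filled, which would
#' inject broadband energy). The series is mean-centred and linearly detrended
#' before return, removing the illumination drift that would otherwise
#' dominate the low band edge.
#'
#' @param stack a cropped RGB `frame_stack`.
#' @param channel `"G"` (green, cardiac) or `"a"` (CIELAB a*, respiratory).
#' @param frame_valid optional per-frame logical from tracking.
#' @return a [channel_signal()].
#' @export
extract_series <- function(stack, channel = c("G", "a"), frame_valid = NULL) {
  channel <- match.arg(channel)
  stopifnot(inherits(stack, "frame_stack"))
  n <- n_frames(stack)
  if (n < 2) abort("need at least 2 frames")
  frame_valid <- frame_valid %||% rep(TRUE, n)
  if (!any(frame_valid)) abort("all frames are invalid; nothing to extract")
  vals <- if (channel == "G") {
    vapply(stack$frames, function(f) mean(f[, , 2]), numeric(1))
  } else {
    a_star_means(stack$frames)
  }
  if (!all(frame_valid)) {
    idx <- which(frame_valid)
    vals <- approx(idx, vals[idx], xout = seq_len(n), rule = 2)$y
  }
  channel_signal(detrend_linear(vals), fs = stack$fps, channel = channel,
                 valid = frame_valid)
}
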