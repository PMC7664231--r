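#' Synthetic RGB scene specification
#'
#' Describes a synthetic one-minute style recording of a textured surface
#' carrying photoplethysmographic modulation confined to a rectangular region
#' of interest: the green channel oscillates at the cardiac frequency and the
#' red channel at the respiratory frequency (red-green opponency drives the
#' CIELAB a* channel), optionally with a slow red-channel drift emulating the
#' chromatic trend that head motion and illumination geometry impose on real
#' recordings. Gaussian pixel noise is added in floating point *before* 8-bit
#' quantization, so sub-unit amplitudes survive the quantizer by dithering.
#'
#' @param width,height frame size in pixels.
#' @param n_frames number of frames.
#' @param fps frame rate in Hz (default 30).
#' @param roi ROI rectangle `c(x, y, w, h)`, 0-based, half-open.
#' @param hr_hz,rr_hz planted cardiac / respiratory frequencies (Hz).
#' @param amp_hr,amp_rr modulation amplitudes in 8-bit digital numbers
#'   (sub-unit values allowed when `noise_sd >= 0.5`).
#' @param noise_sd per-pixel Gaussian noise SD in digital numbers.
#' @param motion per-frame translation: a length-2 vector (constant velocity,
#'   px/frame) or an `n_frames x 2` matrix of per-frame displacements.
#' @param occluders optional list of vertical bars, each `c(x, w)` in frame
#'   coordinates (static), drawn at `occluder_value`.
#' @param occluder_value gray level of occluder bars (digital numbers).
#' @param drift_hz,drift_amp red-channel drift frequency (Hz) and amplitude
#'   (digital numbers); 0 disables it.
#' @param base_rgb background mean colour, digital numbers.
#' @param texture_sd,texture_smooth SD (digital numbers) and smoothing window
#'   (px) of the static random background texture.
#' @param seed RNG seed; identical spec + seed gives bit-identical scenes.
#' @return a validated `scene_spec` object.
#' @export
scene_spec <- function(width = 64, height = 64, n_frames = 300, fps = 30,
                       roi = c(16, 16, 32, 32),
                       hr_hz = 1.5, rr_hz = 0.9,
                       amp_hr = 2, amp_rr = 2, noise_sd = 0,
                       motion = c(0, 0), occluders = NULL, occluder_value = 70,
                       drift_hz = 0, drift_amp = 0,
                       base_rgb = c(150, 135, 120),
                       texture_sd = 12, texture_smooth = 5, seed = 1) {
  stopifnot(width >= 4, height >= 4, n_frames >= 2, fps > 0,
            amp_hr >= 0, amp_rr >= 0, noise_sd >= 0, drift_amp >= 0)
  fmax <- max(hr_hz, rr_hz, drift_hz)
  if (fps <= 2 * fmax) {
    abort(sprintf("fps = %g violates the Nyquist requirement for the planted %g Hz component",
                  fps, fmax))
  }
  if (is.matrix(motion)) {
    stopifnot(nrow(motion) == n_frames, ncol(motion) == 2)
  } else {
    stopifnot(length(motion) == 2)
    motion <- matrix(rep(motion, each = n_frames), n_frames, 2)
  }
  motion[1, ] <- 0 # first frame defines the reference position
  offsets <- apply(motion, 2, cumsum)
  rois <- cbind(roi[1] + offsets[, 1], roi[2] + offsets[, 2], roi[3], roi[4])
  if (any(rois[, 1] < 0 | rois[, 2] < 0 |
          rois[, 1] + rois[, 3] > width | rois[, 2] + rois[, 4] > height)) {
    abort("roi leaves the frame bounds under the requested motion")
  }
  structure(
    list(width = width, height = height, n_frames = n_frames, fps = fps,
         roi = roi, hr_hz = hr_hz, rr_hz = rr_hz,
         amp_hr = amp_hr, amp_rr = amp_rr, noise_sd = noise_sd,
         motion = motion, offsets = offsets, rois = rois,
         occluders = occluders, occluder_value = occluder_value,
         drift_hz = drift_hz, drift_amp = drift_amp,
         base_rgb = base_rgb, texture_sd = texture_sd,
         texture_smooth = texture_smooth, seed = seed),
    class = "scene_spec"
  )
}

# separable moving-average smoothing of a matrix (reflecting edges); k made odd
smooth_field <- function(m, k) {
  if (k <= 1) return(m)
  if (k %% 2 == 0) k <- k + 1
  pad <- k %/% 2
  sm_cols <- function(mm) {
    ext <- rbind(mm[pad:1, , drop = FALSE], mm,
                 mm[nrow(mm):(nrow(mm) - pad + 1), , drop = FALSE])
    sm <- stats::filter(ext, rep(1 / k, k), sides = 2)
    matrix(sm[(pad + 1):(pad + nrow(mm)), ], nrow(mm), ncol(mm))
  }
  t(sm_cols(t(sm_cols(m))))
}

# bilinear sample of big matrix `m` for an H x W window at fractional offset
sample_window <- function(m, h, w, oy, ox) {
  y <- seq_len(h) + oy; x <- seq_len(w) + ox
  y0 <- floor(y); x0 <- floor(x)
  fy <- y - y0; fx <- x - x0
  if (all(fy == 0) && all(fx == 0)) return(m[y0, x0])
  a <- m[y0, x0] * outer(1 - fy, 1 - fx) + m[y0 + 1, x0] * outer(fy, 1 - fx) +
    m[y0, x0 + 1] * outer(1 - fy, fx) + m[y0 + 1, x0 + 1] * outer(fy, fx)
  a
}

#' Generate a synthetic RGB scene
#'
#' Renders the frame stack described by a [scene_spec()]: a smoothed random
#' background texture translating rigidly under the spec's motion, sinusoidal
#' green/red modulation confined to the (moving) ROI, optional static
#' occluder bars overwriting pixels, then pre-quantization Gaussian noise and
#' 8-bit quantization.
#'
#' @param spec a [scene_spec()].
#' @return an `rgb_scene`: list with `stack` (a [frame_stack()]) and `truth`
#'   (planted `hr_hz`, `rr_hz`, per-frame `roi` tibble with 0-based
#'   coordinates, and per-frame `occluded_frac` of ROI pixels overwritten by
#'   occluders).
#' @export
generate_rgb_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  local_seed(spec$seed, {
    h <- spec$height; w <- spec$width; n <- spec$n_frames
    off <- spec$offsets
    # frame f shows the texture shifted by +off, i.e. the sampling window
    # slides by -off; pad the texture accordingly (+1 px for bilinear)
    pad_lo <- ceiling(pmax(0, apply(off, 2, max))) + 1
    pad_hi <- ceiling(pmax(0, -apply(off, 2, min))) + 2
    th <- h + pad_lo[2] + pad_hi[2]
    tw <- w + pad_lo[1] + pad_hi[1]
    tex <- lapply(1:3, function(c) {
      f <- smooth_field(matrix(rnorm(th * tw), th, tw), spec$texture_smooth)
      spec$base_rgb[c] + f / stats::sd(f) * spec$texture_sd
    })
    t_sec <- (seq_len(n) - 1) / spec$fps
    hr_mod <- spec$amp_hr * sin(2 * pi * spec$hr_hz * t_sec)
    rr_mod <- spec$amp_rr * sin(2 * pi * spec$rr_hz * t_sec)
    drift <- if (spec$drift_amp > 0) {
      spec$drift_amp * sin(2 * pi * spec$drift_hz * t_sec + runif(1, 0, 2 * pi))
    } else numeric(n)
    occ_frac <- numeric(n)
    frames <- vector("list", n)
    for (f in seq_len(n)) {
      # scene content at offset: window slides opposite to content motion
      oy <- pad_lo[2] - off[f, 2]; ox <- pad_lo[1] - off[f, 1]
      R <- sample_window(tex[[1]], h, w, oy, ox)
      G <- sample_window(tex[[2]], h, w, oy, ox)
      B <- sample_window(tex[[3]], h, w, oy, ox)
      box <- spec$rois[f, ]
      rr_px <- box_rows(box); rc_px <- box_cols(box)
      G[rr_px, rc_px] <- G[rr_px, rc_px] + hr_mod[f]
      R[rr_px, rc_px] <- R[rr_px, rc_px] + rr_mod[f] + drift[f]
      if (!is.null(spec$occluders)) {
        occ_cols <- integer(0)
        for (bar in spec$occluders) {
          cols <- seq.int(max(1, floor(bar[1]) + 1), min(w, floor(bar[1] + bar[2])))
          R[, cols] <- spec$occluder_value
          G[, cols] <- spec$occluder_value
          B[, cols] <- spec$occluder_value
          occ_cols <- union(occ_cols, cols)
        }
        occ_frac[f] <- length(intersect(occ_cols, rc_px)) / length(rc_px)
      }
      fr <- array(c(R, G, B), c(h, w, 3))
      if (spec$noise_sd > 0) fr <- fr + rnorm(length(fr), sd = spec$noise_sd)
      frames[[f]] <- clamp(round(fr), 0, 255)
    }
    structure(
      list(
        stack = frame_stack(frames, fps = spec$fps),
        truth = list(
          hr_hz = spec$hr_hz, rr_hz = spec$rr_hz,
          roi = tibble(frame = seq_len(n) - 1L,
                       x = spec$rois[, 1], y = spec$rois[, 2],
                       w = spec$rois[, 3], h = spec$rois[, 4]),
          occluded_frac = occ_frac,
          drift_hz = spec$drift_hz, drift_amp = spec$drift_amp
        ),
        spec = spec
      ),
      class = "rgb_scene"
    )
  })
}

#' Synthetic radiometric thermal scene
#'
#' Generates a stack of temperature matrices (degrees C): a uniform background
#' plus a Gaussian hotspot whose peak follows a per-frame trajectory, plus
#' optional Gaussian noise. The hotspot centre sits at the centre of the ROI,
#' on an exact pixel, so at zero noise the per-frame ROI maximum equals the
#' trajectory exactly.
#'
#' @param width,height frame size (defaults mirror a 336 x 256 longwave
#'   sensor, scaled down).
#' @param n_frames number of frames.
#' @param fps thermal frame rate (default 9 Hz).
#' @param background_c background temperature, degrees C.
#' @param hotspot_peak_c scalar or per-frame vector of peak temperature.
#' @param hotspot_sigma Gaussian width in pixels; 0 disables the hotspot.
#' @param roi ROI rectangle `c(x, y, w, h)`, 0-based, half-open.
#' @param noise_sd_c per-pixel noise SD, degrees C.
#' @param seed RNG seed.
#' @return a `thermal_scene`: list with `stack` (single-channel
#'   [frame_stack()]) and `truth` (`peak_c` per frame, `roi`).
#' @export
generate_thermal_scene <- function(width = 56, height = 42, n_frames = 54,
                                   fps = 9, background_c = 22,
                                   hotspot_peak_c = 38.5, hotspot_sigma = 4,
                                   roi = c(16, 10, 24, 20), noise_sd_c = 0,
                                   seed = 1) {
  stopifnot(n_frames >= 1, fps > 0, hotspot_sigma >= 0, noise_sd_c >= 0)
  if (!box_valid_in(roi, height, width)) abort("roi lies outside the thermal frame")
  peak <- rep_len(hotspot_peak_c, n_frames)
  if (hotspot_sigma > 0 && any(peak <= background_c)) {
    abort("hotspot_peak_c must exceed background_c")
  }
  cx <- floor(roi[1] + roi[3] / 2) + 0.5 # pixel centre (1-based grid below)
  cy <- floor(roi[2] + roi[4] / 2) + 0.5
  xg <- (seq_len(width) - 0.5); yg <- (seq_len(height) - 0.5)
  g <- if (hotspot_sigma > 0) {
    outer(exp(-(yg - cy)^2 / (2 * hotspot_sigma^2)),
          exp(-(xg - cx)^2 / (2 * hotspot_sigma^2)))
  } else matrix(0, height, width)
  local_seed(seed, {
    frames <- lapply(seq_len(n_frames), function(f) {
      fr <- background_c + (peak[f] - background_c) * g
      if (noise_sd_c > 0) fr <- fr + rnorm(length(fr), sd = noise_sd_c)
      fr
    })
    structure(
      list(stack = frame_stack(frames, fps = fps),
           truth = list(peak_c = peak,
                        roi = tibble(frame = seq_len(n_frames) - 1L,
                                     x = roi[1], y = roi[2], w = roi[3], h = roi[4]))),
      class = "thermal_scene"
    )
  })
}

#' Write / read a thermal stack as per-frame CSV matrices
#'
#' One comma-separated matrix of degrees-C floats per frame
#' (`frame_%06d.csv`), plus `meta.yaml` with the frame rate and geometry.
#' Decimal points are required; files using decimal commas are rejected.
#'
#' @param stack a single-channel [frame_stack()].
#' @param dir directory to write to / read from.
#' @export
write_thermal_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "frame_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- frame_dim(stack)
  for (i in seq_along(stack$frames)) {
    utils::write.table(stack$frames[[i]],
                       file.path(dir, sprintf("frame_%06d.csv", i - 1L)),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  yaml::write_yaml(list(fps = stack$fps, n_frames = length(stack$frames),
                        width = unname(d[2]), height = unname(d[1])),
                   file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' Signal-to-noise presets for cohort generation
#'
#' `"default"` reproduces the difficulty regime the pipeline is designed for:
#' sub-unit cardiac amplitude (dithered through the quantizer), moderate pixel
#' noise, and a slow red-channel drift whose amplitude is comparable to the
#' respiratory signal. Inside the wide 0.33-3.1 Hz analysis band that drift
#' frequently captures the spectral argmax, which is what makes single-band
#' respiratory estimation unreliable and the band-classified re-analysis
#' worthwhile. `"clean"` is a high-SNR variant without drift.
#'
#' @param name `"default"` or `"clean"`.
#' @return list of generator parameters.
#' @export
snr_preset <- function(name = c("default", "clean")) {
  name <- match.arg(name)
  switch(name,
    default = list(amp_hr = 0.3, amp_rr = 2, noise_sd = 2,
                   drift_hz_range = c(0.25, 0.60), drift_ratio_range = c(0.5, 1.2)),
    clean = list(amp_hr = 0.4, amp_rr = 3, noise_sd = 0.5,
                 drift_hz_range = c(0, 0), drift_ratio_range = c(0, 0))
  )
}

#' Generate a labelled synthetic cohort
#'
#' Draws `n_animals` scenes spanning the three respiratory bands (low
#' 0.2-1.2, medium 1.2-2.2, high 2.2-3.2 Hz; a frequency exactly on a
#' boundary belongs to the lower band) and the cardiac range 1.05-2.2 Hz
#' (63-132 BPM), with reference labels `60 * frequency`. Scene specs are
#' returned in a list-column; frames are rendered on demand by
#' [scene_signals()] or [generate_rgb_scene()].
#'
#' @param n_animals number of scenes (study size: 134).
#' @param band_mix proportions of low/medium/high scenes (must sum to 1).
#' @param seed cohort RNG seed.
#' @param preset SNR preset name, see [snr_preset()].
#' @param fps frame rate (default 30).
#' @param duration_s recording length in seconds (default 60).
#' @param width,height,roi scene geometry shared by all scenes.
#' @return tibble with `scene_id`, `band`, `hr_hz`, `rr_hz`, `hr_bpm`,
#'   `rr_brpm` and the `spec` list-column.
#' @export
generate_cohort <- function(n_animals = 134, band_mix = c(1, 1, 1) / 3,
                            seed = 1, preset = "default",
                            fps = 30, duration_s = 60,
                            width = 40, height = 40, roi = c(8, 8, 24, 24)) {
  stopifnot(length(band_mix) == 3)
  if (abs(sum(band_mix) - 1) > 1e-8) abort("band_mix proportions must sum to 1")
  p <- snr_preset(preset)
  bands <- c("low", "medium", "high")
  ranges <- list(low = c(0.2, 1.2), medium = c(1.2, 2.2), high = c(2.2, 3.2))
  counts <- floor(band_mix * n_animals)
  rem <- n_animals - sum(counts)
  if (rem > 0) counts[order(band_mix * n_animals - counts, decreasing = TRUE)[seq_len(rem)]] <-
      counts[order(band_mix * n_animals - counts, decreasing = TRUE)[seq_len(rem)]] + 1
  local_seed(seed, {
    band <- sample(rep(bands, counts))
    rr_hz <- vapply(band, function(b) runif(1, ranges[[b]][1], ranges[[b]][2]), numeric(1))
    hr_hz <- runif(n_animals, 1.05, 2.2)
    drift_hz <- runif(n_animals, p$drift_hz_range[1], p$drift_hz_range[2])
    drift_amp <- p$amp_rr * runif(n_animals, p$drift_ratio_range[1], p$drift_ratio_range[2])
    scene_seeds <- sample.int(.Machine$integer.max - 1, n_animals)
    specs <- lapply(seq_len(n_animals), function(i) {
      scene_spec(width = width, height = height,
                 n_frames = round(duration_s * fps), fps = fps, roi = roi,
                 hr_hz = hr_hz[i], rr_hz = rr_hz[i],
                 amp_hr = p$amp_hr, amp_rr = p$amp_rr, noise_sd = p$noise_sd,
                 drift_hz = drift_hz[i], drift_amp = drift_amp[i],
                 seed = scene_seeds[i])
    })
    tibble(
      scene_id = sprintf("scene_%03d", seq_len(n_animals)),
      band = factor(band, levels = bands),
      hr_hz = hr_hz, rr_hz = rr_hz,
      hr_bpm = 60 * hr_hz, rr_brpm = 60 * rr_hz,
      spec = specs
    )
  })
}

#' Ground-truth ROI track of a generated scene
#'
#' Converts the per-frame true ROI of an [generate_rgb_scene()] output into a
#' `tracked_roi` (source `"label-file"`), standing in for the supervised ROI
#' selection step of the original acquisition protocol.
#'
#' @param scene an `rgb_scene`.
#' @return a [tracked_roi()].
#' @export
truth_track <- function(scene) {
  tracked_roi(dplyr::mutate(scene$truth$roi, valid = TRUE), source = "label-file")
}

#' Render a scene and extract both luminosity series
#'
#' Convenience wrapper: generates the frames, crops them along the true ROI
#' track and extracts the green-channel and a*-channel series. Frames are
#' discarded afterwards, keeping cohort-scale runs within memory.
#'
#' @param spec a [scene_spec()].
#' @return list with `g` and `a` [channel_signal()]s and the scene `truth`.
#' @export
scene_signals <- function(spec) {
  scene <- generate_rgb_scene(spec)
  crop <- crop_stack(scene$stack, truth_track(scene))
  list(g = extract_series(crop, "G"),
       a = extract_series(crop, "a"),
       truth = scene$truth)
}
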