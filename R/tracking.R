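#' Tracked regions of interest
#'
#' A `tracked_roi` is a tibble with one rectangle per frame (`frame` 0-based,
#' `x`, `y`, `w`, `h` in 0-based half-open pixel coordinates) and a `valid`
#' flag carrying the tracking confidence; frames with `valid = FALSE` carry
#' the last valid box. The `source` attribute records whether the track came
#' from the tracker (`"manual-seed"`) or from a label file (`"label-file"`).
#'
#' @param boxes tibble/data frame with columns `frame, x, y, w, h` and
#'   optionally `valid`.
#' @param source `"manual-seed"` or `"label-file"`.
#' @return a `tracked_roi` tibble.
#' @export
tracked_roi <- function(boxes, source = c("manual-seed", "label-file")) {
  source <- match.arg(source)
  boxes <- as_tibble(boxes)
  need <- c("frame", "x", "y", "w", "h")
  if (!all(need %in% names(boxes))) {
    abort(sprintf("tracked_roi needs columns %s", paste(need, collapse = ", ")))
  }
  if (!"valid" %in% names(boxes)) boxes$valid <- TRUE
  if (any(boxes$w <= 0 | boxes$h <= 0)) abort("box width and height must be positive")
  boxes <- boxes[order(boxes$frame), c(need, "valid")]
  class(boxes) <- c("tracked_roi", class(boxes))
  attr(boxes, "source") <- source
  boxes
}

#' Read / write ROI label files
#'
#' Label files are plain CSV with header `frame,x,y,w,h[,valid]`. Frame
#' indices are 0-based by default; a first comment line `# index_base: 1`
#' declares 1-based indices, which are shifted down on read. Missing frame
#' indices are an error naming the gaps. Writing then reading a track is
#' lossless.
#'
#' @param path CSV path.
#' @return a [tracked_roi()] with source `"label-file"`.
#' @export
read_label_file <- function(path) {
  first <- readLines(path, n = 1)
  base <- 0L
  if (grepl("^#", first)) {
    m <- regmatches(first, regexec("index_base:\\s*(\\d+)", first))[[1]]
    if (length(m) == 2) base <- as.integer(m[2])
  }
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  df$frame <- as.integer(df$frame) - base
  idx <- sort(df$frame)
  gaps <- setdiff(seq(min(idx), max(idx)), idx)
  if (length(gaps)) {
    abort(sprintf("label file has missing frames: %s", paste(gaps, collapse = ", ")))
  }
  if ("valid" %in% names(df)) df$valid <- as.logical(df$valid)
  tracked_roi(df, source = "label-file")
}

#' @rdname read_label_file
#' @param track a [tracked_roi()].
#' @param index_base 0 (default) or 1.
#' @export
write_label_file <- function(track, path, index_base = 0L) {
  df <- as_tibble(track)
  df$frame <- df$frame + index_base
  writeLines(sprintf("# index_base: %d", index_base), path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

rgb_to_gray <- function(frame) {
  if (length(dim(frame)) == 3L) {
    0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3]
  } else frame
}

#' Tracker configuration
#'
#' Pyramidal Lucas-Kanade defaults: 3 pyramid levels, 15 x 15 integration
#' window, up to 30 iterations per level with convergence threshold 0.01 px,
#' at most 30 corner features, and box re-detection when fewer than 25% of the
#' features survive a frame.
#'
#' @param levels pyramid levels.
#' @param window odd window size in px.
#' @param max_iter iterations per level.
#' @param eps convergence threshold (px).
#' @param max_features corner budget.
#' @param min_quality corner threshold relative to the strongest corner.
#' @param resid_tol mean absolute patch residual (digital numbers) above which
#'   a feature is dropped as diverged between consecutive frames.
#' @param monitor_tol mean absolute residual against the feature's *original*
#'   template above which it is dropped (appearance monitoring; kills features
#'   that lock onto static occluders such as cage bars).
#' @param survival_frac minimum surviving-feature fraction for a valid frame.
#' @param motion_gate maximum deviation (px/frame) of a probation feature's
#'   flow from the established track motion before it is rejected.
#' @export
track_config <- function(levels = 3, window = 15, max_iter = 30, eps = 0.01,
                         max_features = 30, min_quality = 0.05,
                         resid_tol = 12, monitor_tol = 25, survival_frac = 0.25,
                         motion_gate = 0.75) {
  list(levels = levels, window = window, max_iter = max_iter, eps = eps,
       max_features = max_features, min_quality = min_quality,
       resid_tol = resid_tol, monitor_tol = monitor_tol,
       survival_frac = survival_frac, motion_gate = motion_gate)
}

#' Detect corner features inside an ROI
#'
#' Shi-Tomasi corners: the minimum eigenvalue of the locally summed gradient
#' structure tensor, with 3 x 3 non-maximum suppression, restricted to the ROI
#' and kept strictly inside the frame so the tracking window fits.
#'
#' @param frame an RGB or grayscale frame (numeric array/matrix).
#' @param roi rectangle `c(x, y, w, h)`, 0-based half-open.
#' @param config a [track_config()].
#' @return tibble with 0-based `x`, `y` and `score`, strongest first.
#' @export
detect_corner_features <- function(frame, roi, config = track_config()) {
  g <- rgb_to_gray(frame)
  h <- nrow(g); w <- ncol(g)
  if (!box_valid_in(roi, h, w)) abort("roi lies outside the frame")
  ix <- matrix(0, h, w); iy <- matrix(0, h, w)
  ix[, 2:(w - 1)] <- (g[, 3:w] - g[, 1:(w - 2)]) / 2
  iy[2:(h - 1), ] <- (g[3:h, ] - g[1:(h - 2), ]) / 2
  k <- 5 # structure-tensor summation window
  sxx <- smooth_field(ix * ix, k); syy <- smooth_field(iy * iy, k)
  sxy <- smooth_field(ix * iy, k)
  tr2 <- (sxx + syy) / 2
  det_off <- sqrt(((sxx - syy) / 2)^2 + sxy^2)
  score <- tr2 - det_off # minimum eigenvalue
  # restrict to roi, with margin so the LK window stays inside the frame
  margin <- (config$window %/% 2) + 2
  rows <- intersect(box_rows(roi), (margin + 1):(h - margin))
  cols <- intersect(box_cols(roi), (margin + 1):(w - margin))
  if (!length(rows) || !length(cols)) abort("no trackable features: roi too small or too close to the frame edge")
  s <- matrix(-Inf, h, w); s[rows, cols] <- score[rows, cols]
  best <- max(s[rows, cols])
  if (!is.finite(best) || best <= 1e-6) abort("no trackable features in the roi (textureless region)")
  thr <- best * config$min_quality
  keep <- which(s >= thr, arr.ind = TRUE)
  # 3x3 non-maximum suppression
  nm <- vapply(seq_len(nrow(keep)), function(i) {
    r <- keep[i, 1]; c <- keep[i, 2]
    nb <- s[max(1, r - 1):min(h, r + 1), max(1, c - 1):min(w, c + 1)]
    s[r, c] >= max(nb)
  }, logical(1))
  keep <- keep[nm, , drop = FALSE]
  ord <- order(s[keep], decreasing = TRUE)
  keep <- keep[ord[seq_len(min(nrow(keep), config$max_features))], , drop = FALSE]
  tibble(x = keep[, 2] - 1, y = keep[, 1] - 1, score = s[keep])
}

build_pyramid <- function(gray, levels) {
  pyr <- vector("list", levels)
  pyr[[1]] <- gray
  for (l in seq_len(levels - 1)) {
    m <- pyr[[l]]
    h2 <- nrow(m) %/% 2; w2 <- ncol(m) %/% 2
    if (h2 < 8 || w2 < 8) { pyr <- pyr[1:l]; break }
    pyr[[l + 1]] <- (m[seq_len(h2) * 2 - 1, seq_len(w2) * 2 - 1] +
                     m[seq_len(h2) * 2, seq_len(w2) * 2 - 1] +
                     m[seq_len(h2) * 2 - 1, seq_len(w2) * 2] +
                     m[seq_len(h2) * 2, seq_len(w2) * 2]) / 4
  }
  pyr
}

# bilinear patch sample centred at 0-based (x, y); returns win x win matrix or NULL
sample_patch <- function(m, x, y, half) {
  xs <- x + 1 + (-half):half
  ys <- y + 1 + (-half):half
  if (min(xs) < 1 || min(ys) < 1 || max(xs) > ncol(m) - 1 || max(ys) > nrow(m) - 1) return(NULL)
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  m[y0, x0] * outer(1 - fy, 1 - fx) + m[y0 + 1, x0] * outer(fy, 1 - fx) +
    m[y0, x0 + 1] * outer(1 - fy, fx) + m[y0 + 1, x0 + 1] * outer(fy, fx)
}

# pyramidal LK for one feature; returns c(dx, dy, resid) or NULL on failure
lk_flow <- function(pyr_prev, pyr_next, x, y, config) {
  half <- config$window %/% 2
  levels <- min(length(pyr_prev), config$levels)
  gx <- 0; gy <- 0
  resid <- Inf
  for (l in levels:1) {
    sc <- 2^(l - 1)
    px <- x / sc; py <- y / sc
    tmpl <- sample_patch(pyr_prev[[l]], px, py, half + 1)
    if (is.null(tmpl)) { if (l > 1) next else return(NULL) }
    w1 <- config$window
    tc <- tmpl[2:(w1 + 1), 2:(w1 + 1)]
    tx <- (tmpl[2:(w1 + 1), 3:(w1 + 2)] - tmpl[2:(w1 + 1), 1:w1]) / 2
    ty <- (tmpl[3:(w1 + 2), 2:(w1 + 1)] - tmpl[1:w1, 2:(w1 + 1)]) / 2
    gxx <- sum(tx * tx); gyy <- sum(ty * ty); gxy <- sum(tx * ty)
    det <- gxx * gyy - gxy^2
    if (det < 1e-6) { if (l > 1) next else return(NULL) }
    vx <- 0; vy <- 0
    for (it in seq_len(config$max_iter)) {
      p <- sample_patch(pyr_next[[l]], px + gx + vx, py + gy + vy, half)
      if (is.null(p)) return(NULL)
      di <- tc - p
      bx <- sum(di * tx); by <- sum(di * ty)
      ddx <- (gyy * bx - gxy * by) / det
      ddy <- (gxx * by - gxy * bx) / det
      vx <- vx + ddx; vy <- vy + ddy
      if (abs(ddx) < config$eps && abs(ddy) < config$eps) break
    }
    if (l > 1) { gx <- 2 * (gx + vx); gy <- 2 * (gy + vy) } else {
      gx <- gx + vx; gy <- gy + vy
      p <- sample_patch(pyr_next[[l]], px + gx, py + gy, half)
      resid <- if (is.null(p)) Inf else mean(abs(tc - p))
    }
  }
  if (!is.finite(resid) || resid > config$resid_tol) return(NULL)
  c(gx, gy, resid)
}

#' Track an ROI across a frame stack
#'
#' Kanade-Lucas-Tomasi scheme: corner features detected in the seed box are
#' propagated frame to frame by pyramidal Lucas-Kanade flow. Each feature is
#' monitored against its original appearance, and the box moves by the median
#' displacement of the surviving established features (robust to partial
#' occlusion by, e.g., cage bars). When fewer than `survival_frac` of the
#' established features survive a frame, the frame is reported
#' `valid = FALSE` carrying the last valid box; internally the box coasts at
#' its last velocity and fresh features are re-detected inside it. Re-detected
#' features start on probation: they only join the established set once their
#' motion agrees with the track, so features seeded on a static occluder can
#' never capture the box.
#'
#' @param stack a [frame_stack()].
#' @param seed_box ROI `c(x, y, w, h)` on frame 0 (0-based, half-open).
#' @param config a [track_config()].
#' @return a [tracked_roi()] with source `"manual-seed"`.
#' @export
track_roi <- function(stack, seed_box, config = track_config()) {
  stopifnot(inherits(stack, "frame_stack"))
  n <- n_frames(stack)
  if (n == 0) abort("empty frame stack")
  d <- frame_dim(stack)
  if (!box_valid_in(seed_box, d[1], d[2])) abort("seed box lies outside the first frame")
  half <- config$window %/% 2
  gate <- config$motion_gate

  gray <- rgb_to_gray(stack$frames[[1]])
  pyr <- build_pyramid(gray, config$levels)
  seed_feats <- function(frame_gray, box) {
    fe <- tryCatch(detect_corner_features(frame_gray, box, config),
                   error = function(e) NULL)
    if (is.null(fe)) return(NULL)
    pts <- cbind(fe$x, fe$y)
    tmpl <- lapply(seq_len(nrow(pts)), function(i) {
      sample_patch(frame_gray, pts[i, 1], pts[i, 2], half)
    })
    keep <- !vapply(tmpl, is.null, logical(1))
    list(pts = pts[keep, , drop = FALSE], tmpl = tmpl[keep])
  }
  fs <- seed_feats(gray, seed_box)
  if (is.null(fs) || nrow(fs$pts) == 0) abort("no trackable features in the seed box")
  pts <- fs$pts; tmpl <- fs$tmpl
  prob <- rep(FALSE, nrow(pts))      # probation flags (seed features are trusted)
  n_ref <- nrow(pts)                 # established-set size at last acquisition

  box_int <- as.numeric(seed_box[1:4])  # internal (coasting) box
  last_disp <- c(0, 0)
  out <- matrix(NA_real_, n, 4)
  out[1, ] <- box_int
  valid <- rep(TRUE, n)
  clamp_box <- function(b) {
    c(clamp(b[1], 0, d[2] - b[3]), clamp(b[2], 0, d[1] - b[4]), b[3], b[4])
  }

  for (f in seq.int(2, length.out = n - 1)) {
    gray_next <- rgb_to_gray(stack$frames[[f]])
    pyr_next <- build_pyramid(gray_next, config$levels)
    moved <- lapply(seq_len(nrow(pts)), function(i) {
      lk_flow(pyr, pyr_next, pts[i, 1], pts[i, 2], config)
    })
    ok <- !vapply(moved, is.null, logical(1))
    for (i in which(ok)) { # appearance monitoring vs the original template
      np <- sample_patch(gray_next, pts[i, 1] + moved[[i]][1],
                         pts[i, 2] + moved[[i]][2], half)
      if (is.null(np) || mean(abs(np - tmpl[[i]])) > config$monitor_tol) ok[i] <- FALSE
    }
    # established features must agree with the track velocity: a feature whose
    # flow diverges (e.g. its window caught a static occluder) is dropped.
    # Frame 2 bootstraps the velocity from the median flow instead.
    est_idx <- which(ok & !prob)
    if (length(est_idx)) {
      dsp <- do.call(rbind, moved[est_idx])
      ref_v <- if (f == 2) c(median(dsp[, 1]), median(dsp[, 2])) else last_disp
      good <- abs(dsp[, 1] - ref_v[1]) <= gate & abs(dsp[, 2] - ref_v[2]) <= gate
      surv <- est_idx[good]
    } else {
      surv <- integer(0)
    }
    if (length(surv) >= max(2, ceiling(config$survival_frac * n_ref))) {
      dsp <- do.call(rbind, moved[surv])
      last_disp <- c(median(dsp[, 1]), median(dsp[, 2]))
      valid[f] <- TRUE
    } else {
      valid[f] <- FALSE # coast on the last velocity
      surv <- integer(0)
    }
    box_int <- clamp_box(c(box_int[1] + last_disp[1], box_int[2] + last_disp[2],
                           box_int[3], box_int[4]))
    # probation features must move with the track to be promoted
    promoted <- vapply(seq_along(moved), function(i) {
      ok[i] && prob[i] &&
        abs(moved[[i]][1] - last_disp[1]) <= gate &&
        abs(moved[[i]][2] - last_disp[2]) <= gate
    }, logical(1))
    keep <- union(surv, which(promoted))
    if (length(keep)) {
      dsp_all <- do.call(rbind, moved[keep])
      pts <- cbind(pts[keep, 1] + dsp_all[, 1], pts[keep, 2] + dsp_all[, 2])
      tmpl <- tmpl[keep]
      inb <- pts[, 1] > half + 2 & pts[, 2] > half + 2 &
        pts[, 1] < d[2] - half - 3 & pts[, 2] < d[1] - half - 3 &
        pts[, 1] >= box_int[1] - 2 & pts[, 1] <= box_int[1] + box_int[3] + 2 &
        pts[, 2] >= box_int[2] - 2 & pts[, 2] <= box_int[2] + box_int[4] + 2
      pts <- pts[inb, , drop = FALSE]; tmpl <- tmpl[inb]
      prob <- rep(FALSE, nrow(pts))
    } else {
      pts <- matrix(numeric(0), 0, 2); tmpl <- list(); prob <- logical(0)
    }
    n_ref <- max(1, nrow(pts))
    # top up with probation features when the set has thinned
    if (nrow(pts) < ceiling(config$max_features / 2)) {
      refs <- seed_feats(gray_next, box_int)
      if (!is.null(refs) && nrow(refs$pts) > 0) {
        new <- rep(TRUE, nrow(refs$pts))
        if (nrow(pts) > 0) {
          for (j in seq_len(nrow(refs$pts))) {
            dmin <- min(sqrt((pts[, 1] - refs$pts[j, 1])^2 +
                               (pts[, 2] - refs$pts[j, 2])^2))
            if (dmin < 2) new[j] <- FALSE
          }
        }
        if (any(new)) {
          pts <- rbind(pts, refs$pts[new, , drop = FALSE])
          tmpl <- c(tmpl, refs$tmpl[new])
          prob <- c(prob, rep(TRUE, sum(new)))
        }
      }
    }
    out[f, ] <- box_int
    pyr <- pyr_next
  }
  # valid = FALSE frames carry the last valid box in the reported track
  for (f in seq.int(2, length.out = n - 1)) {
    if (!valid[f]) out[f, ] <- out[max(which(valid[1:(f - 1)])), ]
  }
  tracked_roi(tibble(frame = seq_len(n) - 1L, x = out[, 1], y = out[, 2],
                     w = out[, 3], h = out[, 4], valid = valid),
              source = "manual-seed")
}

#' Crop a stack along a track
#'
#' Cuts the per-frame box out of each frame and resamples it to a fixed
#' output size (nearest neighbour), so planted ROI content is stationary in
#' crop coordinates even when the box moves. When the output size equals the
#' box size and the box is static on integer coordinates, crops are
#' pixel-identical sub-arrays of the originals.
#'
#' @param stack a [frame_stack()].
#' @param track a [tracked_roi()] covering all frames.
#' @param out_size `c(w, h)` of the cropped frames; defaults to the first box.
#' @return a [frame_stack()] of cropped frames.
#' @export
crop_stack <- function(stack, track, out_size = NULL) {
  stopifnot(inherits(stack, "frame_stack"), inherits(track, "tracked_roi"))
  n <- n_frames(stack)
  if (nrow(track) != n) abort("track must cover every frame of the stack")
  out_size <- out_size %||% c(track$w[1], track$h[1])
  ow <- out_size[1]; oh <- out_size[2]
  d <- frame_dim(stack)
  frames <- lapply(seq_len(n), function(f) {
    bx <- track$x[f]; by <- track$y[f]; bw <- track$w[f]; bh <- track$h[f]
    rows <- clamp(round(by + (seq_len(oh) - 0.5) * bh / oh + 0.5), 1, d[1])
    cols <- clamp(round(bx + (seq_len(ow) - 0.5) * bw / ow + 0.5), 1, d[2])
    fr <- stack$frames[[f]]
    if (length(d) == 3L) fr[rows, cols, , drop = FALSE] else fr[rows, cols, drop = FALSE]
  })
  frame_stack(frames, fps = stack$fps)
}
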