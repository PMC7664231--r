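#' Frame stacks
#'
#' A `frame_stack` is the package's in-memory representation of a short video:
#' an ordered list of frames sharing one geometry, plus the frame rate and the
#' per-frame timestamps. RGB frames are `H x W x 3` numeric arrays holding
#' 8-bit digital numbers (0-255); radiometric thermal frames are `H x W`
#' numeric matrices of temperature in degrees Celsius.
#'
#' @param frames list of arrays (all the same shape).
#' @param fps frames per second (Hz), `> 0`.
#' @param timestamps optional numeric vector of seconds from the first frame;
#'   defaults to `(0:(n-1))/fps`. Must be strictly increasing.
#' @return A `frame_stack` object.
#' @export
frame_stack <- function(frames, fps, timestamps = NULL) {
  stopifnot(is.list(frames), length(frames) >= 1L, is_number(fps), fps > 0)
  d1 <- dim(frames[[1]]) %||% length(frames[[1]])
  ok <- vapply(frames, function(f) identical(dim(f) %||% length(f), d1), logical(1))
  if (!all(ok)) abort("all frames in a frame_stack must have identical shape")
  n <- length(frames)
  if (is.null(timestamps)) timestamps <- (seq_len(n) - 1) / fps
  if (length(timestamps) != n || any(diff(timestamps) <= 0)) {
    abort("timestamps must be strictly increasing, one per frame")
  }
  structure(
    list(frames = frames, fps = fps, timestamps = timestamps),
    class = "frame_stack"
  )
}

#' @export
length.frame_stack <- function(x) length(x$frames)

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  kind <- if (length(d) == 3L) "RGB" else "single-channel"
  cat(sprintf("<frame_stack: %d %s frames %dx%d @ %g fps>\n",
              length(x$frames), kind, d[1], d[2], x$fps))
  invisible(x)
}

n_frames <- function(stack) length(stack$frames)
frame_dim <- function(stack) dim(stack$frames[[1]])

#' Write / read an RGB frame stack as numbered PNG files
#'
#' Frames are written as `frame_%06d.png` (index from 0) next to a `meta.yaml`
#' holding `fps`, `n_frames`, `width` and `height`, so a stack round-trips
#' losslessly through disk.
#'
#' @param stack a `frame_stack` of 8-bit RGB frames.
#' @param dir directory to create/fill.
#' @return `write_frame_stack` returns `dir` invisibly; `read_frame_stack`
#'   returns a `frame_stack`.
#' @export
write_frame_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "frame_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- frame_dim(stack)
  for (i in seq_along(stack$frames)) {
    png::writePNG(stack$frames[[i]] / 255,
                  file.path(dir, sprintf("frame_%06d.png", i - 1L)))
  }
  yaml::write_yaml(
    list(fps = stack$fps, n_frames = length(stack$frames),
         width = unname(d[2]), height = unname(d[1])),
    file.path(dir, "meta.yaml")
  )
  invisible(dir)
}

#' @rdname write_frame_stack
#' @param dir directory holding `frame_%06d.png` files and `meta.yaml`.
#' @export
read_frame_stack <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  files <- list.files(dir, pattern = "^frame_\\d{6}\\.png$", full.names = TRUE)
  if (length(files) == 0L) abort(sprintf("no frame_*.png files in %s", dir))
  idx <- as.integer(sub("^frame_(\\d{6})\\.png$", "\\1", basename(files)))
  files <- files[order(idx)]
  idx <- sort(idx)
  gaps <- setdiff(seq(0L, max(idx)), idx)
  if (length(gaps)) {
    abort(sprintf("missing frame indices: %s", paste(gaps, collapse = ", ")))
  }
  frames <- lapply(files, function(f) {
    a <- png::readPNG(f)
    if (length(dim(a)) == 3L && dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
    round(a * 255)
  })
  frame_stack(frames, fps = meta$fps)
}

# rectangle helpers: boxes are (x, y, w, h), 0-based, half-open on right/bottom
box_valid_in <- function(box, h, w) {
  box[1] >= 0 && box[2] >= 0 && box[3] > 0 && box[4] > 0 &&
    box[1] + box[3] <= w && box[2] + box[4] <= h
}

# 1-based row/col index ranges of a box inside an H x W frame
box_rows <- function(box) seq.int(floor(box[2]) + 1L, floor(box[2] + box[4]))
box_cols <- function(box) seq.int(floor(box[1]) + 1L, floor(box[1] + box[3]))
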