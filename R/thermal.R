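#' Read a radiometric thermal stack from per-frame CSV matrices
#'
#' Reads a directory of `frame_%06d.csv` files (comma-separated degrees-C
#' floats, one matrix per frame) plus an optional `meta.yaml` carrying the
#' frame rate (default 9 Hz, the usual longwave video rate). Frames are
#' ordered by their filename index; gaps and ragged matrices are errors, and
#' files using decimal commas are rejected with a pointer at the locale.
#'
#' @param dir directory of CSV frames.
#' @return a single-channel [frame_stack()] of temperatures in degrees C.
#' @export
read_thermal_stack <- function(dir) {
  files <- list.files(dir, pattern = "^frame_\\d{6}\\.csv$", full.names = TRUE)
  if (!length(files)) abort(sprintf("no frame_*.csv files found in %s", dir))
  idx <- as.integer(sub("^frame_(\\d{6})\\.csv$", "\\1", basename(files)))
  files <- files[order(idx)]; idx <- sort(idx)
  gaps <- setdiff(seq(0L, max(idx)), idx)
  if (length(gaps)) abort(sprintf("missing thermal frame indices: %s", paste(gaps, collapse = ", ")))
  fps <- 9
  meta_path <- file.path(dir, "meta.yaml")
  if (file.exists(meta_path)) fps <- yaml::read_yaml(meta_path)$fps %||% 9
  shape <- NULL
  frames <- lapply(seq_along(files), function(i) {
    lines <- readLines(files[i])
    if (any(grepl(";", lines, fixed = TRUE))) {
      abort(sprintf("%s appears to use ';' separators / decimal commas; export with '.' decimal points", files[i]))
    }
    rows <- strsplit(lines, ",", fixed = TRUE)
    ncols <- lengths(rows)
    if (length(unique(ncols)) != 1) {
      abort(sprintf("ragged CSV in %s: row %d has %d fields, expected %d",
                    basename(files[i]), which(ncols != ncols[1])[1],
                    ncols[ncols != ncols[1]][1], ncols[1]))
    }
    vals <- suppressWarnings(as.numeric(unlist(rows)))
    if (anyNA(vals)) {
      abort(sprintf("non-numeric temperature values in %s (decimal commas are not supported)",
                    basename(files[i])))
    }
    m <- matrix(vals, nrow = length(rows), byrow = TRUE)
    if (is.null(shape)) shape <<- dim(m)
    if (!identical(dim(m), shape)) {
      abort(sprintf("frame %s has shape %dx%d, expected %dx%d",
                    basename(files[i]), nrow(m), ncol(m), shape[1], shape[2]))
    }
    m
  })
  frame_stack(frames, fps = fps)
}

# mode of continuous temperatures: most populated 0.1-degree bin centred on
# multiples of 0.1; ties resolved to the lower bin
temp_mode <- function(x, binwidth = 0.1) {
  bins <- round(x / binwidth)
  tab <- table(bins)
  as.numeric(names(tab)[which.max(tab)]) * binwidth
}

#' ROI temperature statistics
#'
#' For each frame, the maximum, mode (centre of the most populated 0.1-degree
#' bin, ties to the lower bin) and population standard deviation of the
#' temperatures inside the tracked ROI; plus the aggregate mean, maximum, mode
#' and SD of the per-frame maxima. Frames flagged invalid by tracking are
#' reported but excluded from the aggregates.
#'
#' @param stack a thermal [frame_stack()] (degrees C matrices).
#' @param track a [tracked_roi()] covering all frames.
#' @return object of class `roi_temp_stats`: list with `per_frame` (tibble
#'   `frame, max_c, mode_c, sd_c, valid`) and `aggregate` (one-row tibble
#'   `mean_of_max, max_of_max, mode_of_max, sd_of_max, n_valid`).
#' @export
roi_temperature_stats <- function(stack, track) {
  stopifnot(inherits(stack, "frame_stack"), inherits(track, "tracked_roi"))
  n <- n_frames(stack)
  if (nrow(track) != n) abort("track must cover every thermal frame")
  d <- frame_dim(stack)
  per <- purrr::map_dfr(seq_len(n), function(f) {
    box <- c(track$x[f], track$y[f], track$w[f], track$h[f])
    if (!box_valid_in(box, d[1], d[2])) abort(sprintf("roi outside frame %d", f - 1))
    px <- stack$frames[[f]][box_rows(box), box_cols(box)]
    if (!length(px)) abort("empty ROI")
    tibble(frame = f - 1L, max_c = max(px), mode_c = temp_mode(px),
           sd_c = sqrt(mean((px - mean(px))^2)), valid = track$valid[f])
  })
  mx <- per$max_c[per$valid]
  if (!length(mx)) abort("no valid frames to aggregate")
  agg <- tibble(
    mean_of_max = mean(mx), max_of_max = max(mx),
    mode_of_max = temp_mode(mx),
    sd_of_max = sqrt(mean((mx - mean(mx))^2)),
    n_valid = length(mx)
  )
  structure(list(per_frame = per, aggregate = agg), class = "roi_temp_stats")
}

#' @export
print.roi_temp_stats <- function(x, ...) {
  cat(sprintf("<roi_temp_stats: %d frames (%d valid)>\n",
              nrow(x$per_frame), x$aggregate$n_valid))
  print(x$aggregate)
  invisible(x)
}

#' @rdname tidy
#' @export
tidy.roi_temp_stats <- function(x, ...) x$per_frame

#' @rdname tidy
#' @export
glance.roi_temp_stats <- function(x, ...) x$aggregate
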