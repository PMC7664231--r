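#' Engineered signal features
#'
#' Builds the 8-value parameter vector used as neural-network input for one
#' signal: mean, minimum, maximum and standard deviation of the luminosity
#' changes (first differences of the detrended raw series), mean and SD of the
#' band-filtered series, and the dominant in-band frequency and its peak
#' amplitude. Set `diff_changes = FALSE` to compute the raw statistics on the
#' detrended series itself instead of its first differences.
#'
#' @param raw the detrended raw [channel_signal()].
#' @param filtered the band-filtered [channel_signal()] (same length and fs).
#' @param estimate the `spectral_estimate` from [dominant_frequency()].
#' @param diff_changes statistics of first differences (default) or of the
#'   series itself.
#' @return a one-row tibble with columns `raw_mean`, `raw_min`, `raw_max`,
#'   `raw_sd`, `filt_mean`, `filt_sd`, `freq`, `amp`.
#' @export
compute_features <- function(raw, filtered, estimate, diff_changes = TRUE) {
  x <- signal_values(raw)
  y <- signal_values(filtered)
  if (length(x) != length(y)) abort("raw and filtered series must have the same length")
  if (length(x) < 16) abort("need at least 16 samples to compute features")
  chg <- if (diff_changes) diff(x) else x
  tibble(
    raw_mean = mean(chg), raw_min = min(chg), raw_max = max(chg), raw_sd = sd(chg),
    filt_mean = mean(y), filt_sd = sd(y),
    freq = estimate$f_peak, amp = estimate$amplitude
  )
}

feature_cols <- c("raw_mean", "raw_min", "raw_max", "raw_sd",
                  "filt_mean", "filt_sd", "freq", "amp")

#' Min-max feature normalization to [-1, 1]
#'
#' Learns per-column minimum and maximum on the training rows only and maps
#' each column linearly to `[-1, 1]` (matching the tan-sigmoid input
#' convention). Test rows re-use the training parameters and may therefore
#' fall outside `[-1, 1]`. A constant column maps to 0 with a warning.
#'
#' `normalize_features()` applies stored parameters; `denormalize_features()`
#' inverts the map.
#'
#' @param df a data frame of numeric feature columns.
#' @param train_idx row indices to learn the parameters from (default: all).
#' @return `learn_normalization()`: a list with `min`, `max`, `columns`.
#' @export
learn_normalization <- function(df, train_idx = seq_len(nrow(df))) {
  m <- as.matrix(df)
  tr <- m[train_idx, , drop = FALSE]
  lo <- apply(tr, 2, min)
  hi <- apply(tr, 2, max)
  if (any(hi == lo)) {
    warn(sprintf("constant feature column(s) map to 0: %s",
                 paste(colnames(m)[hi == lo], collapse = ", ")))
  }
  list(min = lo, max = hi, columns = colnames(m))
}

#' @rdname learn_normalization
#' @param params parameters from [learn_normalization()].
#' @export
normalize_features <- function(df, params) {
  m <- as.matrix(df[, params$columns, drop = FALSE])
  rng <- params$max - params$min
  out <- sweep(m, 2, params$min)
  out <- sweep(out, 2, ifelse(rng == 0, 1, rng), "/") * 2 - 1
  out[, rng == 0] <- 0
  out
}

#' @rdname learn_normalization
#' @param x a normalized matrix.
#' @export
denormalize_features <- function(x, params) {
  rng <- params$max - params$min
  out <- sweep((x + 1) / 2, 2, rng, "*")
  out <- sweep(out, 2, params$min, "+")
  out[, rng == 0] <- rep(params$min[rng == 0], each = nrow(out))
  colnames(out) <- params$columns
  out
}

#' Assemble the band-classifier input matrix (n x 8)
#'
#' Stacks per-sample wide-band respiratory features and normalizes them with
#' parameters learned on the training rows only.
#'
#' @param features tibble with the 8 feature columns, one row per sample.
#' @param train_idx rows used to learn the normalization (default all).
#' @return list with `x` (normalized matrix) and `normalization` (parameters).
#' @export
assemble_model1_matrix <- function(features, train_idx = seq_len(nrow(features))) {
  stopifnot(nrow(features) >= 1)
  df <- features[, feature_cols]
  params <- learn_normalization(df, train_idx)
  list(x = normalize_features(df, params), normalization = params)
}

#' Assemble the vitals-regression input matrix (n x 16)
#'
#' Concatenates the 8 cardiac-band features (prefixed `hr_`) with the 8
#' band-specific respiratory features (prefixed `rr_`), in matched sample
#' order, then min-max normalizes on the training rows.
#'
#' @param hr_features,rr_features tibbles of 8 feature columns with equal row
#'   counts and matching sample order.
#' @param train_idx rows used to learn the normalization.
#' @return list with `x` (normalized n x 16 matrix) and `normalization`.
#' @export
assemble_model2_matrix <- function(hr_features, rr_features,
                                   train_idx = seq_len(nrow(hr_features))) {
  if (nrow(hr_features) != nrow(rr_features)) {
    abort("hr and rr feature tables must have the same number of rows (same sample order)")
  }
  df <- dplyr::bind_cols(
    stats::setNames(hr_features[, feature_cols], paste0("hr_", feature_cols)),
    stats::setNames(rr_features[, feature_cols], paste0("rr_", feature_cols))
  )
  params <- learn_normalization(df, train_idx)
  list(x = normalize_features(df, params), normalization = params)
}
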