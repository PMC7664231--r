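#' Sheep temperature-humidity index
#'
#' Computes the sheep-specific temperature-humidity index
#' `THI = T - (0.31 - 0.31 * RH) * (T - 14.4)`, where `T` is dry-bulb
#' temperature in degrees Celsius and `RH` is relative humidity as a fraction
#' in `[0, 1]`. At `T = 14.4` the index equals the temperature for any
#' humidity, and at saturation (`RH = 1`) the humidity correction vanishes.
#'
#' @param t_c dry-bulb temperature, degrees C (vectorised).
#' @param rh relative humidity as a fraction in `[0, 1]`. Values in `(1, 100]`
#'   are interpreted as percentages and divided by 100 with a warning.
#' @return numeric vector of THI values.
#' @examples
#' thi(36, 0.4) # 31.9824
#' @export
thi <- function(t_c, rh) {
  stopifnot(is.numeric(t_c), is.numeric(rh))
  if (any(rh < 0 | rh > 100, na.rm = TRUE)) {
    abort("relative humidity must be a fraction in [0, 1] (or a percentage in (1, 100])")
  }
  pct <- !is.na(rh) & rh > 1
  if (any(pct)) {
    warn("relative humidity values > 1 interpreted as percentages and divided by 100")
    rh[pct] <- rh[pct] / 100
  }
  t_c - (0.31 - 0.31 * rh) * (t_c - 14.4)
}

#' Read an environment logger CSV and compute THI
#'
#' Expects columns `timestamp`, `t_c` (degrees C) and `rh` (fraction, or
#' percent which is auto-scaled). Each record is classified against the
#' climate-chamber envelopes used in controlled heat-stress studies:
#' thermoneutral control (18-21 degrees C, 40-50% RH) and cyclic heat
#' (28-40 degrees C, 40-60% RH); anything else is `"out-of-range"`.
#' Logging gaps larger than the nominal 30-minute cadence raise a warning.
#'
#' @param path CSV file path.
#' @param expected_interval_min nominal logging interval used for the gap
#'   check, in minutes (default 30).
#' @return a tibble with columns `timestamp`, `t_c`, `rh`, `thi`, `range`.
#' @export
read_env_log <- function(path, expected_interval_min = 30) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("timestamp", "t_c", "rh")
  if (!all(need %in% names(df))) {
    abort(sprintf("environment log must have columns %s", paste(need, collapse = ", ")))
  }
  rh <- df$rh
  if (any(rh > 1, na.rm = TRUE)) rh <- rh / 100
  ts <- df$timestamp
  if (is.character(ts)) ts <- suppressWarnings(as.POSIXct(ts, tz = "UTC"))
  if (inherits(ts, "POSIXct") && !anyNA(ts)) {
    dmin <- diff(as.numeric(ts)) / 60
    if (length(dmin) && any(dmin > expected_interval_min * 2)) {
      warn("gaps larger than twice the expected logging interval found in environment log")
    }
  }
  tibble(
    timestamp = df$timestamp,
    t_c = df$t_c,
    rh = rh,
    thi = thi(df$t_c, rh),
    range = dplyr::case_when(
      df$t_c >= 18 & df$t_c <= 21 & rh >= 0.40 & rh <= 0.50 ~ "control-range",
      df$t_c >= 28 & df$t_c <= 40 & rh >= 0.40 & rh <= 0.60 ~ "heat-range",
      TRUE ~ "out-of-range"
    )
  )
}
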