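#' Through-origin linear regression with prediction-band outlier counting
#'
#' Fits `y = b * x` with no intercept (`b = sum(xy) / sum(x^2)`), and reports
#' the ordinary Pearson correlation, root-mean-squared error
#' `sqrt(sum((y - b x)^2) / n)`, and the number of points falling outside the
#' two-sided 95% (by default) t-based prediction interval of the fit. The
#' reported `r` is the centred Pearson correlation between `x` and `y`; set
#' `uncentered = TRUE` to also report the uncentred (through-origin) R-squared.
#'
#' @param x,y numeric vectors of equal length (`n >= 3`), `x` not all zero.
#' @param level prediction-interval coverage (default 0.95).
#' @param uncentered also compute the uncentred R-squared.
#' @return an object of class `to_regression`; see [tidy.to_regression()] and
#'   [glance.to_regression()].
#' @export
regress_through_origin <- function(x, y, level = 0.95, uncentered = FALSE) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) abort("need at least 3 points")
  if (all(x == 0)) abort("x is degenerate (all zero); through-origin slope undefined")
  sxx <- sum(x^2)
  slope <- sum(x * y) / sxx
  resid <- y - slope * x
  rmse <- sqrt(sum(resid^2) / n)
  r <- stats::cor(x, y)
  # residual variance of the no-intercept fit has n - 1 df
  s2 <- sum(resid^2) / (n - 1)
  tcrit <- qt(1 - (1 - level) / 2, df = n - 1)
  half <- tcrit * sqrt(s2) * sqrt(1 + x^2 / sxx)
  out <- abs(resid) > half
  structure(
    list(
      slope = slope, r = r, r2 = r^2,
      r2_uncentered = if (uncentered) 1 - sum(resid^2) / sum(y^2) else NA_real_,
      rmse = rmse, n = n,
      outlier_count = sum(out), outlier_pct = 100 * mean(out),
      level = level,
      data = tibble(x = x, y = y, fitted = slope * x,
                    residual = resid, pi_half_width = half, outlier = out)
    ),
    class = "to_regression"
  )
}

#' @export
print.to_regression <- function(x, ...) {
  cat(sprintf(
    "<through-origin regression: n = %d, slope = %.4f, R = %.4f, RMSE = %.4f, %d outliers (%.1f%%) outside the %g%% prediction band>\n",
    x$n, x$slope, x$r, x$rmse, x$outlier_count, x$outlier_pct, 100 * x$level))
  invisible(x)
}

#' Broom-style accessors for through-origin regressions
#'
#' `tidy()` returns the per-point table (observed, fitted, residual, prediction
#' band half-width, outlier flag); `glance()` returns the one-row summary.
#'
#' @param x a `to_regression` object.
#' @param ... unused.
#' @export
tidy.to_regression <- function(x, ...) x$data

#' @rdname tidy.to_regression
#' @export
glance.to_regression <- function(x, ...) {
  tibble(n = x$n, slope = x$slope, r = x$r, r2 = x$r2,
         rmse = x$rmse, outlier_count = x$outlier_count,
         outlier_pct = x$outlier_pct)
}

#' Classification report: per-stage accuracy, confusion matrix, MSE and ROC
#'
#' Builds the accuracy / error / mean-squared-error table used to report a
#' band classifier stage by stage (training / testing / overall), the
#' confusion matrix, and one-vs-rest ROC points per class obtained by sweeping
#' a threshold over the class scores.
#'
#' @param truth factor (or character) of reference labels.
#' @param labels predicted labels, same length.
#' @param scores numeric matrix (`n x n_classes`) of class scores (softmax
#'   outputs); column order must follow `levels(truth)`. MSE is computed
#'   between scores and the one-hot encoding of `truth`. Optional.
#' @param stage character vector assigning each sample to a stage (e.g.
#'   `"training"` / `"testing"`); an `"overall"` row pooling everything is
#'   always added.
#' @return an object of class `classifier_report` with elements `stages`
#'   (tibble), `confusion` (table) and `roc` (tibble of fpr/tpr per class).
#' @export
classification_report <- function(truth, labels, scores = NULL, stage = NULL) {
  truth <- factor(truth)
  lv <- levels(truth)
  labels <- factor(labels, levels = lv)
  if (any(is.na(labels))) abort("predicted labels contain classes absent from the truth")
  n <- length(truth)
  if (is.null(stage)) stage <- rep("overall", n)
  onehot <- function(f) {
    m <- matrix(0, length(f), length(lv))
    m[cbind(seq_along(f), as.integer(f))] <- 1
    m
  }
  stage_row <- function(name, idx) {
    acc <- 100 * mean(labels[idx] == truth[idx])
    mse <- if (!is.null(scores)) {
      mean((scores[idx, , drop = FALSE] - onehot(truth[idx]))^2)
    } else NA_real_
    tibble(stage = name, samples = length(idx), accuracy = acc,
           error = 100 - acc, mse = mse)
  }
  stages <- unique(stage)
  stages <- stages[stages != "overall"]
  canon <- intersect(c("training", "testing"), stages)
  stages <- c(canon, setdiff(stages, canon))
  rows <- lapply(stages, function(s) stage_row(s, which(stage == s)))
  rows <- c(rows, list(stage_row("overall", seq_len(n))))
  roc <- if (!is.null(scores)) {
    purrr::map_dfr(seq_along(lv), function(k) {
      roc_points(truth == lv[k], scores[, k]) |>
        dplyr::mutate(class = lv[k], .before = 1)
    })
  } else NULL
  structure(
    list(stages = dplyr::bind_rows(rows),
         confusion = table(truth = truth, predicted = labels),
         roc = roc),
    class = "classifier_report"
  )
}

# one-vs-rest ROC by threshold sweep; monotone with endpoints (0,0) and (1,1)
roc_points <- function(positive, score) {
  ord <- order(score, decreasing = TRUE)
  pos <- as.logical(positive)[ord]
  tp <- cumsum(pos)
  fp <- cumsum(!pos)
  tibble(
    fpr = c(0, fp / max(1, sum(!positive))),
    tpr = c(0, tp / max(1, sum(positive)))
  )
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("<classifier_report>\n")
  print(x$stages)
  cat("\nConfusion matrix:\n")
  print(x$confusion)
  invisible(x)
}

#' @rdname tidy.to_regression
#' @export
tidy.classifier_report <- function(x, ...) x$stages

#' Generic tidy/glance (broom-style)
#'
#' Thin generics so fitted objects in this package can be summarised the way
#' broom does it, without depending on broom itself.
#' @param x an object.
#' @param ... passed to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")
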