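#' Per-scene spectral features for a synthetic cohort
#'
#' Renders each scene, extracts the green and a* series, runs the cardiac-band
#' analysis on the green channel and the wide-band respiratory analysis on the
#' a* channel, and keeps the a* series for band-specific re-analysis. This is
#' the feature-engineering front end shared by training and prediction.
#'
#' @param cohort a [generate_cohort()] tibble.
#' @return list with `hr` and `rr_wide` feature tibbles (8 columns each),
#'   `raw_hr_bpm` / `raw_rr_wide_bpm` spectral estimates, `edge_peak` flags,
#'   and the retained `a_signals`.
#' @export
cohort_features <- function(cohort) {
  n <- nrow(cohort)
  hr_list <- vector("list", n); rr_list <- vector("list", n)
  a_signals <- vector("list", n)
  raw_hr <- numeric(n); raw_rr <- numeric(n); edge <- logical(n)
  hr_band <- band_spec("HR"); wide <- band_spec("RR-wide")
  for (i in seq_len(n)) {
    sig <- scene_signals(cohort$spec[[i]])
    hr_an <- analyze_band(sig$g, hr_band)
    rr_an <- analyze_band(sig$a, wide)
    hr_list[[i]] <- compute_features(sig$g, hr_an$filtered, hr_an$estimate)
    rr_list[[i]] <- compute_features(sig$a, rr_an$filtered, rr_an$estimate)
    raw_hr[i] <- to_bpm(hr_an$estimate)
    raw_rr[i] <- to_bpm(rr_an$estimate)
    edge[i] <- rr_an$estimate$edge_peak
    a_signals[[i]] <- sig$a
  }
  list(hr = dplyr::bind_rows(hr_list), rr_wide = dplyr::bind_rows(rr_list),
       raw_hr_bpm = raw_hr, raw_rr_wide_bpm = raw_rr,
       edge_peak = edge, a_signals = a_signals)
}

#' Band-specific re-analysis of an a* signal
#'
#' Re-runs the respiratory analysis restricted to the band chosen by the
#' classifier (`"low"`, `"medium"` or `"high"`), returning the 8 engineered
#' features and the raw spectral estimate. Identical to calling
#' [analyze_band()] with the corresponding [band_spec()] directly.
#'
#' @param a_signal the a*-channel [channel_signal()].
#' @param label respiration class label.
#' @return list with `features` (one-row tibble) and `estimate`.
#' @export
reanalyze <- function(a_signal, label) {
  an <- analyze_band(a_signal, rr_band_for(label))
  list(features = compute_features(a_signal, an$filtered, an$estimate),
       estimate = an$estimate)
}

band_levels <- c("low", "medium", "high")

one_hot <- function(f, levels) {
  f <- factor(f, levels = levels)
  m <- matrix(0, length(f), length(levels))
  m[cbind(seq_along(f), as.integer(f))] <- 1
  m
}

# pooled Pearson r / through-origin slope / mse over both targets
pooled_stats <- function(truth_hr, pred_hr, truth_rr, pred_rr) {
  x <- c(truth_hr, truth_rr); y <- c(pred_hr, pred_rr)
  list(r = stats::cor(x, y), slope = sum(x * y) / sum(x^2),
       mse = mean((y - x)^2), n_obs = length(x))
}

#' Train the two-stage vitals models on a cohort
#'
#' The full training pipeline: wide-band respiratory features feed a softmax
#' band classifier (10 tan-sigmoid hidden units, Bayesian-regularized
#' Levenberg-Marquardt); every scene is re-analysed in its predicted band; the
#' 16 cardiac + band-specific respiratory features then feed a linear-output
#' regression network trained against the reference heart and respiration
#' rates (standardized per target on the training rows). Samples are split
#' 70/30 at random. The returned fit carries stage-wise reports for both
#' models plus the single-wide-band raw baseline.
#'
#' @param cohort a [generate_cohort()] tibble with reference labels.
#' @param seed RNG seed driving the split and both weight initializations.
#' @param n_hidden hidden units per network (default 10).
#' @param max_epochs Levenberg-Marquardt epoch budget per network.
#' @param features optional precomputed [cohort_features()] output for this
#'   cohort (skips re-rendering the scenes).
#' @param n_restarts weight initializations tried per network; the restart
#'   with the lowest final data error is kept. Levenberg-Marquardt has
#'   init-dependent plateaus, and a handful of restarts makes training
#'   performance reproducible across seeds.
#' @return a `vitals_fit` object.
#' @export
fit_vitals_models <- function(cohort, seed = 1, n_hidden = 10, max_epochs = 300,
                              features = NULL, n_restarts = 5) {
  n <- nrow(cohort)
  if (n < 10) abort("refusing to train on fewer than 10 samples")
  feats <- features %||% cohort_features(cohort)
  split <- split_data(n, seed = seed)
  tr <- split$train_idx
  stage <- ifelse(seq_len(n) %in% tr, "training", "testing")

  train_best <- function(n_in, n_out, out_act, x, y, seed0) {
    fits <- lapply(seq_len(n_restarts), function(j) {
      net <- ffnet(n_in, n_hidden, n_out, out_act = out_act,
                   seed = seed0 + 1000L * (j - 1L))
      train_bayesian_regularization(net, x, y, max_epochs = max_epochs)
    })
    fits[[which.min(vapply(fits, function(f) f$train_state$sse_data, numeric(1)))]]
  }

  # Model 1: band classifier on wide-band respiratory features
  m1 <- assemble_model1_matrix(feats$rr_wide, tr)
  net1 <- train_best(ncol(m1$x), 3, "softmax", m1$x[tr, , drop = FALSE],
                     one_hot(cohort$band[tr], band_levels), seed + 1)
  p1 <- predict_class(net1, m1$x, levels = band_levels)

  # band-specific re-analysis under the predicted band
  re <- lapply(seq_len(n), function(i) reanalyze(feats$a_signals[[i]], as.character(p1$label[i])))
  rr_band_feats <- dplyr::bind_rows(lapply(re, `[[`, "features"))
  raw_rr_band <- vapply(re, function(r) to_bpm(r$estimate), numeric(1))

  # Model 2: vitals regression on 16 features, standardized targets
  m2 <- assemble_model2_matrix(feats$hr, rr_band_feats, tr)
  ytgt <- cbind(hr_bpm = cohort$hr_bpm, rr_brpm = cohort$rr_brpm)
  mu <- colMeans(ytgt[tr, , drop = FALSE])
  sdv <- apply(ytgt[tr, , drop = FALSE], 2, sd)
  ystd <- sweep(sweep(ytgt, 2, mu), 2, sdv, "/")
  net2 <- train_best(ncol(m2$x), 2, "linear", m2$x[tr, , drop = FALSE],
                     ystd[tr, , drop = FALSE], seed + 2)
  pred_std <- predict_values(net2, m2$x)
  pred <- sweep(sweep(pred_std, 2, sdv, "*"), 2, mu, "+")

  predictions <- tibble(
    scene_id = cohort$scene_id, stage = stage,
    band_true = cohort$band, band_pred = p1$label,
    hr_true = cohort$hr_bpm, hr_pred = pred[, 1],
    rr_true = cohort$rr_brpm, rr_pred = pred[, 2],
    raw_hr_bpm = feats$raw_hr_bpm,
    raw_rr_wide_bpm = feats$raw_rr_wide_bpm,
    raw_rr_band_bpm = raw_rr_band,
    edge_peak = feats$edge_peak
  )

  model1_report <- classification_report(cohort$band, p1$label, p1$scores, stage)
  m2_stage <- function(name, idx) {
    s <- pooled_stats(cohort$hr_bpm[idx], pred[idx, 1], cohort$rr_brpm[idx], pred[idx, 2])
    tibble(stage = name, samples = length(idx), observations = s$n_obs,
           r = s$r, slope = s$slope, mse = s$mse)
  }
  model2_report <- dplyr::bind_rows(
    m2_stage("training", tr), m2_stage("testing", split$test_idx),
    m2_stage("overall", seq_len(n))
  )
  raw_wide <- pooled_stats(cohort$hr_bpm, feats$raw_hr_bpm,
                           cohort$rr_brpm, feats$raw_rr_wide_bpm)
  raw_band <- pooled_stats(cohort$hr_bpm, feats$raw_hr_bpm,
                           cohort$rr_brpm, raw_rr_band)
  raw_report <- tibble(
    analysis = c("single-wide-band", "band-classified"),
    r = c(raw_wide$r, raw_band$r),
    slope = c(raw_wide$slope, raw_band$slope),
    mse = c(raw_wide$mse, raw_band$mse)
  )

  structure(
    list(model1 = net1, model2 = net2,
         norm1 = m1$normalization, norm2 = m2$normalization,
         target_center = mu, target_scale = sdv,
         split = split, predictions = predictions,
         model1_report = model1_report, model2_report = model2_report,
         raw_report = raw_report, seed = seed),
    class = "vitals_fit"
  )
}

#' @export
print.vitals_fit <- function(x, ...) {
  cat("<vitals_fit>\nBand classifier (Model 1):\n")
  print(x$model1_report$stages)
  cat("\nVitals regression (Model 2):\n")
  print(x$model2_report)
  cat("\nRaw spectral baseline:\n")
  print(x$raw_report)
  invisible(x)
}

#' @rdname tidy
#' @export
tidy.vitals_fit <- function(x, ...) x$predictions

#' @rdname tidy
#' @export
glance.vitals_fit <- function(x, ...) {
  s1 <- x$model1_report$stages
  s2 <- x$model2_report
  tibble(
    n = nrow(x$predictions),
    band_accuracy = s1$accuracy[s1$stage == "overall"],
    band_accuracy_training = s1$accuracy[s1$stage == "training"],
    r = s2$r[s2$stage == "overall"],
    slope = s2$slope[s2$stage == "overall"],
    raw_wide_r = x$raw_report$r[x$raw_report$analysis == "single-wide-band"]
  )
}

#' Classify the respiration band of one signal
#'
#' Applies the trained band classifier to the wide-band features of an
#' a*-channel signal.
#'
#' @param fit a [fit_vitals_models()] object (or missing-model error).
#' @param a_signal the a*-channel [channel_signal()].
#' @return list with `label` and the three softmax `scores`.
#' @export
classify_band <- function(fit, a_signal) {
  if (is.null(fit$model1)) abort("no trained band classifier; run fit_vitals_models() first")
  an <- analyze_band(a_signal, band_spec("RR-wide"))
  f <- compute_features(a_signal, an$filtered, an$estimate)
  x <- normalize_features(f, fit$norm1)
  p <- predict_class(fit$model1, x, levels = band_levels)
  list(label = as.character(p$label[1]), scores = p$scores[1, ])
}

#' Estimate vitals for one recording
#'
#' Full inference path for a pair of extracted signals: cardiac-band analysis
#' of the green series, band classification and band-specific re-analysis of
#' the a* series, then the regression network mapping the 16 features to
#' heart and respiration rate. Raw spectral estimates are reported alongside.
#'
#' @param g_signal green-channel [channel_signal()].
#' @param a_signal a*-channel [channel_signal()] of the same recording.
#' @param fit a trained [fit_vitals_models()] object.
#' @return one-row tibble: `hr_bpm`, `rr_brpm`, `band`, band scores,
#'   `raw_hr_bpm`, `raw_rr_bpm`, `edge_peak`.
#' @export
estimate_vitals <- function(g_signal, a_signal, fit) {
  if (is.null(fit$model2)) abort("no trained vitals regressor; run fit_vitals_models() first")
  hr_an <- analyze_band(g_signal, band_spec("HR"))
  hr_f <- compute_features(g_signal, hr_an$filtered, hr_an$estimate)
  cls <- classify_band(fit, a_signal)
  re <- reanalyze(a_signal, cls$label)
  df <- dplyr::bind_cols(
    stats::setNames(hr_f[, feature_cols], paste0("hr_", feature_cols)),
    stats::setNames(re$features[, feature_cols], paste0("rr_", feature_cols))
  )
  x <- normalize_features(df, fit$norm2)
  pred <- predict_values(fit$model2, x)
  pred <- sweep(sweep(pred, 2, fit$target_scale, "*"), 2, fit$target_center, "+")
  tibble(
    hr_bpm = pred[1, 1], rr_brpm = pred[1, 2],
    band = cls$label,
    score_low = cls$scores[["low"]], score_medium = cls$scores[["medium"]],
    score_high = cls$scores[["high"]],
    raw_hr_bpm = to_bpm(hr_an$estimate),
    raw_rr_bpm = to_bpm(re$estimate),
    edge_peak = re$estimate$edge_peak
  )
}

#' Persist / reload a trained vitals fit
#'
#' Writes the two trained networks plus the feature-normalization and
#' target-scaling parameters as JSON files in a directory, enough to run
#' [estimate_vitals()] and [classify_band()] after reloading. Reports and
#' per-scene predictions are not persisted.
#'
#' @param fit a [fit_vitals_models()] object.
#' @param dir directory to create/fill.
#' @export
write_vitals_fit <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ffnet(fit$model1, file.path(dir, "model1.json"))
  write_ffnet(fit$model2, file.path(dir, "model2.json"))
  jsonlite::write_json(
    list(norm1 = fit$norm1, norm2 = fit$norm2,
         target_center = as.list(fit$target_center),
         target_scale = as.list(fit$target_scale),
         seed = fit$seed),
    file.path(dir, "scaling.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname write_vitals_fit
#' @export
read_vitals_fit <- function(dir) {
  sc <- jsonlite::read_json(file.path(dir, "scaling.json"), simplifyVector = TRUE)
  fix_norm <- function(nm) list(min = unlist(nm$min), max = unlist(nm$max),
                                columns = nm$columns)
  structure(
    list(model1 = read_ffnet(file.path(dir, "model1.json")),
         model2 = read_ffnet(file.path(dir, "model2.json")),
         norm1 = fix_norm(sc$norm1), norm2 = fix_norm(sc$norm2),
         target_center = unlist(sc$target_center),
         target_scale = unlist(sc$target_scale),
         split = NULL, predictions = NULL,
         model1_report = NULL, model2_report = NULL, raw_report = NULL,
         seed = sc$seed),
    class = "vitals_fit"
  )
}
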