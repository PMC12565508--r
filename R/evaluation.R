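#' Original-scale regression metrics
#'
#' MAE, MSE, RMSE (`= sqrt(MSE)`) and the coefficient of determination
#' `R^2 = 1 - sum((pred - truth)^2) / sum((truth - mean(truth))^2)`, all on
#' the original mL scale. A constant truth vector makes `R^2` undefined; it
#' is reported as `NA` with `r2_defined = FALSE` rather than propagating a
#' division by zero.
#'
#' @param truth,pred Equal-length numeric vectors (mL), length >= 2.
#' @return Object of class `metric_report`: `mae`, `mse`, `rmse`, `r2`,
#'   `r2_defined`, `n`.
#' @export
regression_metrics <- function(truth, pred) {
  stopifnot(length(truth) == length(pred), length(truth) >= 2)
  err <- pred - truth
  mse <- mean(err^2)
  ss_tot <- sum((truth - mean(truth))^2)
  r2_defined <- ss_tot > 0
  structure(list(mae = mean(abs(err)), mse = mse, rmse = sqrt(mse),
                 r2 = if (r2_defined) 1 - sum(err^2) / ss_tot else NA_real_,
                 r2_defined = r2_defined, n = length(truth)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("n=%d  MAE=%.3f  MSE=%.3f  RMSE=%.3f  R2=%s\n", x$n, x$mae,
              x$mse, x$rmse,
              if (x$r2_defined) sprintf("%.4f", x$r2) else "undefined"))
  invisible(x)
}

#' Geometric-proxy volume baseline
#'
#' Evaluates the four closed-form proxies (three ellipsoid variants and the
#' mean-diameter sphere) as direct volume predictors and labels the one with
#' the lowest MSE on the supplied evaluation set as the best proxy.
#'
#' @param features Feature data.frame containing the proxy columns (built by
#'   [build_feature_table()]) — or a dimension data.frame, which is
#'   featurised first.
#' @param volume_ml Ground-truth volumes; taken from the table if absent.
#' @return List with `per_proxy` (named [regression_metrics()] reports),
#'   `best_proxy` (label), and `predictions` (the best proxy's mL vector).
#' @export
geometric_baseline <- function(features, volume_ml = features$volume_ml) {
  if (!all(c("v_ellip_avg", "v_sphere") %in% names(features)))
    features <- build_feature_table(features)
  if (is.null(volume_ml)) volume_ml <- features$volume_ml
  stopifnot(!is.null(volume_ml))
  proxies <- c("v_ellip_avg", "v_ellip_sw", "v_ellip_sh", "v_sphere")
  reports <- lapply(proxies, function(p) regression_metrics(volume_ml, features[[p]]))
  names(reports) <- proxies
  best <- proxies[which.min(vapply(reports, `[[`, numeric(1), "mse"))]
  list(per_proxy = reports, best_proxy = best, predictions = features[[best]])
}

# Ordinary least squares on the same transformed + selected features as the
# ensemble (fitted per training fold; isolates the model-family effect).
.fit_linear <- function(x, volume_ml, seed) {
  tf <- .fit_transforms(x, volume_ml, seed = seed, select = TRUE)
  dat <- tf$x_sel
  dat$.y <- tf$y_log
  fit <- stats::lm(.y ~ ., data = dat)
  structure(list(caps = tf$caps, selection = tf$selection, fit = fit),
            class = "linear_baseline")
}

.predict_linear <- function(object, newdata) {
  pipeline <- list(caps = object$caps, selection = object$selection)
  xf <- .apply_transforms(pipeline, newdata)
  pmax(inverse_transform_target(as.numeric(predict(object$fit, xf))), 0)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired error vectors. Zero differences are
#' dropped; ranks of tied absolute differences are averaged. The null
#' distribution is exact (computed by convolution over the 2^n sign
#' assignments, which handles tied ranks) for up to 25 non-zero differences,
#' and a normal approximation with tie correction beyond that.
#'
#' @param errors_a,errors_b Paired numeric vectors (e.g. per-sample
#'   out-of-fold absolute errors of two models), length >= 5.
#' @return List with `statistic` (V, sum of positive-difference ranks),
#'   `p_value`, `n_nonzero`, `method`, `degenerate`.
#' @export
wilcoxon_compare <- function(errors_a, errors_b) {
  stopifnot(length(errors_a) == length(errors_b), length(errors_a) >= 5)
  d <- errors_a - errors_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(statistic = NA_real_, p_value = NA_real_, n_nonzero = 0L,
                method = "degenerate", degenerate = TRUE))
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= 25) {
    # exact distribution of 2*V over sign patterns via convolution;
    # doubling keeps tied (half-integer) average ranks integral
    r2 <- as.integer(round(2 * r))
    dist <- c(1, rep(0, sum(r2)))
    for (ri in r2) {
      shifted <- c(rep(0, ri), dist[seq_len(length(dist) - ri)])
      dist <- dist + shifted
    }
    dist <- dist / 2^n
    v2 <- as.integer(round(2 * V))
    p_le <- sum(dist[seq_len(v2 + 1)])
    p_ge <- sum(dist[(v2 + 1):length(dist)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    ties <- table(r)
    mu <- n * (n + 1) / 4
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (V - mu) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal-approximation"
  }
  list(statistic = V, p_value = p, n_nonzero = as.integer(n),
       method = method, degenerate = FALSE)
}

#' Residual summary
#'
#' Residuals `truth - pred` on the mL scale: mean, SD, quartiles, moment
#' skewness and the box-plot five-number summary, serialisable for plotting.
#'
#' @param truth,pred Paired numeric vectors (mL).
#' @return List with `mean`, `sd`, `quartiles`, `skewness`, `boxplot`
#'   (fivenum), `residuals`.
#' @export
residual_summary <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  res <- truth - pred
  s <- stats::sd(res)
  skew <- if (isTRUE(s > 0)) mean((res - mean(res))^3) / s^3 else 0
  list(mean = mean(res), sd = s,
       quartiles = stats::quantile(res, c(0.25, 0.5, 0.75), names = FALSE),
       skewness = skew, boxplot = stats::fivenum(res), residuals = res)
}

#' Multi-model comparison study
#'
#' Evaluates the full roster — best geometric proxy, ordinary linear
#' regression on the selected transformed features, the three boosted base
#' learners, and the stacked ensemble — under one shared quantile-stratified
#' k-fold split. Every trainable model is refit from scratch inside each
#' fold (transforms, selection and tuning included), predictions are pooled
#' out-of-fold, and metrics are computed on the original mL scale. A paired
#' Wilcoxon signed-rank test compares per-sample absolute errors of the
#' stack against the best single base learner.
#'
#' @param features Feature data.frame (25 canonical columns + `volume_ml`).
#' @param k,bins Fold count and quantile strata for the shared split.
#' @param seed Integer seed.
#' @param tune Run the exhaustive hyperparameter grids inside each fold
#'   (exhaustive; slow). With `FALSE` the family default parameter sets are
#'   used.
#' @param spec A [stack_spec()] for the ensemble rows.
#' @return Object of class `comparison_report`: `metrics` (data.frame, one
#'   row per model), `reports`, `predictions` (matrix of out-of-fold mL
#'   predictions), `wilcoxon` (stack vs best single), `folds`, `fold_signature`.
#' @export
compare_models <- function(features, k = 5, bins = 5, seed = 1L, tune = FALSE,
                           spec = stack_spec()) {
  stopifnot("volume_ml" %in% names(features))
  y <- features$volume_ml
  x <- features[feature_names()]
  folds <- stratified_folds(y, k = k, bins = bins, seed = seed)
  sig <- paste(folds$fold, collapse = ",")
  model_names <- c("best_geometric_proxy", "linear_regression",
                   "classic_gbrt", "regularised_depthwise_gbrt",
                   "histogram_leafwise_gbrt", "stack")
  preds <- matrix(NA_real_, length(y), length(model_names),
                  dimnames = list(NULL, model_names))
  fold_sigs <- stats::setNames(rep(sig, length(model_names)), model_names)
  proxy <- geometric_baseline(features, y)
  preds[, "best_geometric_proxy"] <- proxy$predictions
  for (f in seq_len(k)) {
    tr <- folds$fold != f
    xtr <- x[tr, , drop = FALSE]; ytr <- y[tr]
    xte <- x[!tr, , drop = FALSE]
    lin <- .fit_linear(xtr, ytr, seed = seed)
    preds[!tr, "linear_regression"] <- .predict_linear(lin, xte)
    for (bs in spec$bases) {
      single <- fit_single_learner(xtr, ytr, bs, seed = seed, tune = tune)
      preds[!tr, bs$family] <- predict_volume(single, xte)
    }
    stk <- fit_stack(xtr, ytr, spec = spec, seed = seed, tune = tune)
    preds[!tr, "stack"] <- predict_volume(stk, xte)
  }
  if (length(unique(fold_sigs)) != 1)
    stop("contract error: models evaluated on differing fold assignments",
         call. = FALSE)
  reports <- lapply(model_names, function(m) {
    rep <- regression_metrics(y, preds[, m])
    rep$per_fold <- vapply(seq_len(k), function(f)
      mean((preds[folds$fold == f, m] - y[folds$fold == f])^2), numeric(1))
    rep
  })
  names(reports) <- model_names
  singles <- c("classic_gbrt", "regularised_depthwise_gbrt",
               "histogram_leafwise_gbrt")
  best_single <- singles[which.min(vapply(reports[singles], `[[`, numeric(1), "mse"))]
  wil <- wilcoxon_compare(abs(preds[, "stack"] - y), abs(preds[, best_single] - y))
  metrics <- data.frame(
    model = model_names,
    mae = vapply(reports, `[[`, numeric(1), "mae"),
    mse = vapply(reports, `[[`, numeric(1), "mse"),
    rmse = vapply(reports, `[[`, numeric(1), "rmse"),
    r2 = vapply(reports, `[[`, numeric(1), "r2"),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(metrics = metrics, reports = reports, predictions = preds,
                 best_single = best_single, best_proxy = proxy$best_proxy,
                 wilcoxon = wil, folds = folds, fold_signature = sig,
                 seed = as.integer(seed)),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Model performance comparison (", x$folds$k, "-fold cross-validation)\n",
      sep = "")
  m <- x$metrics
  m[-1] <- lapply(m[-1], function(v) round(v, 3))
  print(m, row.names = FALSE)
  cat(sprintf("best proxy: %s; best single: %s; Wilcoxon stack vs best single: V=%.1f, p=%.4g\n",
              x$best_proxy, x$best_single, x$wilcoxon$statistic, x$wilcoxon$p_value))
  invisible(x)
}
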