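#' Hyperparameter grids for the base-learner families
#'
#' The two tuned families carry their full factorial search spaces: the
#' classic GBRT family (trees 200/400, learning rate 0.05/0.1, depth 4/5,
#' subsample 0.8/0.9, per-split column sampling sqrt/log2 of the feature
#' count: 32 candidates) and the regularised depth-wise family (trees
#' 200/400, learning rate 0.01/0.05/0.1, depth 4/5/6, subsample 0.8/0.9,
#' per-tree column sampling 0.8/0.9: 72 candidates). The histogram leaf-wise
#' family is deliberately untuned and runs with fixed defaults (200 trees,
#' learning rate 0.1, 31 leaves, loss-guided growth, minimum leaf occupancy
#' 5 — the family's reference occupancy of 20 assumes thousands of rows and
#' underfits 120-row training folds).
#'
#' @param family One of `"classic_gbrt"`, `"regularised_depthwise_gbrt"`,
#'   `"histogram_leafwise_gbrt"`.
#' @return Named list of value vectors (a grid), or a single-row grid for the
#'   untuned family.
#' @export
default_grid <- function(family = c("classic_gbrt", "regularised_depthwise_gbrt",
                                    "histogram_leafwise_gbrt")) {
  family <- match.arg(family)
  switch(family,
    classic_gbrt = list(
      n_estimators = c(200, 400), learning_rate = c(0.05, 0.1),
      max_depth = c(4, 5), subsample = c(0.8, 0.9),
      max_features = c("sqrt", "log2")),
    regularised_depthwise_gbrt = list(
      n_estimators = c(200, 400), learning_rate = c(0.01, 0.05, 0.1),
      max_depth = c(4, 5, 6), subsample = c(0.8, 0.9),
      colsample_bytree = c(0.8, 0.9)),
    histogram_leafwise_gbrt = list(
      n_estimators = 200, learning_rate = 0.1, max_leaves = 31,
      min_child_weight = 5))
}

#' A reduced single-point grid (family defaults) for fast refits
#'
#' Mid-grid values used when a caller opts out of the exhaustive search.
#' @inheritParams default_grid
#' @return Named list of scalar hyperparameters.
#' @export
default_params <- function(family = c("classic_gbrt", "regularised_depthwise_gbrt",
                                      "histogram_leafwise_gbrt")) {
  family <- match.arg(family)
  switch(family,
    classic_gbrt = list(n_estimators = 400, learning_rate = 0.05, max_depth = 4,
                        subsample = 0.9, max_features = "sqrt"),
    regularised_depthwise_gbrt = list(n_estimators = 400, learning_rate = 0.05,
                                      max_depth = 4, subsample = 0.9,
                                      colsample_bytree = 0.9),
    histogram_leafwise_gbrt = list(n_estimators = 200, learning_rate = 0.1,
                                   max_leaves = 31, min_child_weight = 5))
}

#' Base-learner specification
#'
#' One member of the ensemble roster: a gradient-boosted tree family, its
#' hyperparameter grid (or a fixed parameter set), and whether monotone
#' constraints on the primary axes are applied.
#'
#' @inheritParams default_grid
#' @param grid Hyperparameter grid; defaults to the full factorial search space.
#' @param params Optional fixed hyperparameters (skips tuning).
#' @param monotone Apply non-decreasing constraints on the raw dimensions and
#'   mean diameter (all three families support per-feature constraints).
#' @return Object of class `base_learner_spec`.
#' @export
base_learner_spec <- function(family, grid = default_grid(family), params = NULL,
                              monotone = TRUE) {
  family <- match.arg(family, c("classic_gbrt", "regularised_depthwise_gbrt",
                                "histogram_leafwise_gbrt"))
  if (length(grid) == 0) stop("empty hyperparameter grid", call. = FALSE)
  structure(list(family = family, grid = grid, params = params,
                 monotone = isTRUE(monotone)),
            class = "base_learner_spec")
}

#' Monotonicity-constraint vector for a feature set
#'
#' Non-decreasing (+1) constraints on the four raw dimensions and the mean
#' diameter (predicted volume must not decrease when a fruit gets larger);
#' zero elsewhere. Errors on unknown constrained names.
#'
#' @param features Character vector of model feature names, in column order.
#' @param constrained Names to constrain (default the five size features).
#' @return Named integer vector aligned with `features`.
#' @export
apply_monotone_constraints <- function(features,
                                       constrained = c("w_top", "h_top", "w_side",
                                                       "h_side", "d_mean")) {
  unknown <- setdiff(constrained, feature_names())
  if (length(unknown))
    stop("config error: unknown constrained feature(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  v <- integer(length(features))
  names(v) <- features
  v[features %in% constrained] <- 1L
  v
}

# Map a family + hyperparameter set to xgboost params. All families run on
# the histogram tree builder (xgboost rejects per-node column sampling under
# the exact builder); the families differ in growth policy and sampling.
.xgb_params <- function(family, hp, n_features, monotone_vec = NULL, seed = 0L) {
  p <- list(objective = "reg:squarederror", nthread = 1, seed = as.integer(seed),
            eta = hp$learning_rate, tree_method = "hist")
  if (family == "classic_gbrt") {
    p$max_depth <- hp$max_depth
    p$subsample <- hp$subsample
    frac <- switch(hp$max_features,
                   sqrt = sqrt(n_features) / n_features,
                   log2 = log2(n_features) / n_features,
                   as.numeric(hp$max_features))
    p$colsample_bynode <- min(1, max(frac, 1 / n_features))
  } else if (family == "regularised_depthwise_gbrt") {
    p$max_depth <- hp$max_depth
    p$subsample <- hp$subsample
    p$colsample_bytree <- hp$colsample_bytree
    p$lambda <- 1 # L2 regularisation on leaf weights
  } else { # histogram_leafwise_gbrt
    p$grow_policy <- "lossguide"
    p$max_depth <- 0
    p$max_leaves <- hp$max_leaves
    # minimum leaf occupancy; for squared error the hessian sum equals the
    # sample count
    p$min_child_weight <- hp$min_child_weight %||% 5
  }
  if (!is.null(monotone_vec)) p$monotone_constraints <- as.integer(monotone_vec)
  p
}

# Fit one base learner on a numeric matrix (log-scale target).
.fit_base <- function(family, hp, x, y, monotone_vec = NULL, seed = 0L) {
  dtr <- xgboost::xgb.DMatrix(as.matrix(x), label = y, nthread = 1)
  params <- .xgb_params(family, hp, ncol(x), monotone_vec, seed)
  xgboost::xgb.train(params = params, data = dtr, nrounds = hp$n_estimators,
                     verbose = 0)
}

.predict_base <- function(model, x) {
  predict(model, as.matrix(x))
}

# Expand a grid (list of vectors) into a list of hyperparameter sets ordered
# simplest-first: fewer trees, then shallower, then lower learning rate.
.expand_candidates <- function(grid) {
  gdf <- expand.grid(grid, stringsAsFactors = FALSE)
  ord_cols <- intersect(c("n_estimators", "max_depth", "learning_rate"), names(gdf))
  gdf <- gdf[do.call(order, gdf[ord_cols]), , drop = FALSE]
  lapply(seq_len(nrow(gdf)), function(i) as.list(gdf[i, , drop = FALSE]))
}

#' Exhaustive grid search for a base learner
#'
#' Scores every candidate in the spec's grid by mean k-fold cross-validated
#' MSE on the log-scale target and returns the spec frozen at the best
#' candidate. Candidates are visited simplest-first (fewer trees, then
#' shallower, then lower learning rate) so exact score ties resolve to the
#' simpler model.
#'
#' @param spec A [base_learner_spec()].
#' @param x Numeric feature matrix / data.frame (training rows).
#' @param y Log-scale target vector.
#' @param folds A [stratified_folds()] assignment over `y` (built with
#'   defaults if omitted).
#' @param seed Seed forwarded to the learner.
#' @return The spec with `$params` (best set), `$cv_mse`, and
#'   `$n_candidates` filled in.
#' @export
tune_base_learner <- function(spec, x, y, folds = NULL, seed = 0L) {
  stopifnot(inherits(spec, "base_learner_spec"))
  if (stats::var(y) == 0) stop("tuning error: constant target", call. = FALSE)
  if (is.null(folds)) folds <- stratified_folds(y, k = 5, bins = 5, seed = seed)
  cands <- .expand_candidates(spec$grid)
  mono <- if (spec$monotone) apply_monotone_constraints(colnames(x)) else NULL
  x <- as.matrix(x)
  scores <- vapply(cands, function(hp) {
    errs <- vapply(seq_len(folds$k), function(f) {
      tr <- folds$fold != f
      m <- .fit_base(spec$family, hp, x[tr, , drop = FALSE], y[tr], mono, seed)
      mean((.predict_base(m, x[!tr, , drop = FALSE]) - y[!tr])^2)
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  best <- which.min(scores)
  spec$params <- cands[[best]]
  spec$cv_mse <- scores[best]
  spec$n_candidates <- length(cands)
  spec
}

# Total split gain per feature, parsed from the booster's text dump and
# normalised to sum to one (features the booster never used score 0).
.gain_importance <- function(model, features) {
  dump <- xgboost::xgb.dump(model, with_stats = TRUE)
  splits <- grep("gain=", dump, fixed = TRUE, value = TRUE)
  imp <- stats::setNames(numeric(length(features)), features)
  if (length(splits)) {
    feat <- sub(".*\\[([^<]+)<.*", "\\1", splits)
    gain <- as.numeric(sub(".*gain=([-0-9.eE+]+).*", "\\1", splits))
    agg <- tapply(gain, feat, sum)
    agg <- agg[names(agg) %in% features]
    imp[names(agg)] <- agg
    if (sum(imp) > 0) imp <- imp / sum(imp)
  }
  imp
}

#' Embedded median-importance feature selection
#'
#' Fits a gradient-boosted importance model on the current training rows
#' only, ranks features by total gain, and retains those whose importance
#' strictly exceeds the median importance of all features (features the
#' booster never split on count as zero importance). With distinct
#' importances over 25 features this keeps at most 12; ties at the median
#' are excluded.
#'
#' @param x Feature matrix / data.frame (training rows).
#' @param y Log-scale target.
#' @param seed Seed for the importance model.
#' @param params Hyperparameters for the importance model (defaults to the
#'   regularised depth-wise family defaults).
#' @return Object of class `selection_result`: `importances` (named, all
#'   features), `threshold`, `selected` (ordered subset of column names).
#' @export
select_features <- function(x, y, seed = 0L,
                            params = default_params("regularised_depthwise_gbrt")) {
  x <- as.matrix(x)
  m <- .fit_base("regularised_depthwise_gbrt", params, x, y,
                 monotone_vec = NULL, seed = seed)
  imp <- .gain_importance(m, colnames(x))
  if (all(imp == 0)) stop("selection error: all importances are zero", call. = FALSE)
  thr <- stats::median(imp)
  sel <- names(imp)[imp > thr]
  structure(list(importances = imp, threshold = thr,
                 selected = colnames(x)[colnames(x) %in% sel]),
            class = "selection_result")
}

#' Stacked-ensemble specification
#'
#' Roster of three complementary boosted base learners plus an L1-penalised
#' linear meta-learner that combines their out-of-fold predictions. The
#' meta-learner's combination weights are constrained non-negative: the base
#' predictions are strongly collinear, and unconstrained weights estimated
#' from 150 out-of-fold values are unstable in sign without any plausible
#' interpretation for a negative vote.
#'
#' @param bases List of three [base_learner_spec()] objects.
#' @param lambda_grid Log-spaced Lasso penalty grid searched by internal CV.
#' @param k_meta Folds used both for the out-of-fold meta-features and the
#'   internal penalty CV (default 10; finer folds give the meta-learner
#'   training rows that better resemble final-model predictions).
#' @return Object of class `stack_spec`.
#' @export
stack_spec <- function(bases = list(
                         base_learner_spec("classic_gbrt",
                                           params = default_params("classic_gbrt")),
                         base_learner_spec("regularised_depthwise_gbrt",
                                           params = default_params("regularised_depthwise_gbrt")),
                         base_learner_spec("histogram_leafwise_gbrt",
                                           params = default_params("histogram_leafwise_gbrt"))),
                       lambda_grid = 10^seq(0, -4, length.out = 25),
                       k_meta = 10) {
  stopifnot(length(bases) >= 1,
            all(vapply(bases, inherits, logical(1), "base_learner_spec")))
  structure(list(bases = bases, lambda_grid = lambda_grid,
                 k_meta = as.integer(k_meta)),
            class = "stack_spec")
}

# Shared transform-fitting step: caps on features + target, log features,
# log1p target, embedded selection. Training rows only.
.fit_transforms <- function(x, volume_ml, seed, select = TRUE) {
  stopifnot(is.data.frame(x))
  full <- x
  full$volume_ml <- volume_ml
  caps <- suppressWarnings(fit_iqr_caps(full))
  capped <- apply_caps(full, caps)
  y_log <- transform_target(capped$volume_ml)
  x_t <- winsorize_log_features(capped[setdiff(names(capped), "volume_ml")])
  selection <- if (select) select_features(x_t, y_log, seed = seed)
               else structure(list(importances = NULL, threshold = NA_real_,
                                   selected = names(x_t)),
                              class = "selection_result")
  list(caps = caps, selection = selection,
       x_sel = x_t[selection$selected], y_log = y_log)
}

# Transform new feature data with frozen artifacts (predictions: the target
# is never capped and never transformed here).
.apply_transforms <- function(pipeline, newdata) {
  if (inherits(newdata, "fruit_dimensions"))
    newdata <- build_feature_table(dimension_table(list(newdata)))
  stopifnot(is.data.frame(newdata))
  miss <- setdiff(feature_names(), names(newdata))
  if (length(miss))
    stop("prediction error: missing feature column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  xf <- newdata[feature_names()] # schema-keyed: order by name, ignore extras
  feat_caps <- pipeline$caps
  feat_caps$bounds <- feat_caps$bounds[names(feat_caps$bounds) != "volume_ml"]
  xf <- apply_caps(xf, feat_caps)
  xf <- winsorize_log_features(xf)
  xf[pipeline$selection$selected]
}

#' Fit the two-layer stacked ensemble
#'
#' Full training procedure on one training set: IQR capping of features and
#' target, log transforms, embedded median-importance feature selection, then
#' (i) out-of-fold predictions of every base learner over `k_meta`
#' quantile-stratified folds, (ii) a Lasso meta-learner fitted to those
#' out-of-fold meta-features (penalty chosen by internal cross-validation
#' over `lambda_grid`), and (iii) a final refit of each base on the full
#' training set. The meta-feature for any training row is always produced by
#' base models whose training fold excluded that row.
#'
#' @param x Data.frame with the 25 canonical feature columns.
#' @param volume_ml Ground-truth volumes (mL).
#' @param spec A [stack_spec()].
#' @param seed Integer seed controlling folds and learners.
#' @param tune Run the exhaustive grid search per base (families with fixed
#'   `params` and the untuned leaf-wise family are refit as-is when `FALSE`).
#' @param select Run embedded feature selection (`TRUE`).
#' @return Object of class `fitted_pipeline`.
#' @export
fit_stack <- function(x, volume_ml, spec = stack_spec(), seed = 1L,
                      tune = FALSE, select = TRUE) {
  tf <- .fit_transforms(x, volume_ml, seed = seed, select = select)
  x_sel <- as.matrix(tf$x_sel); y_log <- tf$y_log
  folds <- stratified_folds(y_log, k = spec$k_meta, bins = spec$k_meta, seed = seed)
  bases <- lapply(spec$bases, function(bs) {
    if (tune && bs$family != "histogram_leafwise_gbrt") {
      bs <- tune_base_learner(bs, x_sel, y_log, folds = folds, seed = seed)
    } else if (is.null(bs$params)) {
      bs$params <- default_params(bs$family)
    }
    bs
  })
  names(bases) <- vapply(bases, `[[`, character(1), "family")
  mono <- apply_monotone_constraints(colnames(x_sel))
  oof <- matrix(NA_real_, nrow(x_sel), length(bases),
                dimnames = list(NULL, names(bases)))
  for (f in seq_len(folds$k)) {
    tr <- folds$fold != f
    for (b in names(bases)) {
      m <- .fit_base(bases[[b]]$family, bases[[b]]$params,
                     x_sel[tr, , drop = FALSE], y_log[tr],
                     if (bases[[b]]$monotone) mono else NULL, seed)
      oof[!tr, b] <- .predict_base(m, x_sel[!tr, , drop = FALSE])
    }
  }
  stopifnot(!anyNA(oof))
  meta_cv <- glmnet::cv.glmnet(oof, y_log, alpha = 1, lambda = spec$lambda_grid,
                               foldid = folds$fold, standardize = TRUE,
                               lower.limits = 0)
  meta <- glmnet::glmnet(oof, y_log, alpha = 1, lambda = spec$lambda_grid,
                         standardize = TRUE, lower.limits = 0)
  models <- lapply(bases, function(bs)
    .fit_base(bs$family, bs$params, x_sel, y_log,
              if (bs$monotone) mono else NULL, seed))
  oof_stack <- as.numeric(predict(meta, oof, s = meta_cv$lambda.min))
  fold_record <- data.frame(fold = folds$fold,
                            y_log = y_log, volume_ml = volume_ml,
                            oof, oof_stack = oof_stack,
                            check.names = FALSE)
  structure(list(caps = tf$caps, selection = tf$selection,
                 bases = bases, models = models,
                 meta = meta, meta_lambda = meta_cv$lambda.min,
                 meta_coef = stats::setNames(
                   as.numeric(stats::coef(meta, s = meta_cv$lambda.min)),
                   rownames(stats::coef(meta, s = meta_cv$lambda.min))),
                 folds = folds, fold_record = fold_record,
                 feature_names = colnames(x_sel), seed = as.integer(seed)),
            class = "fitted_pipeline")
}

#' @export
print.fitted_pipeline <- function(x, ...) {
  cat("fitted_pipeline (stacked ensemble)\n")
  cat("  bases:", paste(names(x$bases), collapse = ", "), "\n")
  cat("  selected features:", length(x$feature_names), "of 25:",
      paste(x$feature_names, collapse = ", "), "\n")
  cat(sprintf("  meta: Lasso, lambda=%.4g; coefficients: %s\n", x$meta_lambda,
              paste(sprintf("%s=%.3f", names(x$meta_coef), x$meta_coef),
                    collapse = ", ")))
  invisible(x)
}

#' Fit a single boosted learner through the same pipeline
#'
#' Same transforms and embedded selection as [fit_stack()], but a single base
#' learner and no meta-layer; used for the single-model rows of the
#' comparison study.
#'
#' @inheritParams fit_stack
#' @param spec A [base_learner_spec()].
#' @return Object of class `fitted_pipeline` (with a single base and no meta).
#' @export
fit_single_learner <- function(x, volume_ml, spec, seed = 1L, tune = FALSE,
                               select = TRUE) {
  stopifnot(inherits(spec, "base_learner_spec"))
  tf <- .fit_transforms(x, volume_ml, seed = seed, select = select)
  x_sel <- as.matrix(tf$x_sel); y_log <- tf$y_log
  if (tune && spec$family != "histogram_leafwise_gbrt") {
    folds <- stratified_folds(y_log, k = 5, bins = 5, seed = seed)
    spec <- tune_base_learner(spec, x_sel, y_log, folds = folds, seed = seed)
  } else if (is.null(spec$params)) {
    spec$params <- default_params(spec$family)
  }
  mono <- apply_monotone_constraints(colnames(x_sel))
  model <- .fit_base(spec$family, spec$params, x_sel, y_log,
                     if (spec$monotone) mono else NULL, seed)
  structure(list(caps = tf$caps, selection = tf$selection,
                 bases = stats::setNames(list(spec), spec$family),
                 models = stats::setNames(list(model), spec$family),
                 meta = NULL, meta_lambda = NA_real_, meta_coef = NULL,
                 folds = NULL, fold_record = NULL,
                 feature_names = colnames(x_sel), seed = as.integer(seed)),
            class = "fitted_pipeline")
}

#' Predict fruit volume with a fitted pipeline
#'
#' Applies the frozen transforms and feature selection, runs the base
#' learners, combines with the Lasso meta-learner (single-learner pipelines
#' skip this step), and inverts the log-target transform. Output is clamped
#' at zero with a warning should a log-scale prediction fall below
#' `log(1 + 0)`.
#'
#' @param pipeline A `fitted_pipeline` from [fit_stack()] or
#'   [fit_single_learner()].
#' @param newdata Feature data.frame (canonical 25 columns, any order, extra
#'   columns ignored) or a single [fruit_dimensions()].
#' @return Numeric vector of predicted volumes (mL).
#' @export
predict_volume <- function(pipeline, newdata) {
  stopifnot(inherits(pipeline, "fitted_pipeline"))
  x_sel <- as.matrix(.apply_transforms(pipeline, newdata))
  base_pred <- vapply(pipeline$models, .predict_base, numeric(nrow(x_sel)),
                      x = x_sel)
  if (nrow(x_sel) == 1) base_pred <- matrix(base_pred, 1,
                                            dimnames = list(NULL, names(pipeline$models)))
  y_hat <- if (is.null(pipeline$meta_coef)) base_pred[, 1]
           else as.numeric(pipeline$meta_coef[1] +
                             base_pred[, names(pipeline$models), drop = FALSE] %*%
                             pipeline$meta_coef[-1])
  out <- inverse_transform_target(y_hat)
  if (any(out < 0)) {
    warning("negative predicted volume clamped to 0", call. = FALSE)
    out <- pmax(out, 0)
  }
  out
}
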