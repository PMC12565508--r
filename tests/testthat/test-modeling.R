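# Small deterministic regression problem used across modeling tests: the
# noiseless pure-ellipsoid population, where volume is an exact function of
# the dimensions.
local_small_features <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_dataset(noiseless_ellipsoid_config(n = 80, seed = 13))$features
    cache
  }
})

test_that("default grids enumerate to 32 and 72 candidates", {
  expect_length(fruitvol:::.expand_candidates(default_grid("classic_gbrt")), 32)
  expect_length(fruitvol:::.expand_candidates(
    default_grid("regularised_depthwise_gbrt")), 72)
  expect_length(fruitvol:::.expand_candidates(
    default_grid("histogram_leafwise_gbrt")), 1)
})

test_that("grid search returns a grid member, honours singletons and ties", {
  ft <- local_small_features()
  x <- as.matrix(winsorize_log_features(ft[feature_names()]))
  y <- transform_target(ft$volume_ml)
  single <- base_learner_spec("classic_gbrt",
                              grid = list(n_estimators = 50, learning_rate = 0.1,
                                          max_depth = 3, subsample = 1,
                                          max_features = "sqrt"))
  tuned <- tune_base_learner(single, x, y, seed = 1)
  expect_equal(tuned$params$n_estimators, 50)
  expect_equal(tuned$n_candidates, 1)
  small_grid <- list(n_estimators = c(50, 100), learning_rate = 0.1,
                     max_depth = c(3, 4), subsample = 1, max_features = "sqrt")
  tuned2 <- tune_base_learner(base_learner_spec("classic_gbrt", grid = small_grid),
                              x, y, seed = 1)
  expect_true(tuned2$params$n_estimators %in% c(50, 100))
  expect_true(tuned2$params$max_depth %in% c(3, 4))
  expect_true(is.finite(tuned2$cv_mse))
  expect_error(tune_base_learner(single, x, rep(1, nrow(x))), "constant target")
})

test_that("median-importance selection keeps at most 12 of 25 and finds signal", {
  ft <- local_small_features()
  x <- winsorize_log_features(ft[feature_names()])
  y <- transform_target(ft$volume_ml)
  sel <- select_features(x, y, seed = 1)
  expect_s3_class(sel, "selection_result")
  expect_lte(length(sel$selected), 12)
  expect_identical(sel$selected, names(sel$importances)[sel$importances > sel$threshold])
  # identifiability: a feature equal to the target among pure noise columns
  hits <- 0
  for (s in 1:20) {
    withr::with_seed(s, {
      n <- 80
      noise <- as.data.frame(matrix(rnorm(n * 24), n))
      names(noise) <- paste0("noise_", 1:24)
      target <- runif(n, 4, 6)
      dat <- cbind(signal = target, noise)
      sel_s <- select_features(dat, target, seed = s)
      if ("signal" %in% sel_s$selected) hits <- hits + 1
    })
  }
  expect_gte(hits, 19)
})

test_that("monotone constraint vectors mark the five size features", {
  v <- apply_monotone_constraints(feature_names())
  expect_equal(sum(v), 5)
  expect_equal(unname(v[c("w_top", "h_top", "w_side", "h_side", "d_mean")]),
               rep(1L, 5))
  expect_equal(unname(v[["ar_top"]]), 0L)
  sel <- c("w_side", "v_ellip_avg", "e_side")
  expect_equal(unname(apply_monotone_constraints(sel)), c(1L, 0L, 0L))
  expect_error(apply_monotone_constraints(feature_names(), constrained = "bogus"),
               "config error")
})

test_that("stack fitting is deterministic and keeps meta-features out-of-fold", {
  ft <- local_small_features()
  x <- ft[feature_names()]; y <- ft$volume_ml
  p1 <- fit_stack(x, y, seed = 7)
  p2 <- fit_stack(x, y, seed = 7)
  expect_identical(p1$fold_record, p2$fold_record)
  expect_identical(p1$meta_coef, p2$meta_coef)
  expect_identical(predict_volume(p1, x), predict_volume(p2, x))
  # structural out-of-fold purity: recompute one fold's meta-features with a
  # base trained only on the complementary rows and compare exactly
  f <- 1
  tf <- fruitvol:::.fit_transforms(x, y, seed = 7, select = TRUE)
  xs <- as.matrix(tf$x_sel)
  mono <- apply_monotone_constraints(colnames(xs))
  tr <- p1$folds$fold != f
  bs <- p1$bases$classic_gbrt
  m <- fruitvol:::.fit_base(bs$family, bs$params, xs[tr, ], tf$y_log[tr], mono, 7)
  expect_equal(unname(p1$fold_record$classic_gbrt[!tr]),
               unname(fruitvol:::.predict_base(m, xs[!tr, ])), tolerance = 1e-10)
})

test_that("the meta-learner tracks a dominant base and shrinks to the mean", {
  ft <- local_small_features()
  p <- fit_stack(ft[feature_names()], ft$volume_ml, seed = 3)
  oof <- as.matrix(p$fold_record[names(p$bases)])
  y_log <- p$fold_record$y_log
  base_mse <- colMeans((oof - y_log)^2)
  stack_mse <- mean((p$fold_record$oof_stack - y_log)^2)
  expect_lte(stack_mse, 1.05 * min(base_mse))
  # Lasso limit: an overwhelming penalty leaves only the intercept
  pred_inf <- as.numeric(predict(p$meta, oof, s = 1e6))
  expect_equal(pred_inf, rep(mean(y_log), nrow(oof)), tolerance = 1e-6)
})

test_that("predictions are schema-keyed, positive, and accurate in-sample", {
  ft <- local_small_features()
  p <- fit_stack(ft[feature_names()], ft$volume_ml, seed = 7)
  pred <- predict_volume(p, ft)
  expect_true(all(is.finite(pred)) && all(pred > 0))
  shuffled <- ft[c(sample(feature_names()), "volume_ml", "fruit_id")]
  expect_identical(predict_volume(p, shuffled), pred)
  expect_error(predict_volume(p, ft[1:5]), "missing feature")
  expect_lt(mean(abs(pred - ft$volume_ml) / ft$volume_ml), 0.05)
})

test_that("single-learner pipelines share the transform stack", {
  ft <- local_small_features()
  sp <- base_learner_spec("histogram_leafwise_gbrt",
                          params = default_params("histogram_leafwise_gbrt"))
  p <- fit_single_learner(ft[feature_names()], ft$volume_ml, sp, seed = 2)
  expect_null(p$meta)
  pred <- predict_volume(p, ft)
  expect_true(all(pred > 0))
  expect_lt(mean(abs(pred - ft$volume_ml) / ft$volume_ml), 0.1)
})

test_that("constrained learners never decrease along size-scaling rays", {
  ft <- local_small_features()
  p <- fit_stack(ft[feature_names()], ft$volume_ml, seed = 5)
  xs <- as.matrix(fruitvol:::.apply_transforms(p, ft))
  cons <- intersect(colnames(xs), c("w_top", "h_top", "w_side", "h_side", "d_mean"))
  expect_gt(length(cons), 0)
  withr::with_seed(6, {
    for (ray in 1:20) {
      row <- xs[sample(nrow(xs), 1), , drop = FALSE]
      steps <- seq(1, 1.25, length.out = 6)
      grid <- row[rep(1, length(steps)), , drop = FALSE]
      grid[, cons] <- outer(steps, row[1, cons])
      for (m in p$models) {
        path <- fruitvol:::.predict_base(m, grid)
        expect_true(all(diff(path) >= -1e-9))
      }
    }
  })
})

test_that("pipelines round-trip through the model-artifact directory", {
  ft <- local_small_features()
  p <- fit_stack(ft[feature_names()], ft$volume_ml, seed = 11)
  dir <- withr::local_tempdir()
  save_pipeline(p, dir)
  expect_true(all(file.exists(file.path(dir, c("transforms.json", "selection.json",
                                               "meta.json", "manifest.json",
                                               "foldrecord.csv")))))
  p2 <- load_pipeline(dir)
  expect_equal(predict_volume(p2, ft), predict_volume(p, ft), tolerance = 1e-8)
  expect_identical(p2$feature_names, p$feature_names)
})
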