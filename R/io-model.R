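#' Save / load a fitted pipeline as a model-artifact directory
#'
#' The artifact layout is plain-file and language-agnostic where possible:
#' `transforms.json` (capping bounds, log columns), `selection.json`
#' (importances, threshold, selected names), one natively serialised booster
#' per base learner (`base_<family>.ubj`), `meta.json` (Lasso coefficients
#' and penalty), and `manifest.json` (seed, feature schema, base roster,
#' fold assignment).
#'
#' @param pipeline A `fitted_pipeline`.
#' @param dir Output directory (created if needed).
#' @return `save_pipeline`: the directory, invisibly.
#' @export
save_pipeline <- function(pipeline, dir) {
  stopifnot(inherits(pipeline, "fitted_pipeline"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_capping_bounds(pipeline$caps, file.path(dir, "transforms.json"))
  jsonlite::write_json(list(importances = as.list(pipeline$selection$importances),
                            threshold = pipeline$selection$threshold,
                            selected = pipeline$selection$selected),
                       file.path(dir, "selection.json"),
                       auto_unbox = TRUE, digits = NA)
  for (fam in names(pipeline$models))
    xgboost::xgb.save(pipeline$models[[fam]],
                      file.path(dir, paste0("base_", fam, ".ubj")))
  jsonlite::write_json(list(coefficients = as.list(pipeline$meta_coef),
                            lambda = pipeline$meta_lambda),
                       file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(seed = pipeline$seed,
                            feature_names = pipeline$feature_names,
                            bases = lapply(pipeline$bases, function(b)
                              list(family = b$family, params = b$params,
                                   monotone = b$monotone)),
                            folds = if (!is.null(pipeline$folds))
                              pipeline$folds$fold),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(pipeline$fold_record))
    utils::write.csv(pipeline$fold_record, file.path(dir, "foldrecord.csv"),
                     row.names = FALSE)
  invisible(dir)
}

#' @rdname save_pipeline
#' @return `load_pipeline`: a `fitted_pipeline` usable with
#'   [predict_volume()].
#' @export
load_pipeline <- function(dir) {
  caps <- read_capping_bounds(file.path(dir, "transforms.json"))
  sel <- jsonlite::read_json(file.path(dir, "selection.json"),
                             simplifyVector = TRUE)
  selection <- structure(list(importances = unlist(sel$importances),
                              threshold = sel$threshold,
                              selected = sel$selected),
                         class = "selection_result")
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  fams <- vapply(manifest$bases, `[[`, character(1), "family")
  models <- lapply(fams, function(fam)
    xgboost::xgb.load(file.path(dir, paste0("base_", fam, ".ubj"))))
  names(models) <- fams
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  meta_coef <- unlist(meta$coefficients)
  if (length(meta_coef) < 2 || all(is.na(meta_coef))) meta_coef <- NULL
  structure(list(caps = caps, selection = selection,
                 bases = manifest$bases, models = models,
                 meta = NULL, meta_lambda = meta$lambda %||% NA_real_,
                 meta_coef = meta_coef, folds = NULL, fold_record = NULL,
                 feature_names = manifest$feature_names,
                 seed = manifest$seed),
            class = "fitted_pipeline")
}
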