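#' Fit IQR outlier-capping bounds
#'
#' Computes per-column quartiles (linear interpolation between order
#' statistics, `stats::quantile` type 7) and Tukey fences
#' `q1 - k*IQR`, `q3 + k*IQR` on training rows only — callers are responsible
#' for passing training folds exclusively, which keeps the transform
#' leakage-free. A constant column has zero IQR: its fences collapse to the
#' constant and capping is a no-op (a warning is raised).
#'
#' @param table Numeric data.frame or matrix (training rows).
#' @param k IQR multiplier (default 1.5).
#' @param columns Columns to fit; defaults to all numeric columns.
#' @return Object of class `capping_bounds`: per-column `q1, q3, lower, upper`
#'   and the multiplier `k`.
#' @export
fit_iqr_caps <- function(table, k = 1.5, columns = NULL) {
  df <- as.data.frame(table)
  if (is.null(columns)) columns <- names(df)[vapply(df, is.numeric, logical(1))]
  if (nrow(df) < 4) stop("need at least 4 training rows to fit quartiles", call. = FALSE)
  bounds <- lapply(columns, function(cn) {
    x <- df[[cn]]
    q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
    iqr <- q[2] - q[1]
    if (iqr == 0) warning("constant column '", cn, "': capping is a no-op",
                          call. = FALSE)
    c(q1 = q[1], q3 = q[2], lower = q[1] - k * iqr, upper = q[2] + k * iqr)
  })
  names(bounds) <- columns
  structure(list(bounds = bounds, k = k), class = "capping_bounds")
}

#' Apply fitted capping bounds
#'
#' Clips each fitted column into `[lower, upper]`. Idempotent; columns of the
#' table that were never fitted cause a schema error, unfitted extra columns
#' in `bounds` are ignored.
#'
#' @param table Data.frame to cap.
#' @param bounds A [fit_iqr_caps()] result.
#' @return The capped data.frame.
#' @export
apply_caps <- function(table, bounds) {
  stopifnot(inherits(bounds, "capping_bounds"))
  df <- as.data.frame(table)
  fit_cols <- names(bounds$bounds)
  num_cols <- names(df)[vapply(df, is.numeric, logical(1))]
  miss <- setdiff(num_cols, fit_cols)
  if (length(miss))
    stop("schema error: no capping bounds fitted for column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (cn in intersect(fit_cols, names(df))) {
    b <- bounds$bounds[[cn]]
    df[[cn]] <- pmin(pmax(df[[cn]], b[["lower"]]), b[["upper"]])
  }
  df
}

#' Log-transform the strictly positive magnitude features
#'
#' Natural log applied to the configured column subset (by default
#' [log_feature_names()]: volumes, areas, perimeters, surface area,
#' interactions). Ratio-type and eccentricity features stay untouched. Any
#' non-positive value in a designated column is an error naming the column
#' and row (capping runs first, so this indicates invalid input rather than
#' an outlier).
#'
#' @param table Data.frame.
#' @param log_columns Columns to log-transform (intersected with the table).
#' @return Transformed data.frame.
#' @export
winsorize_log_features <- function(table, log_columns = log_feature_names()) {
  df <- as.data.frame(table)
  for (cn in intersect(log_columns, names(df))) {
    bad <- which(df[[cn]] <= 0)
    if (length(bad))
      stop("transform error: non-positive value in log column '", cn,
           "' at row ", bad[1], call. = FALSE)
    df[[cn]] <- log(df[[cn]])
  }
  df
}

#' Log-scale target transform and inverse
#'
#' The volume target is modelled as `y = log(1 + volume_mL)` to tame
#' heteroscedastic errors; predictions are mapped back with
#' `volume = exp(y) - 1`. Round-trip identity holds to floating-point
#' precision for non-negative volumes.
#'
#' @param volume_ml Non-negative volumes (mL).
#' @return `transform_target`: log-scale target vector.
#' @export
transform_target <- function(volume_ml) {
  if (any(volume_ml < 0)) stop("domain error: negative volume", call. = FALSE)
  log1p(volume_ml)
}

#' @rdname transform_target
#' @param y_hat Predictions on the log scale.
#' @export
inverse_transform_target <- function(y_hat) {
  expm1(y_hat)
}

#' Quantile-stratified k-fold assignment
#'
#' Targets are binned by empirical quantiles into `bins` groups; within each
#' bin the samples are shuffled (seeded) and dealt round-robin onto folds
#' with a counter that carries across bins, so fold sizes differ by at most
#' one and every quantile stratum is spread over all folds where counts
#' permit.
#'
#' @param targets Numeric target vector.
#' @param k Number of folds (default 5).
#' @param bins Number of quantile strata (default 5).
#' @param seed Integer seed for the within-bin shuffles.
#' @return Object of class `fold_assignment`: integer `fold` (1..k) per
#'   sample, plus `k`, `bins`, `seed`.
#' @export
stratified_folds <- function(targets, k = 5, bins = 5, seed = 1L) {
  n <- length(targets)
  if (n < k) stop("fold error: fewer samples than folds", call. = FALSE)
  probs <- seq(0, 1, length.out = bins + 1)
  edges <- stats::quantile(targets, probs, names = FALSE, type = 7)
  bin <- findInterval(targets, unique(edges), rightmost.closed = TRUE)
  fold <- integer(n)
  counter <- 0L
  with_rng(seed, {
    for (b in sort(unique(bin))) {
      idx <- which(bin == b)
      idx <- idx[sample.int(length(idx))]
      for (i in idx) {
        fold[i] <- (counter %% k) + 1L
        counter <- counter + 1L
      }
    }
  })
  structure(list(fold = fold, k = as.integer(k), bins = as.integer(bins),
                 seed = as.integer(seed)),
            class = "fold_assignment")
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat(sprintf("fold_assignment: %d samples, k=%d, bins=%d, seed=%d; sizes: %s\n",
              length(x$fold), x$k, x$bins, x$seed,
              paste(tabulate(x$fold, x$k), collapse = ", ")))
  invisible(x)
}

#' Serialise / restore preprocessing artifacts
#'
#' Capping bounds and fold assignments round-trip through JSON so a fitted
#' pipeline can be frozen alongside model artifacts.
#'
#' @param bounds A `capping_bounds` object.
#' @param path JSON file path.
#' @export
write_capping_bounds <- function(bounds, path) {
  stopifnot(inherits(bounds, "capping_bounds"))
  jsonlite::write_json(list(k = bounds$k,
                            bounds = lapply(bounds$bounds, as.list)), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_capping_bounds
#' @export
read_capping_bounds <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  bounds <- lapply(obj$bounds, function(b) unlist(b))
  structure(list(bounds = bounds, k = obj$k), class = "capping_bounds")
}
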