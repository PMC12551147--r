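#' Model configuration for cross-validated tree-ensemble regression
#'
#' @param algorithm `"random_forest"` (default) or `"xgboost"` (gradient
#'   boosted trees).
#' @param n_trees Number of trees (random forest default 1000).
#' @param grid Hyperparameter grid as a data frame; one row per candidate.
#'   For the random forest the single tuned parameter is `mtry`
#'   (features per split); the default grid is `round(sqrt(p))`,
#'   `round(p/3)`, `round(p/2)` for `p` features. For xgboost, columns may
#'   include `eta`, `max_depth`, `gamma`, `colsample_bytree`,
#'   `min_child_weight`, `subsample`, `nrounds`.
#' @param n_folds Cross-validation folds (default 5).
#' @param seed Integer seed controlling fold assignment and tree growth.
#' @return A list of class `tep_config`.
#' @export
tep_model_config <- function(algorithm = c("random_forest", "xgboost"),
                             n_trees = 1000L, grid = NULL, n_folds = 5L,
                             seed = 1L) {
  algorithm <- match.arg(algorithm)
  stopifnot(n_folds >= 2L, n_trees >= 1L)
  if (!is.null(grid)) {
    grid <- as.data.frame(grid)
    if (nrow(grid) == 0L) stop("hyperparameter grid must be non-empty")
  }
  structure(list(algorithm = algorithm, n_trees = as.integer(n_trees),
                 grid = grid, n_folds = as.integer(n_folds),
                 seed = as.integer(seed)),
            class = "tep_config")
}

default_grid <- function(config, p) {
  if (!is.null(config$grid)) return(config$grid)
  if (config$algorithm == "random_forest") {
    data.frame(mtry = unique(pmax(1L, round(c(sqrt(p), p / 3, p / 2)))))
  } else {
    expand.grid(eta = 0.1, max_depth = c(2L, 4L), gamma = 0,
                colsample_bytree = 0.8, min_child_weight = 1,
                subsample = 0.8, nrounds = 300L)
  }
}

fit_one <- function(x, y, config, params, seed) {
  if (config$algorithm == "random_forest") {
    ranger::ranger(x = x, y = y, num.trees = config$n_trees,
                   mtry = min(params$mtry, ncol(x)),
                   importance = "impurity", seed = seed, num.threads = 1L)
  } else {
    set.seed(seed)
    xgboost::xgb.train(params = list(eta = params$eta,
                                     max_depth = params$max_depth,
                                     gamma = params$gamma,
                                     colsample_bytree = params$colsample_bytree,
                                     min_child_weight = params$min_child_weight,
                                     subsample = params$subsample,
                                     objective = "reg:squarederror",
                                     nthread = 1L),
                       data = xgboost::xgb.DMatrix(x, label = y, nthread = 1L),
                       nrounds = params$nrounds, verbose = 0)
  }
}

predict_one <- function(fit, x) {
  if (inherits(fit, "ranger")) {
    stats::predict(fit, data = x, num.threads = 1L)$predictions
  } else {
    stats::predict(fit, xgboost::xgb.DMatrix(x, nthread = 1L))
  }
}

#' Pearson correlation and RMSE between predictions and observations
#'
#' @param pred,obs Numeric vectors of equal length >= 2.
#' @return A list with `r` (Pearson correlation; `NA` with `r_defined =
#'   FALSE` when either vector has zero variance), `rmse`, and `r_defined`.
#' @examples
#' evaluate_predictions(c(1, 2, 3), c(2, 2, 5))
#' @export
evaluate_predictions <- function(pred, obs) {
  stopifnot(length(pred) == length(obs), length(obs) >= 2L)
  rmse <- sqrt(mean((pred - obs)^2))
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0) {
    list(r = NA_real_, rmse = rmse, r_defined = FALSE)
  } else {
    list(r = stats::cor(pred, obs), rmse = rmse, r_defined = TRUE)
  }
}

#' Cross-validated tree-ensemble regression of peptide activity
#'
#' Fits a random forest or gradient-boosted-tree regression of relative
#' fluorescence on the 157 descriptor features under k-fold cross-validation.
#' Hyperparameters are chosen by minimum pooled out-of-fold RMSE over the
#' grid; the winning configuration is refit on all data. Pooled metrics are
#' computed on the concatenated out-of-fold predictions (per-fold metrics are
#' also kept). Fully reproducible given `config$seed`.
#'
#' @param x Numeric feature matrix (rows = peptides, named columns).
#' @param y Numeric response (relative fluorescence intensities).
#' @param config A [tep_model_config()].
#' @return An object of class `tep_model` with elements `fit` (the refit
#'   ensemble), `config`, `best_params`, `folds`, `oof` (out-of-fold
#'   predictions aligned with `y`), `fold_metrics`, `pooled_r`,
#'   `pooled_rmse`, `r_defined`, `importance`, `feature_names`,
#'   `y_range`, `grid_results`.
#' @export
tep_train <- function(x, y, config = tep_model_config()) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), all(is.finite(y)))
  if (nrow(x) < config$n_folds) stop("need at least n_folds rows")
  if (is.null(colnames(x))) stop("feature matrix must have column names")
  grid <- default_grid(config, ncol(x))
  set.seed(config$seed)
  folds <- sample(rep(seq_len(config$n_folds), length.out = nrow(x)))
  oof_by_cand <- matrix(NA_real_, nrow(x), nrow(grid))
  for (g in seq_len(nrow(grid))) {
    for (f in seq_len(config$n_folds)) {
      tr <- folds != f
      fit <- fit_one(x[tr, , drop = FALSE], y[tr], config, grid[g, , drop = FALSE],
                     seed = config$seed + 1000L * g + f)
      oof_by_cand[!tr, g] <- predict_one(fit, x[!tr, , drop = FALSE])
    }
  }
  cand_rmse <- sqrt(colMeans((oof_by_cand - y)^2))
  best <- which.min(cand_rmse)  # ties: first grid row wins (documented)
  oof <- oof_by_cand[, best]
  fold_metrics <- do.call(rbind, lapply(seq_len(config$n_folds), function(f) {
    m <- evaluate_predictions(oof[folds == f], y[folds == f])
    data.frame(fold = f, n = sum(folds == f), r = m$r, rmse = m$rmse)
  }))
  pooled <- evaluate_predictions(oof, y)
  fit <- fit_one(x, y, config, grid[best, , drop = FALSE],
                 seed = config$seed)
  model <- list(fit = fit, config = config,
                best_params = grid[best, , drop = FALSE],
                grid_results = data.frame(grid, cv_rmse = cand_rmse),
                folds = folds, oof = oof, y = y,
                fold_metrics = fold_metrics,
                pooled_r = pooled$r, pooled_rmse = pooled$rmse,
                r_defined = pooled$r_defined,
                feature_names = colnames(x),
                y_range = range(y),
                n_train = nrow(x))
  class(model) <- "tep_model"
  model$importance <- feature_importance(model)
  model
}

#' Predict activity over a peptide feature matrix
#'
#' @param object A `tep_model`.
#' @param newdata Feature matrix whose columns match the training features
#'   (same names, same order).
#' @param ... Unused.
#' @return Numeric vector of predicted relative intensities.
#' @export
predict.tep_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (is.null(colnames(newdata)) ||
      !identical(colnames(newdata), object$feature_names)) {
    missing <- setdiff(object$feature_names, colnames(newdata))
    extra <- setdiff(colnames(newdata), object$feature_names)
    stop("feature columns do not match training schema",
         if (length(missing)) paste0("; missing: ",
                                     paste(utils::head(missing, 5), collapse = ", ")),
         if (length(extra)) paste0("; unexpected: ",
                                   paste(utils::head(extra, 5), collapse = ", ")),
         if (!length(missing) && !length(extra)) "; column order differs")
  }
  predict_one(object$fit, newdata)
}

#' Normalized feature importance of a fitted model
#'
#' Impurity-based importance scores normalized to sum to one, ranked in
#' descending order with ties broken by feature name. Features the ensemble
#' never used get score zero, so the table always has one row per training
#' feature.
#'
#' @param model A `tep_model`.
#' @return Data frame with columns `feature`, `importance`, `rank`.
#' @export
feature_importance <- function(model) {
  stopifnot(inherits(model, "tep_model"))
  imp <- stats::setNames(numeric(length(model$feature_names)),
                         model$feature_names)
  if (inherits(model$fit, "ranger")) {
    v <- ranger::importance(model$fit)
    imp[names(v)] <- pmax(v, 0)
  } else {
    it <- xgboost::xgb.importance(model = model$fit)
    imp[it$Feature] <- it$Gain
  }
  if (sum(imp) > 0) imp <- imp / sum(imp)
  ord <- order(-imp, names(imp))
  out <- data.frame(feature = names(imp)[ord], importance = unname(imp[ord]))
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' @export
print.tep_model <- function(x, ...) {
  cat("Cross-validated", gsub("_", " ", x$config$algorithm), "regression\n")
  cat(sprintf("  n = %d peptides, %d features, %d folds\n",
              x$n_train, length(x$feature_names), x$config$n_folds))
  cat(sprintf("  pooled out-of-fold: r = %s, RMSE = %.3f\n",
              if (x$r_defined) sprintf("%.3f", x$pooled_r) else "undefined",
              x$pooled_rmse))
  cat("  best hyperparameters:",
      paste(names(x$best_params), unlist(x$best_params), sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.tep_model <- function(object, ...) {
  cat("Per-fold out-of-fold metrics:\n")
  print(object$fold_metrics, row.names = FALSE)
  cat(sprintf("Pooled: r = %s, RMSE = %.4f\n",
              if (object$r_defined) sprintf("%.4f", object$pooled_r) else "undefined (constant input)",
              object$pooled_rmse))
  cat("Top 10 features by importance:\n")
  print(utils::head(object$importance, 10), row.names = FALSE)
  invisible(object)
}

#' @export
residuals.tep_model <- function(object, ...) {
  object$y - object$oof
}

#' Predicted-versus-observed plot of the cross-validation
#'
#' @param x A `tep_model`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.tep_model <- function(x, ...) {
  graphics::plot(x$oof, x$y, xlab = "predicted (out-of-fold)",
                 ylab = "observed relative intensity",
                 main = sprintf("pooled r = %s, RMSE = %.3f",
                                if (x$r_defined) sprintf("%.2f", x$pooled_r) else "NA",
                                x$pooled_rmse), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
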