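#' Random fold plan for k-fold cross-validation
#'
#' Partitions samples uniformly at random into folds of near-equal size
#' (sizes differ by at most 1; when `n` is divisible by `k` every fold has
#' exactly `n/k` samples, e.g. 92 samples in 4 folds of 23). All randomness
#' flows from the supplied seed, so plans are reproducible.
#'
#' @param n_samples Number of samples (>= `n_folds`).
#' @param n_folds Number of folds (default 4, i.e. a 75/25 split per fold).
#' @param seed Integer seed.
#' @return An object of class `fold_plan`: `n_samples`, `n_folds`, `seed`,
#'   `assignments` (fold index per sample).
#' @export
make_fold_plan <- function(n_samples, n_folds = 4, seed) {
  stopifnot(is.numeric(n_samples), length(n_samples) == 1,
            is.numeric(n_folds), length(n_folds) == 1)
  n_samples <- as.integer(n_samples)
  n_folds <- as.integer(n_folds)
  if (n_folds < 2) stop("need at least 2 folds", call. = FALSE)
  if (n_samples < n_folds) stop("need at least one sample per fold", call. = FALSE)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  base <- n_samples %/% n_folds
  sizes <- base + (seq_len(n_folds) <= n_samples %% n_folds)
  assignments <- withr::with_seed(seed,
                                  sample(rep(seq_len(n_folds), times = sizes)))
  structure(list(n_samples = n_samples, n_folds = n_folds, seed = seed,
                 assignments = assignments),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> %d samples in %d folds (seed %d): sizes %s\n",
              x$n_samples, x$n_folds, x$seed,
              paste(tabulate(x$assignments, x$n_folds), collapse = "/")))
  invisible(x)
}

#' Prediction-quality metrics
#'
#' Root-mean-square error, OLS coefficient of determination and slope of
#' the regression of predicted on observed, and the relative error
#' (RMSE as a percentage of the observed mean). For constant observations
#' R^2 and slope are undefined and reported as `NA` with a warning.
#'
#' @param y_obs,y_pred Numeric vectors of equal length (>= 2).
#' @return A list: `rmse`, `r2`, `slope`, `relative_error_pct`.
#' @examples
#' evaluate_predictions(c(1, 2, 3), c(2, 3, 4)) # rmse 1, slope 1, rel.err 50%
#' @export
evaluate_predictions <- function(y_obs, y_pred) {
  stopifnot(is.numeric(y_obs), is.numeric(y_pred),
            length(y_obs) == length(y_pred), length(y_obs) >= 2,
            all(is.finite(y_obs)), all(is.finite(y_pred)))
  rmse <- sqrt(mean((y_obs - y_pred)^2))
  if (stats::sd(y_obs) == 0) {
    warning("constant observations: R^2 and slope are undefined", call. = FALSE)
    r2 <- NA_real_
    slope <- NA_real_
  } else {
    # closed-form simple OLS of predicted on observed; R^2 of a simple
    # regression is the squared correlation
    slope <- stats::cov(y_obs, y_pred) / stats::var(y_obs)
    r2 <- if (stats::sd(y_pred) == 0) 0 else stats::cor(y_obs, y_pred)^2
  }
  list(rmse = rmse, r2 = r2, slope = slope,
       relative_error_pct = 100 * rmse / mean(y_obs))
}

#' Variance explained in the response
#'
#' `100 * (1 - SS_residual / SS_total)` of the model's predictions for
#' `dataset` against `y`, on the modelling scale.
#'
#' @param model An `npls_model`.
#' @param dataset An `eem_dataset`.
#' @param y Observed responses.
#' @return Percentage (may be negative for a model worse than the mean).
#' @export
variance_explained_y <- function(model, dataset, y) {
  stopifnot(inherits(model, "npls_model"))
  pred <- stats::predict(model, dataset)
  100 * (1 - sum((y - pred)^2) / sum((y - mean(y))^2))
}

#' Select the number of latent variables by leave-one-out CV
#'
#' For each candidate model size F, every training sample is left out in
#' turn, the model refitted on the remainder and the left-out sample
#' predicted; `RMSECV(F)` is the root mean squared error of those
#' predictions. The chosen size minimises RMSECV, taking the smallest F on
#' ties (parsimony). `max_lvs` is clipped to `training size - 2` with a
#' warning. Because tri-PLS1 is sequential (the first F LVs of a larger
#' model are the F-LV model), each leave-one-out refit is done once at
#' `max_lvs` and evaluated at every F.
#'
#' @param dataset Training `eem_dataset`.
#' @param y Training responses.
#' @param max_lvs Largest model size to consider.
#' @return A list: `chosen_lvs`, `rmsecv_curve` (named vector over F),
#'   `loocv_predictions` (samples x F matrix).
#' @export
loocv_select_lvs <- function(dataset, y, max_lvs = 12) {
  stopifnot(inherits(dataset, "eem_dataset"), is.numeric(y))
  n <- length(dataset$samples)
  stopifnot(length(y) == n, n >= 3)
  if (stats::sd(y) == 0) stop("constant training response", call. = FALSE)
  if (max_lvs < 1) stop("max_lvs must be at least 1", call. = FALSE)
  if (max_lvs > n - 2) {
    warning("max_lvs clipped from ", max_lvs, " to ", n - 2,
            " (training size - 2)", call. = FALSE)
    max_lvs <- n - 2
  }
  preds <- matrix(NA_real_, n, max_lvs,
                  dimnames = list(dataset$samples, paste0("F", seq_len(max_lvs))))
  for (i in seq_len(n)) {
    train <- dataset_subset(dataset, setdiff(seq_len(n), i))
    test <- dataset_subset(dataset, i)
    fit <- fit_npls(train, y[-i], n_lvs = max_lvs)
    for (f in seq_len(max_lvs)) {
      preds[i, f] <- if (f <= fit$n_lvs) {
        stats::predict(fit, test, n_lvs = f)
      } else {
        stats::predict(fit, test, n_lvs = fit$n_lvs)
      }
    }
  }
  rmsecv <- sqrt(colMeans((preds - y)^2))
  list(chosen_lvs = unname(which.min(rmsecv)),   # which.min: smallest F on ties
       rmsecv_curve = rmsecv,
       loocv_predictions = preds)
}

#' Nested (double) cross-validation of an N-PLS model
#'
#' The outer loop splits the samples into `n_folds` random folds (75/25
#' train/validation per fold with the default 4); for each fold the inner
#' leave-one-out loop selects the number of LVs on the training portion
#' only, a model of that size is fitted on the full training portion and
#' the held-out fold predicted. Every sample is predicted out-of-fold
#' exactly once; pooled metrics are computed over those predictions. Fully
#' deterministic given the seed.
#'
#' @param dataset An `eem_dataset`.
#' @param y Responses on the modelling scale.
#' @param n_folds Outer folds (default 4).
#' @param seed Integer seed for the fold plan.
#' @param max_lvs Largest model size for the inner loop (default 12,
#'   clipped by training size).
#' @param response_name Label carried into reports.
#' @return An object of class `double_cv_report`: `folds` (per-fold
#'   data.frame of `chosen_lvs`, `rmsecv`, `rmsep`, `r2_train`, `r2_val`,
#'   `slope_train`, `slope_val`, `variance_explained_pct`,
#'   `relative_error_pct`), `pooled` (metrics over all out-of-fold
#'   predictions), `oof` (per-sample out-of-fold predictions), `plan`.
#' @export
run_double_cv <- function(dataset, y, n_folds = 4, seed, max_lvs = 12,
                          response_name = "response") {
  stopifnot(inherits(dataset, "eem_dataset"), is.numeric(y))
  n <- length(dataset$samples)
  stopifnot(length(y) == n)
  plan <- make_fold_plan(n, n_folds, seed)
  fold_rows <- vector("list", n_folds)
  oof_pred <- rep(NA_real_, n)
  oof_lvs <- rep(NA_integer_, n)
  for (k in seq_len(n_folds)) {
    val_idx <- which(plan$assignments == k)
    train_idx <- setdiff(seq_len(n), val_idx)
    ds_train <- dataset_subset(dataset, train_idx)
    ds_val <- dataset_subset(dataset, val_idx)
    sel <- loocv_select_lvs(ds_train, y[train_idx], max_lvs = max_lvs)
    fit <- fit_npls(ds_train, y[train_idx], n_lvs = sel$chosen_lvs,
                    response_name = response_name)
    pred_val <- stats::predict(fit, ds_val)
    oof_pred[val_idx] <- pred_val
    oof_lvs[val_idx] <- fit$n_lvs
    m_train <- evaluate_predictions(y[train_idx], fit$fitted)
    m_val <- evaluate_predictions(y[val_idx], pred_val)
    fold_rows[[k]] <- data.frame(
      fold = k,
      n_train = length(train_idx), n_val = length(val_idx),
      chosen_lvs = fit$n_lvs,
      rmsecv = unname(sel$rmsecv_curve[fit$n_lvs]),
      rmsep = m_val$rmse,
      r2_train = m_train$r2, r2_val = m_val$r2,
      slope_train = m_train$slope, slope_val = m_val$slope,
      variance_explained_pct = variance_explained_y(fit, ds_train, y[train_idx]),
      relative_error_pct = m_val$relative_error_pct)
  }
  pooled <- evaluate_predictions(y, oof_pred)
  folds <- do.call(rbind, fold_rows)
  structure(list(response_name = response_name,
                 folds = folds,
                 pooled = list(rmsep = pooled$rmse, r2 = pooled$r2,
                               slope = pooled$slope,
                               relative_error_pct = pooled$relative_error_pct),
                 oof = data.frame(sample_id = dataset$samples,
                                  fold = plan$assignments,
                                  chosen_lvs = oof_lvs,
                                  observed = y, predicted = oof_pred,
                                  stringsAsFactors = FALSE),
                 plan = plan),
            class = "double_cv_report")
}

#' @export
print.double_cv_report <- function(x, ...) {
  cat(sprintf("<double_cv_report> '%s': %d folds over %d samples\n",
              x$response_name, x$plan$n_folds, x$plan$n_samples))
  print(x$folds, row.names = FALSE, digits = 4)
  cat(sprintf("pooled: RMSEP %.4g, R^2 %.4g, slope %.4g, rel. error %.3g%%\n",
              x$pooled$rmsep, x$pooled$r2, x$pooled$slope,
              x$pooled$relative_error_pct))
  invisible(x)
}

#' Fit the final full-data model
#'
#' After cross-validation, a deployment model is fitted on 100% of the
#' samples at the cross-validated number of LVs (the mode of the per-fold
#' choices, ties resolved toward the smaller size), and folded into its
#' regression-coefficient map.
#'
#' @param dataset An `eem_dataset`.
#' @param y Responses on the modelling scale.
#' @param chosen_lvs Explicit number of LVs; overrides `report`.
#' @param report A `double_cv_report` to take the LV choice from.
#' @param response_name Label stored with the model.
#' @param log10_applied Passed to [fit_npls()].
#' @return A list: `model` (`npls_model`), `map` ([coefficient_map()]),
#'   `chosen_lvs`.
#' @export
fit_final_model <- function(dataset, y, chosen_lvs = NULL, report = NULL,
                            response_name = "response", log10_applied = FALSE) {
  if (is.null(chosen_lvs)) {
    if (is.null(report)) {
      stop("supply either `chosen_lvs` or a `report`", call. = FALSE)
    }
    stopifnot(inherits(report, "double_cv_report"))
    choices <- report$folds$chosen_lvs
    tab <- table(choices)
    best <- as.integer(names(tab)[tab == max(tab)])
    chosen_lvs <- min(best)
  }
  model <- fit_npls(dataset, y, n_lvs = chosen_lvs,
                    response_name = response_name,
                    log10_applied = log10_applied)
  list(model = model, map = coefficient_map(model), chosen_lvs = model$n_lvs)
}

#' Serialize a double-CV report
#'
#' Writes the report as JSON and, alongside it, the per-sample out-of-fold
#' predictions as CSV (same path with suffix `_oof.csv`).
#'
#' @param report A `double_cv_report`.
#' @param path Output JSON path.
#' @export
write_cv_report <- function(report, path) {
  stopifnot(inherits(report, "double_cv_report"))
  payload <- list(response_name = report$response_name,
                  folds = report$folds,
                  pooled = report$pooled,
                  plan = report$plan[c("n_samples", "n_folds", "seed",
                                       "assignments")])
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       na = "null", pretty = TRUE)
  oof_path <- sub("\\.json$", "", path)
  utils::write.csv(report$oof, paste0(oof_path, "_oof.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
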