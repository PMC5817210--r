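#' Normalized root mean squared error
#'
#' `NRMSE = sqrt(sum((pred - obs)^2) / n) / (Xmax - Xmin) * 100`, where
#' `Xmax` and `Xmin` are the maximum and minimum *observed* response values
#' of the evaluation split. For comparability across folds the normalizing
#' range can instead be fixed via `range_obs` (e.g. the global observed
#' response range).
#'
#' @param obs Observed response vector.
#' @param pred Predicted response vector of the same length.
#' @param range_obs Optional fixed `c(min, max)` normalizing range; default
#'   is the observed range of `obs`.
#' @return NRMSE in percent.
#' @examples
#' nrmse(c(0, 10), c(0, 0))  # 70.71068
#' @export
nrmse <- function(obs, pred, range_obs = NULL) {
  stopifnot(length(obs) == length(pred), length(obs) >= 2L)
  if (is.null(range_obs)) range_obs <- range(obs)
  if (diff(range_obs) <= 0)
    stop("normalization undefined: observed range is degenerate")
  sqrt(mean((pred - obs)^2)) / diff(range_obs) * 100
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot`. Equals 1 iff `pred == obs`; can be negative
#' for predictors worse than the observed mean.
#'
#' @inheritParams nrmse
#' @return R-squared.
#' @export
r_squared <- function(obs, pred) {
  stopifnot(length(obs) == length(pred), length(obs) >= 2L)
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot <= 0) stop("R-squared undefined for a constant observed vector")
  1 - sum((pred - obs)^2) / ss_tot
}

#' Grouped cross-validated evaluation
#'
#' Runs a fit procedure over a fold assignment: for each fold the model is
#' fitted on the training records and scored (NRMSE, R-squared) on the
#' held-out arm, forcing prediction of an unseen drug combination. Reports
#' per-fold metrics, their mean, and a pooled NRMSE over the concatenated
#' held-out predictions (pooling and averaging generally differ; both are
#' returned). Optionally the model fitted on all records is scored on a
#' noised replicate of the data as a stability check.
#'
#' @param fit_fun Function taking a training data frame and returning a
#'   prediction function `function(newdata) -> numeric`.
#' @param data Data frame containing the covariates and the response.
#' @param folds Fold assignment from [make_loio_folds()].
#' @param response Name of the response column (default `"dQTc"`).
#' @param noised Optional noised data frame ([add_noise()]) for stability
#'   testing.
#' @return An object of class `cv_report`: list with `per_fold` (data
#'   frame: arm, n_test, nrmse, r2), `mean_nrmse`, `pooled_nrmse`, and
#'   `noised_nrmse` (or `NA`).
#' @export
cv_evaluate <- function(fit_fun, data, folds, response = "dQTc",
                        noised = NULL) {
  obs_all <- data[[response]]
  pooled_obs <- numeric()
  pooled_pred <- numeric()
  per_fold <- do.call(rbind, lapply(folds, function(f) {
    if (length(f$test) < 2L)
      stop("fold '", f$arm, "' has fewer than 2 test records")
    predict_fun <- fit_fun(data[f$train, , drop = FALSE])
    pred <- predict_fun(data[f$test, , drop = FALSE])
    obs <- obs_all[f$test]
    pooled_obs <<- c(pooled_obs, obs)
    pooled_pred <<- c(pooled_pred, pred)
    data.frame(arm = f$arm, n_test = length(f$test),
               nrmse = nrmse(obs, pred), r2 = r_squared(obs, pred),
               stringsAsFactors = FALSE)
  }))
  rownames(per_fold) <- NULL
  noised_nrmse <- NA_real_
  if (!is.null(noised)) {
    predict_fun <- fit_fun(data)
    noised_nrmse <- nrmse(noised[[response]], predict_fun(noised))
  }
  structure(list(per_fold = per_fold,
                 mean_nrmse = mean(per_fold$nrmse),
                 pooled_nrmse = nrmse(pooled_obs, pooled_pred),
                 noised_nrmse = noised_nrmse),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("Grouped cross-validation over", nrow(x$per_fold), "folds\n")
  print(x$per_fold, row.names = FALSE)
  cat("mean NRMSE:", format(x$mean_nrmse, digits = 4),
      "%; pooled NRMSE:", format(x$pooled_nrmse, digits = 4), "%\n")
  if (is.finite(x$noised_nrmse))
    cat("noised-set NRMSE:", format(x$noised_nrmse, digits = 4), "%\n")
  invisible(x)
}
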