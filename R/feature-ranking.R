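#' Permutation importance of covariates under a fitted predictor
#'
#' Built-in importance estimator for the ranking stage: the importance of a
#' variable is the average increase in prediction error (RMSE or MSE) after
#' randomly permuting that variable's column, over `repeats` permutations.
#' Variables the predictor ignores score (up to permutation noise) zero;
#' negative estimates are clamped at zero.
#'
#' The ranking stage is learner-agnostic: any number of importance reports
#' from any predictors can be aggregated with [scale_and_aggregate()].
#'
#' @param predict_fun Function mapping a data frame of covariates to a
#'   numeric prediction vector.
#' @param data Data frame of covariates.
#' @param response Numeric observed response vector.
#' @param metric `"rmse"` or `"mse"`.
#' @param repeats Permutations per variable.
#' @param seed Integer seed; required.
#' @param learner Label stored in the report.
#' @return An object of class `importance_report`: list with `learner`,
#'   `importance` (named non-negative vector), `error` (unpermuted global
#'   error) and `metric`.
#' @export
permutation_importance <- function(predict_fun, data, response,
                                   metric = c("rmse", "mse"),
                                   repeats = 10L, seed, learner = "predictor") {
  metric <- match.arg(metric)
  if (missing(seed) || is.null(seed))
    stop("a seed is required for permutation importance")
  if (length(unique(response)) < 2L)
    stop("importance metric undefined on a constant response")
  err <- function(pred) {
    m <- mean((pred - response)^2)
    if (metric == "rmse") sqrt(m) else m
  }
  base <- err(predict_fun(data))
  set.seed(as.integer(seed))
  imp <- vapply(names(data), function(v) {
    mean(vapply(seq_len(repeats), function(r) {
      perm <- data
      perm[[v]] <- perm[[v]][sample.int(nrow(perm))]
      err(predict_fun(perm)) - base
    }, numeric(1)))
  }, numeric(1))
  structure(list(learner = learner, importance = pmax(imp, 0),
                 error = base, metric = metric),
            class = "importance_report")
}

#' Performance-weighted aggregation of importance reports
#'
#' Combines per-learner importance vectors into one feature ranking: each
#' learner's vector is normalized to sum one, weighted by the inverse of that
#' learner's global error (so better-performing learners contribute more),
#' summed across learners and sorted in descending order. All-zero importance
#' vectors are excluded with a warning. The aggregate is invariant to
#' rescaling any single learner's raw importances.
#'
#' @param reports List of `importance_report` objects (a single report may be
#'   passed bare).
#' @return An object of class `feature_ranking`: data frame with columns
#'   `variable` and `importance`, sorted descending.
#' @export
scale_and_aggregate <- function(reports) {
  if (inherits(reports, "importance_report")) reports <- list(reports)
  if (!length(reports)) stop("at least one importance report is required")
  keep <- vapply(reports, function(r) sum(r$importance) > 0, logical(1))
  if (!any(keep)) stop("all importance vectors are zero")
  if (!all(keep))
    warning("excluding ", sum(!keep), " report(s) with all-zero importances")
  reports <- reports[keep]
  vars <- unique(unlist(lapply(reports, function(r) names(r$importance))))
  total <- stats::setNames(numeric(length(vars)), vars)
  for (r in reports) {
    if (r$error <= 0) stop("learner global error must be positive")
    w <- r$importance / sum(r$importance) / r$error
    total[names(w)] <- total[names(w)] + w
  }
  rk <- data.frame(variable = names(total), importance = unname(total),
                   stringsAsFactors = FALSE)
  rk <- rk[order(-rk$importance), ]
  rownames(rk) <- NULL
  class(rk) <- c("feature_ranking", "data.frame")
  rk
}

#' Importance-drop cut-off rule
#'
#' Selects the leading variables of a descending ranking by locating
#' consecutive-importance drops larger than `threshold` times the total
#' importance sum. Every such drop is a candidate cut point (this is how a
#' single ranking yields several nested candidate input vectors); the
#' returned selection keeps everything above the deepest qualifying cut,
#' i.e. the prefix ending just before the last position whose drop from its
#' predecessor exceeds the threshold. If no drop qualifies, all variables are
#' kept. With `rule = "share"` the alternative reading is used instead: keep
#' variables whose importance share is at least `threshold`.
#'
#' @param ranking A `feature_ranking` from [scale_and_aggregate()] (or any
#'   data frame with `variable` and descending `importance`).
#' @param threshold Fraction of the total importance sum (default 0.05).
#' @param rule `"drop"` (consecutive drop, default) or `"share"`.
#' @return Character vector of selected variable names (a prefix of the
#'   ranking), with attribute `cutpoints` listing all qualifying prefix
#'   lengths under the drop rule.
#' @export
apply_cutoff <- function(ranking, threshold = 0.05,
                         rule = c("drop", "share")) {
  rule <- match.arg(rule)
  if (!nrow(ranking)) stop("empty ranking")
  imp <- ranking$importance
  if (is.unsorted(rev(imp))) stop("ranking must be sorted descending")
  total <- sum(imp)
  if (rule == "share") {
    sel <- ranking$variable[imp / total >= threshold]
    if (!length(sel)) sel <- ranking$variable[1L]
    return(sel)
  }
  drops <- -diff(imp)
  qualifying <- which(drops > threshold * total)
  keep_n <- if (length(qualifying)) max(qualifying) else nrow(ranking)
  structure(ranking$variable[seq_len(keep_n)],
            cutpoints = qualifying)
}
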