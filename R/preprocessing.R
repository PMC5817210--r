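#' Fit a linear 0.1-0.9 scaler
#'
#' Builds the per-variable affine maps that carry each raw variable onto the
#' interval `<0.1, 0.9>`:
#' `scaled = 0.1 + 0.8 * (x - raw_min) / (raw_max - raw_min)`.
#' Bounds come either from the published summary (`source = "table"`,
#' reproducible, the default) or from the empirical range of a data set
#' (`source = "empirical"`). Constant-class variables (identically zero) are
#' exempt and pass through as zero. The `dQTc` output keeps an entry (raw
#' bounds -15.707 to 78.142 under the published summary) for optional
#' scaled-target model fits, but the white-box equation emits raw
#' milliseconds and does not use it.
#'
#' Values outside the raw bounds extrapolate linearly; this is intentional
#' (the channel-effect comparison sweeps ICaL inhibition beyond its observed
#' maximum).
#'
#' @param specs Specification table ([reference_specs()]); used for bounds
#'   when `source = "table"` and for variable classes always.
#' @param data Data frame of raw records, required for `source = "empirical"`.
#' @param source `"table"` or `"empirical"`.
#' @param target_lo,target_hi Target interval endpoints.
#' @return An object of class `qt_scaler`: a data frame with one row per
#'   variable (`name`, `raw_min`, `raw_max`, `target_lo`, `target_hi`,
#'   `constant`).
#' @examples
#' sc <- fit_scaler()
#' scale_values(sc, "K", c(3.053, 4.268, 5.363))
#' @export
fit_scaler <- function(specs = reference_specs(), data = NULL,
                       source = c("table", "empirical"),
                       target_lo = 0.1, target_hi = 0.9) {
  source <- match.arg(source)
  if (source == "empirical") {
    if (is.null(data)) stop("empirical scaling requires data")
    nm <- intersect(specs$name, names(data))
    raw_min <- vapply(nm, function(v) min(data[[v]]), numeric(1))
    raw_max <- vapply(nm, function(v) max(data[[v]]), numeric(1))
    cls <- specs$vclass[match(nm, specs$name)]
  } else {
    nm <- specs$name
    raw_min <- specs$vmin
    raw_max <- specs$vmax
    cls <- specs$vclass
  }
  constant <- cls == "constant"
  degenerate <- !constant & raw_max <= raw_min
  if (any(degenerate))
    stop("degenerate range for non-constant variable(s): ",
         paste(nm[degenerate], collapse = ", "))
  structure(data.frame(name = nm, raw_min = raw_min, raw_max = raw_max,
                       target_lo = target_lo, target_hi = target_hi,
                       constant = constant, stringsAsFactors = FALSE,
                       row.names = NULL),
            class = c("qt_scaler", "data.frame"))
}

scaler_row <- function(scaler, variable) {
  i <- match(variable, scaler$name)
  if (is.na(i)) stop("variable '", variable, "' not in scaler")
  scaler[i, ]
}

#' Apply or invert the 0.1-0.9 scaling for one variable
#'
#' @param scaler A `qt_scaler` from [fit_scaler()].
#' @param variable Variable name.
#' @param x Numeric vector on the raw (for `scale_values`) or scaled (for
#'   `unscale_values`) scale.
#' @return Numeric vector of the same length.
#' @export
scale_values <- function(scaler, variable, x) {
  r <- scaler_row(scaler, variable)
  if (r$constant) return(rep(0, length(x)))
  r$target_lo + (r$target_hi - r$target_lo) * (x - r$raw_min) /
    (r$raw_max - r$raw_min)
}

#' @rdname scale_values
#' @export
unscale_values <- function(scaler, variable, x) {
  r <- scaler_row(scaler, variable)
  if (r$constant) return(rep(0, length(x)))
  r$raw_min + (x - r$target_lo) * (r$raw_max - r$raw_min) /
    (r$target_hi - r$target_lo)
}

#' Scale every covered column of a table
#'
#' Applies [scale_values()] to each data-frame column present in the scaler;
#' id/label columns (`patient_id`, `arm`, anything not in the scaler) pass
#' through untouched.
#'
#' @inheritParams scale_values
#' @param data Data frame of raw records.
#' @return Data frame of the same shape on the scaled scale.
#' @export
scale_table <- function(scaler, data) {
  for (v in intersect(scaler$name, names(data)))
    data[[v]] <- scale_values(scaler, v, data[[v]])
  data
}

#' @rdname scale_table
#' @export
unscale_table <- function(scaler, data) {
  for (v in intersect(scaler$name, names(data)))
    data[[v]] <- unscale_values(scaler, v, data[[v]])
  data
}

#' Multiplicative noise augmentation
#'
#' Produces `copies` noised replicates of every record: each numeric value
#' `x` is replaced by `x * (1 + u)` with `u ~ Uniform(-amplitude, +amplitude)`
#' drawn independently per cell. "Amplitude" is read as a bounded relative
#' band, and multiplicative noise keeps zero-valued covariates at exactly
#' zero. Id and label columns are preserved; by default the `dQTc` output is
#' noised along with the inputs (`exempt` can exclude it). With
#' `amplitude = 0` the function returns exact duplicates.
#'
#' The noised set is intended for model stability testing; it can equally be
#' appended to a training set for augmentation.
#'
#' @param data Data frame of records.
#' @param amplitude Relative half-width of the noise band (default 0.05,
#'   i.e. +/-5 percent).
#' @param copies Number of noised replicates of the table (default 2).
#' @param seed Integer seed; required.
#' @param exempt Character vector of columns to pass through unnoised
#'   (besides the always-exempt `patient_id` and `arm`).
#' @return Data frame with `copies * nrow(data)` rows.
#' @export
add_noise <- function(data, amplitude = 0.05, copies = 2L, seed,
                      exempt = character()) {
  if (missing(seed) || is.null(seed)) stop("a seed is required to add noise")
  if (amplitude < 0) stop("amplitude must be non-negative")
  if (copies < 1) stop("copies must be at least 1")
  exempt <- union(exempt, c("patient_id", "arm"))
  num_cols <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                      exempt)
  set.seed(as.integer(seed))
  out <- do.call(rbind, lapply(seq_len(copies), function(k) {
    rep_k <- data
    for (v in num_cols) {
      u <- stats::runif(nrow(rep_k), -amplitude, amplitude)
      rep_k[[v]] <- rep_k[[v]] * (1 + u)
    }
    rep_k
  }))
  rownames(out) <- NULL
  out
}

#' Leave-one-inhibitor-out fold assignment
#'
#' Splits records into grouped cross-validation folds keyed by treatment arm:
#' fold *k* trains on every record except those of arm *k* and tests on arm
#' *k*, forcing the model to predict the QTc response of a drug-drug
#' combination it has never seen. The default contract expects exactly 8 arms
#' (the published scheme); other group counts need `allow_other = TRUE`.
#'
#' @param arm_labels Character vector, one arm label per record.
#' @param allow_other Allow a number of distinct arms other than 8.
#' @return A named list (one element per arm, in first-appearance order of
#'   sorted label) of lists with integer index vectors `train` and `test`.
#'   Folds are keyed by label, so they are invariant to row order.
#' @export
make_loio_folds <- function(arm_labels, allow_other = FALSE) {
  arms <- sort(unique(arm_labels))
  if (length(arms) != 8L && !allow_other)
    stop("expected exactly 8 treatment arms, got ", length(arms),
         "; set allow_other = TRUE to override")
  idx <- seq_along(arm_labels)
  folds <- lapply(arms, function(a)
    list(arm = a, train = idx[arm_labels != a], test = idx[arm_labels == a]))
  names(folds) <- arms
  folds
}
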