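#' Quantile-knot sampler for one variable
#'
#' Builds a sampler whose marginal distribution is anchored to a published
#' five-number summary. Continuous variables use a piecewise-linear
#' inverse CDF through the probability knots (0, 0.25, 0.5, 0.75, 1) at
#' (`vmin`, `q25`, `median`, `q75`, `vmax`); constant variables are degenerate
#' at zero; binary variables are Bernoulli with success probability equal to
#' the published mean. Draws from a continuous sampler never leave
#' `[vmin, vmax]` and reproduce the summary quantiles in distribution.
#'
#' @param spec A single-row data frame as returned by [reference_specs()], or
#'   a list with fields `name`, `vmin`, `q25`, `median`, `q75`, `vmax`,
#'   `mean`, `vclass`.
#' @param repair If `TRUE`, a non-monotone set of quantile knots (as printed
#'   for the `Gut_CYP2C9` row, whose minimum exceeds its first quartile) is
#'   repaired by sorting the five knots; if `FALSE` (default) non-monotone
#'   knots are a validation error.
#' @return An object of class `quantile_sampler` with a `$draw(n)` function.
#'   `draw()` consumes the R random-number stream (`runif`), so set the seed
#'   before drawing for reproducibility.
#' @examples
#' k <- reference_specs()
#' s <- quantile_sampler(k[k$name == "K", ])
#' set.seed(1); median(s$draw(1e4))
#' @export
quantile_sampler <- function(spec, repair = FALSE) {
  spec <- as.list(spec)
  knots <- as.numeric(spec[c("vmin", "q25", "median", "q75", "vmax")])
  vclass <- spec$vclass
  if (vclass == "continuous") {
    if (any(diff(knots) < 0)) {
      if (!repair)
        stop("non-monotone quantile knots for variable '", spec$name,
             "'; use repair = TRUE to sort them")
      knots <- sort(knots)
    }
    draw <- function(n) {
      stats::approx(x = c(0, 0.25, 0.5, 0.75, 1), y = knots,
                    xout = stats::runif(n), ties = "ordered")$y
    }
  } else if (vclass == "constant") {
    draw <- function(n) rep(0, n)
  } else if (vclass == "binary") {
    p <- as.numeric(spec$mean)
    if (p < 0 || p > 1) stop("binary variable mean must lie in [0, 1]")
    draw <- function(n) as.numeric(stats::runif(n) < p)
  } else {
    stop("unknown variable class: ", vclass)
  }
  structure(list(name = spec$name, vclass = vclass, knots = knots,
                 draw = draw),
            class = "quantile_sampler")
}

#' Sample a virtual-trial population table
#'
#' Generates a rectangular record set (patients x visits) whose marginal
#' distributions emulate the published data summary. Covariates are sampled
#' independently by default; a Gaussian-copula hook accepts a rank-correlation
#' matrix over a subset of continuous variables. The `dQTc` output is either
#' drawn from its own published marginal (`mode = "marginal"`) or computed
#' mechanistically from the sampled covariates through the white-box equation
#' (`mode = "mechanistic"`, see [predict_dqtc()]).
#'
#' The generator is a statistical stand-in for the proprietary
#' simulator-derived source data: it reproduces marginals, record counts and
#' arm structure, not joint structure, within-patient correlation or
#' pharmacology (the per-arm inhibition shift hook defaults to no shift).
#'
#' @param specs Specification table from [reference_specs()].
#' @param design A `trial_design`, see [default_design()].
#' @param seed Integer seed; required (reproducibility contract).
#' @param mode `"marginal"` or `"mechanistic"` for the `dQTc` column.
#' @param rank_corr Optional named rank-correlation matrix (Gaussian copula)
#'   over a subset of continuous variable names.
#' @param arm_shift Optional named list `list(<arm> = c(<variable> = factor))`
#'   of multiplicative shifts applied to inhibition columns per arm;
#'   default: no shift (marginals as published).
#' @param constants Model constants used in mechanistic mode.
#' @return A data frame with columns `patient_id`, `arm`, the 48 input
#'   variables in published order, and `dQTc`.
#' @examples
#' d <- default_design(n_patients = 5, total_records = 50)
#' pop <- sample_population(design = d, seed = 42)
#' nrow(pop)
#' @export
sample_population <- function(specs = reference_specs(),
                              design = default_design(),
                              seed,
                              mode = c("marginal", "mechanistic"),
                              rank_corr = NULL,
                              arm_shift = NULL,
                              constants = model_constants()) {
  if (missing(seed) || is.null(seed))
    stop("a seed is required to sample a population")
  mode <- match.arg(mode)
  validate_design(design)
  inputs <- specs[specs$role == "input", ]
  out_spec <- specs[specs$role == "output", ]

  alloc <- design$allocation
  patient_id <- rep(alloc$patient_id, alloc$n_records)
  arm <- rep(alloc$arm, alloc$n_records)
  n <- length(patient_id)

  set.seed(as.integer(seed))
  cols <- vector("list", nrow(inputs))
  names(cols) <- inputs$name
  corr_vars <- if (!is.null(rank_corr)) colnames(rank_corr) else character()
  if (length(corr_vars)) {
    bad <- setdiff(corr_vars, inputs$name[inputs$vclass == "continuous"])
    if (length(bad))
      stop("rank_corr names must be continuous variables; offending: ",
           paste(bad, collapse = ", "))
    z <- matrix(stats::rnorm(n * length(corr_vars)), n)
    ch <- chol(rank_corr)
    u <- stats::pnorm(z %*% ch)
    colnames(u) <- corr_vars
  }
  for (i in seq_len(nrow(inputs))) {
    sp <- inputs[i, ]
    smp <- quantile_sampler(sp, repair = TRUE)
    if (sp$name %in% corr_vars) {
      knots <- smp$knots
      cols[[sp$name]] <- stats::approx(c(0, 0.25, 0.5, 0.75, 1), knots,
                                       xout = u[, sp$name],
                                       ties = "ordered")$y
    } else {
      cols[[sp$name]] <- smp$draw(n)
    }
  }
  tab <- data.frame(patient_id = patient_id, arm = arm, cols,
                    check.names = FALSE, stringsAsFactors = FALSE)

  if (!is.null(arm_shift)) {
    for (a in names(arm_shift)) {
      idx <- tab$arm == a
      for (v in names(arm_shift[[a]]))
        tab[[v]][idx] <- tab[[v]][idx] * arm_shift[[a]][[v]]
    }
  }

  if (mode == "marginal") {
    tab$dQTc <- quantile_sampler(out_spec)$draw(n)
  } else {
    scaler <- fit_scaler(specs)
    tab$dQTc <- predict_dqtc(tab, constants = constants, scaler = scaler)
  }
  tab
}
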