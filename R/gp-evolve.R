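# Generation and variation of expression trees, the evolutionary loop with
# age-fitness-complexity Pareto survivor selection, and derivative-free
# refitting of the adjustable constants.

#' GP configuration
#'
#' Collects the tunable parameters of the symbolic-regression engine.
#' Defaults follow the published setup where one is stated (population 100,
#' individual size limit within 10-100, elite testing every
#' `1000 * population_size` fitness evaluations); the evaluation budget is a
#' knob, since the original hundred-million-step runs are far beyond desk
#' scale.
#'
#' @param population_size Individuals per generation (>= 2).
#' @param budget Total fitness-evaluation budget for [evolve()].
#' @param size_limit Maximum tree node count, must lie in `[10, 100]`.
#' @param elite_test_cadence Fitness evaluations between elite
#'   cross-validation / constant-refit events.
#' @param heuristic `"afc"` (age-fitness-complexity Pareto survivor
#'   selection with random-individual injection) or `"apt"` (archive-based
#'   Pareto tournament of size 4 on fitness and complexity). Both are
#'   approximations of the cited search heuristics, whose internal defaults
#'   are not published.
#' @param constant_range Range for freshly generated constants.
#' @param p_crossover Probability an offspring comes from crossover rather
#'   than mutation.
#' @param p_const Probability a generated leaf is a constant slot.
#' @param n_random Fresh random individuals injected per generation
#'   (age-layering pressure; `"afc"` only).
#' @param elite_n Number of elite individuals tested/refitted per cadence
#'   event.
#' @param stop_fitness Early-stop threshold on training RMSE (`NULL` to
#'   disable).
#' @param max_depth Depth bound for freshly generated trees.
#' @return A list of class `gp_config`.
#' @export
gp_config <- function(population_size = 100L, budget = 2e4,
                      size_limit = 64L, elite_test_cadence = NULL,
                      heuristic = c("afc", "apt"),
                      constant_range = c(-5, 5), p_crossover = 0.7,
                      p_const = 0.2, n_random = 2L, elite_n = 5L,
                      stop_fitness = NULL, max_depth = 4L) {
  heuristic <- match.arg(heuristic)
  if (population_size < 2L) stop("population_size must be at least 2")
  if (size_limit < 10L || size_limit > 100L)
    stop("size_limit must lie in [10, 100]")
  if (is.null(elite_test_cadence))
    elite_test_cadence <- 1000L * population_size
  structure(list(population_size = as.integer(population_size),
                 budget = budget, size_limit = as.integer(size_limit),
                 elite_test_cadence = elite_test_cadence,
                 heuristic = heuristic, constant_range = constant_range,
                 p_crossover = p_crossover, p_const = p_const,
                 n_random = as.integer(n_random),
                 elite_n = as.integer(elite_n),
                 stop_fitness = stop_fitness,
                 max_depth = as.integer(max_depth)),
            class = "gp_config")
}

#' Random tree generation
#'
#' Grow-style generation over the function set
#' `{add, mul, neg, sin, exp_protected}` with variable and constant leaves.
#' Generation consumes the R random-number stream; seed it for
#' reproducibility. The result always respects `config$size_limit`.
#'
#' @param vars Character vector of admissible variable names.
#' @param config A [gp_config()].
#' @param depth Maximum remaining depth (internal recursion parameter).
#' @return An expression tree.
#' @export
random_tree <- function(vars, config = gp_config(), depth = config$max_depth) {
  make_leaf <- function() {
    if (stats::runif(1) < config$p_const)
      gp_const(stats::runif(1, config$constant_range[1],
                            config$constant_range[2]))
    else gp_var(sample(vars, 1L))
  }
  grow <- function(d) {
    if (d <= 0L || stats::runif(1) < 0.3) return(make_leaf())
    op <- sample(c("add", "mul", "neg", "sin", "pexp"), 1L,
                 prob = c(0.3, 0.3, 0.1, 0.2, 0.1))
    if (op %in% .gp_binary) gp_node(op, grow(d - 1L), grow(d - 1L))
    else gp_node(op, grow(d - 1L))
  }
  for (i in 1:20) {
    t <- grow(depth)
    if (tree_size(t) <= config$size_limit) return(t)
  }
  make_leaf()
}

# Enumerate node paths; a path is an integer vector of child indices
# (1 = $a, 2 = $b), root = integer(0).
node_paths <- function(tree) {
  out <- list(integer())
  if (tree$op %in% .gp_binary) {
    out <- c(out, lapply(node_paths(tree$a), function(p) c(1L, p)),
             lapply(node_paths(tree$b), function(p) c(2L, p)))
  } else if (tree$op %in% .gp_unary) {
    out <- c(out, lapply(node_paths(tree$a), function(p) c(1L, p)))
  }
  out
}

get_subtree <- function(tree, path) {
  for (i in path) tree <- if (i == 1L) tree$a else tree$b
  tree
}

set_subtree <- function(tree, path, sub) {
  if (!length(path)) return(sub)
  slot <- if (path[1L] == 1L) "a" else "b"
  tree[[slot]] <- set_subtree(tree[[slot]], path[-1L], sub)
  tree
}

#' Subtree crossover
#'
#' Swaps a random subtree of `a` with a random subtree of `b`. Offspring
#' exceeding the size limit are rejected and the cut points resampled; after
#' `retries` failures a copy of `a` is returned unchanged.
#'
#' @param a,b Parent trees.
#' @param config A [gp_config()].
#' @param retries Resampling attempts before giving up.
#' @return An offspring tree within the size limit.
#' @export
crossover <- function(a, b, config = gp_config(), retries = 10L) {
  pa <- node_paths(a)
  pb <- node_paths(b)
  for (i in seq_len(retries)) {
    child <- set_subtree(a, pa[[sample.int(length(pa), 1L)]],
                         get_subtree(b, pb[[sample.int(length(pb), 1L)]]))
    if (tree_size(child) <= config$size_limit) return(child)
  }
  a
}

#' Mutation
#'
#' Three mutation kinds: `"point"` swaps one operator for another of the same
#' arity (or one variable for another), `"subtree"` replaces a random node
#' with a freshly grown subtree (size-checked), `"jitter"` perturbs one
#' constant multiplicatively (`value * (1 + N(0, sd))`, additive `N(0, sd)`
#' at zero) and never changes structure. `"any"` picks a kind at random,
#' falling back from `"jitter"` when the tree has no constants.
#'
#' @param tree Tree to mutate.
#' @param vars Admissible variable names.
#' @param config A [gp_config()].
#' @param kind Mutation kind.
#' @param sd Jitter standard deviation.
#' @return A mutated tree within the size limit.
#' @export
mutate <- function(tree, vars, config = gp_config(),
                   kind = c("any", "point", "subtree", "jitter"), sd = 0.1) {
  kind <- match.arg(kind)
  if (kind == "any")
    kind <- sample(c("point", "subtree", "jitter"), 1L,
                   prob = c(0.4, 0.4, 0.2))
  if (kind == "jitter" && n_constants(tree) == 0L) kind <- "point"
  paths <- node_paths(tree)
  if (kind == "jitter") {
    k <- get_constants(tree)
    i <- sample.int(length(k), 1L)
    k[i] <- if (k[i] == 0) stats::rnorm(1, 0, sd)
            else k[i] * (1 + stats::rnorm(1, 0, sd))
    return(set_constants(tree, k))
  }
  if (kind == "subtree") {
    for (r in 1:10) {
      p <- paths[[sample.int(length(paths), 1L)]]
      child <- set_subtree(tree, p, random_tree(vars, config, depth = 2L))
      if (tree_size(child) <= config$size_limit) return(child)
    }
    return(tree)
  }
  # point mutation
  p <- paths[[sample.int(length(paths), 1L)]]
  node <- get_subtree(tree, p)
  node <- switch(node$op,
                 var = gp_var(sample(vars, 1L)),
                 const = gp_const(stats::runif(1, config$constant_range[1],
                                               config$constant_range[2])),
                 add = { node$op <- "mul"; node },
                 mul = { node$op <- "add"; node },
                 { node$op <- sample(setdiff(.gp_unary, node$op), 1L); node })
  set_subtree(tree, p, node)
}

rmse <- function(obs, pred) sqrt(mean((pred - obs)^2))

gp_fitness <- function(cl, data_env, response) {
  pred <- eval_tree_call(cl, data_env)
  if (length(pred) == 1L) pred <- rep(pred, length(response))
  if (!all(is.finite(pred))) return(Inf)
  rmse(response, pred)
}

new_individual <- function(tree, fitness = NA_real_, age = 0L) {
  list(tree = tree, call = tree_to_call(tree), fitness = fitness,
       complexity = tree_size(tree), age = age, cv_error = NA_real_)
}

# Pareto helpers: objectives in columns, smaller is better.
dominates <- function(x, y) all(x <= y) && any(x < y)

nondominated_mask <- function(m) {
  n <- nrow(m)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && keep[i] && dominates(m[j, ], m[i, ])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  keep
}

objective_matrix <- function(pop, objectives) {
  m <- cbind(fitness = vapply(pop, `[[`, numeric(1), "fitness"),
             complexity = vapply(pop, function(i) as.numeric(i$complexity),
                                 numeric(1)),
             age = vapply(pop, function(i) as.numeric(i$age), numeric(1)))
  m[, objectives, drop = FALSE]
}

# Non-dominated sorting fill (NSGA-style) used for survivor selection.
pareto_fill <- function(pop, n, objectives) {
  selected <- list()
  remaining <- pop
  while (length(selected) < n && length(remaining)) {
    m <- objective_matrix(remaining, objectives)
    front <- which(nondominated_mask(m))
    if (length(selected) + length(front) <= n) {
      selected <- c(selected, remaining[front])
      remaining <- remaining[-front]
    } else {
      need <- n - length(selected)
      fit <- m[front, "fitness"]
      selected <- c(selected, remaining[front[order(fit)][seq_len(need)]])
      remaining <- list()
    }
  }
  selected
}

#' Derivative-free refitting of a tree's constants
#'
#' Minimizes training RMSE over the tree's constant slots with seeded
#' multi-start Nelder-Mead simplex search. Starts are the supplied (or
#' embedded) values plus `n_starts - 1` random reinitializations spread by
#' `spread` around them; each constant is softly bounded to ten times the
#' magnitude of its initial value (a floor of 10 applies near zero) via a
#' quadratic penalty. The best start wins; the search is deterministic given
#' `seed`.
#'
#' @param tree Expression tree with at least one constant slot.
#' @param data Data frame of covariates.
#' @param response Observed response vector.
#' @param seed Integer seed; required.
#' @param init Initial constants (default: the tree's embedded values).
#' @param n_starts Number of starts (first = `init` itself).
#' @param spread Relative half-width of the random reinitialization band.
#' @param maxit Nelder-Mead iteration cap per start.
#' @return List with `constants`, `rmse`, and `tree` (constants written
#'   back).
#' @export
optimize_constants <- function(tree, data, response, seed,
                               init = get_constants(tree), n_starts = 5L,
                               spread = 0.5, maxit = 1000L) {
  k <- n_constants(tree)
  if (k == 0L) stop("tree has no adjustable constants")
  if (missing(seed) || is.null(seed))
    stop("a seed is required for constant optimization")
  stopifnot(length(init) == k)
  bound <- pmax(10 * abs(init), 10)
  obj <- function(cc) {
    t2 <- set_constants(tree, cc)
    pred <- eval_tree_call(tree_to_call(t2), data)
    if (length(pred) == 1L) pred <- rep(pred, length(response))
    if (!all(is.finite(pred))) return(1e12)
    pen <- sum(pmax(abs(cc) - bound, 0)^2)
    rmse(response, pred) + pen
  }
  set.seed(as.integer(seed))
  starts <- c(list(init), lapply(seq_len(n_starts - 1L), function(i) {
    ifelse(init == 0,
           stats::runif(k, -spread, spread),
           init * (1 + stats::runif(k, -spread, spread)))
  }))
  best <- NULL
  any_finite <- FALSE
  for (s in starts) {
    if (!is.finite(obj(s))) next
    if (k == 1L) {
      # Brent line search: the derivative-free choice for a single constant
      fit <- stats::optim(s, obj, method = "Brent",
                          lower = -bound, upper = bound,
                          control = list(maxit = maxit))
    } else {
      fit <- stats::optim(s, obj, method = "Nelder-Mead",
                          control = list(maxit = maxit, reltol = 1e-12))
      # one restart from the incumbent tightens convergence of the simplex
      fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                          control = list(maxit = maxit, reltol = 1e-12))
    }
    any_finite <- TRUE
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (!any_finite || is.null(best))
    stop("objective non-finite at every start")
  list(constants = best$par, rmse = best$value,
       tree = set_constants(tree, best$par))
}

cv_error_tree <- function(tree, data, response, folds, seed) {
  errs <- vapply(folds, function(f) {
    t2 <- tree
    if (n_constants(tree) > 0L) {
      fit <- try(optimize_constants(tree, data[f$train, , drop = FALSE],
                                    response[f$train], seed = seed,
                                    n_starts = 2L, maxit = 200L),
                 silent = TRUE)
      if (!inherits(fit, "try-error")) t2 <- fit$tree
    }
    pred <- eval_tree_call(tree_to_call(t2), data[f$test, , drop = FALSE])
    if (length(pred) == 1L) pred <- rep(pred, length(f$test))
    if (!all(is.finite(pred))) return(Inf)
    rmse(response[f$test], pred)
  }, numeric(1))
  mean(errs)
}

#' Evolve symbolic-regression models
#'
#' Runs the genetic-programming loop on a (scaled) training table: random
#' initialization, subtree crossover and point/subtree/jitter mutation,
#' survivor selection by the configured Pareto heuristic, and — every
#' `elite_test_cadence` fitness evaluations — testing of the current elite
#' under the supplied grouped cross-validation folds with random
#' reinitialization and refitting of their constants. An archive of mutually
#' non-dominated individuals (training RMSE, complexity, age at insertion)
#' is maintained throughout and returned.
#'
#' @param data Data frame of covariates (typically on the 0.1-0.9 scale).
#' @param response Observed response vector (raw milliseconds by default in
#'   this package's pipeline).
#' @param config A [gp_config()].
#' @param folds Optional fold assignment ([make_loio_folds()]) for elite
#'   generalization testing.
#' @param seed Integer seed; required.
#' @param vars Variable names available to the evolution (default: all
#'   columns of `data`).
#' @return A list of class `gp_archive`: `archive` (list of individuals,
#'   mutually non-dominated), `best` (lowest training RMSE seen),
#'   `evaluations` (fitness evaluations spent), `config`.
#' @export
evolve <- function(data, response, config = gp_config(), folds = NULL,
                   seed, vars = names(data)) {
  if (missing(seed) || is.null(seed)) stop("a seed is required to evolve")
  if (config$budget < config$population_size)
    stop("budget smaller than one generation")
  set.seed(as.integer(seed))
  data_env <- list2env(as.list(data[vars]))
  evals <- 0L
  evaluate <- function(ind) {
    ind$fitness <- gp_fitness(ind$call, data_env, response)
    evals <<- evals + 1L
    ind
  }
  pop <- lapply(seq_len(config$population_size), function(i)
    evaluate(new_individual(random_tree(vars, config))))
  archive <- list()
  update_archive <- function(archive, pool) {
    cand <- c(archive, pool)
    m <- objective_matrix(cand, c("fitness", "complexity", "age"))
    keep <- is.finite(m[, "fitness"]) & nondominated_mask(m)
    cand <- cand[keep]
    # drop exact duplicates (same serialized genotype)
    sig <- vapply(cand, function(i) tree_to_prefix(i$tree), character(1))
    cand <- cand[!duplicated(sig)]
    if (length(cand) > 50L) {
      ord <- order(vapply(cand, `[[`, numeric(1), "fitness"))
      cand <- cand[ord[1:50]]
    }
    cand
  }
  archive <- update_archive(archive, pop)
  next_elite_mark <- config$elite_test_cadence

  elite_pass <- function(pop) {
    ord <- order(vapply(pop, `[[`, numeric(1), "fitness"))
    for (i in ord[seq_len(min(config$elite_n, length(pop)))]) {
      ind <- pop[[i]]
      if (n_constants(ind$tree) > 0L) {
        fit <- try(optimize_constants(ind$tree, data, response,
                                      seed = seed + evals + i,
                                      n_starts = 3L, maxit = 300L),
                   silent = TRUE)
        if (!inherits(fit, "try-error") && fit$rmse < ind$fitness) {
          ind$tree <- fit$tree
          ind$call <- tree_to_call(fit$tree)
          ind$fitness <- fit$rmse
        }
      }
      if (!is.null(folds))
        ind$cv_error <- cv_error_tree(ind$tree, data, response, folds,
                                      seed = seed + evals + i)
      pop[[i]] <- ind
    }
    pop
  }

  repeat {
    best_fit <- min(vapply(pop, `[[`, numeric(1), "fitness"))
    if (!is.null(config$stop_fitness) && best_fit <= config$stop_fitness)
      break
    if (evals >= config$budget) break

    n_off <- config$population_size -
      if (config$heuristic == "afc") config$n_random else 0L
    offspring <- vector("list", n_off)
    for (i in seq_len(n_off)) {
      if (config$heuristic == "apt") {
        pick <- function() {
          cand <- sample.int(length(pop), min(4L, length(pop)))
          m <- objective_matrix(pop[cand], c("fitness", "complexity"))
          nd <- which(nondominated_mask(m))
          pop[[cand[nd[sample.int(length(nd), 1L)]]]]
        }
        p1 <- pick(); p2 <- pick()
      } else {
        ij <- sample.int(length(pop), 2L)
        p1 <- pop[[ij[1L]]]; p2 <- pop[[ij[2L]]]
      }
      if (stats::runif(1) < config$p_crossover) {
        child_tree <- crossover(p1$tree, p2$tree, config)
        child_age <- max(p1$age, p2$age)
      } else {
        child_tree <- mutate(p1$tree, vars, config)
        child_age <- p1$age
      }
      offspring[[i]] <- evaluate(new_individual(child_tree, age = child_age))
    }
    if (config$heuristic == "afc" && config$n_random > 0L) {
      offspring <- c(offspring, lapply(seq_len(config$n_random), function(i)
        evaluate(new_individual(random_tree(vars, config)))))
    }
    pool <- c(pop, offspring)
    objectives <- if (config$heuristic == "afc")
      c("fitness", "complexity", "age") else c("fitness", "complexity")
    pop <- pareto_fill(pool, config$population_size, objectives)
    pop <- lapply(pop, function(ind) { ind$age <- ind$age + 1L; ind })

    if (evals >= next_elite_mark) {
      pop <- elite_pass(pop)
      next_elite_mark <- next_elite_mark + config$elite_test_cadence
    }
    archive <- update_archive(archive, pop)
  }
  # final elite pass so the archive front carries cv_error where folds exist
  pop <- elite_pass(pop)
  archive <- update_archive(archive, pop)
  best <- archive[[which.min(vapply(archive, `[[`, numeric(1), "fitness"))]]
  structure(list(archive = archive, best = best, evaluations = evals,
                 config = config),
            class = "gp_archive")
}

#' @export
print.gp_archive <- function(x, ...) {
  cat("GP archive:", length(x$archive), "non-dominated individuals,",
      x$evaluations, "fitness evaluations\n")
  cat("best training RMSE:", format(x$best$fitness), "| complexity",
      x$best$complexity, "\n")
  invisible(x)
}

#' Final model selection from a Pareto archive
#'
#' Operationalizes the multivariate selection criterion (generalization
#' error, complexity, number of adjustable parameters): candidates are first
#' Pareto-filtered on those three objectives, then all candidates whose
#' cross-validated error lies within a relative `band` of the best are
#' considered equivalent, and ties break by minimum complexity, then by
#' fewest constants, then by cv error itself.
#'
#' @param archive A `gp_archive` from [evolve()], or a bare list of
#'   individuals carrying `cv_error`.
#' @param band Relative cv-error equivalence band (default 0.05).
#' @return The selected individual.
#' @export
select_final <- function(archive, band = 0.05) {
  cand <- if (inherits(archive, "gp_archive")) archive$archive else archive
  cand <- cand[vapply(cand, function(i) is.finite(i$cv_error), logical(1))]
  if (!length(cand)) stop("archive holds no individuals with a cv error")
  m <- cbind(vapply(cand, `[[`, numeric(1), "cv_error"),
             vapply(cand, function(i) as.numeric(i$complexity), numeric(1)),
             vapply(cand, function(i) as.numeric(n_constants(i$tree)),
                    numeric(1)))
  cand <- cand[nondominated_mask(m)]
  m <- m[nondominated_mask(m), , drop = FALSE]
  best_cv <- min(m[, 1L])
  in_band <- m[, 1L] <= best_cv * (1 + band)
  ord <- order(!in_band, m[, 2L], m[, 3L], m[, 1L])
  cand[[ord[1L]]]
}
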