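test_that("tree evaluation matches base R's evaluator on random genotypes", {
  cfg <- gp_config(size_limit = 30L)
  set.seed(61)
  X <- data.frame(x1 = runif(100, -3, 3), x2 = runif(100, -3, 3),
                  x3 = runif(100, -3, 3))
  worst <- 0
  for (i in 1:200) {
    tr <- random_tree(c("x1", "x2", "x3"), cfg)
    a <- eval_tree(tr, X)
    b <- eval_tree_call(tree_to_call(tr), X)
    worst <- max(worst, max(abs(a - b)))
  }
  expect_lt(worst, 1e-10)
})

test_that("identity, clamping and constant-override semantics hold", {
  X <- data.frame(x1 = c(-2, 0, 1000))
  expect_identical(eval_tree(gp_var("x1"), X), X$x1)
  # protected exponential clamps at 50
  pe <- gp_node("pexp", gp_var("x1"))
  expect_equal(eval_tree(pe, X)[3], exp(50))
  expect_true(all(is.finite(eval_tree(pe, X))))
  # constants override in pre-order
  tr <- gp_node("add", gp_const(1), gp_node("mul", gp_const(2), gp_var("x1")))
  expect_equal(get_constants(tr), c(1, 2))
  expect_equal(eval_tree(tr, X, constants = c(10, 3)), 10 + 3 * X$x1)
  expect_error(eval_tree(gp_var("nope"), X), "unknown variable")
})

test_that("prefix serialization round-trips trees exactly", {
  cfg <- gp_config(size_limit = 40L)
  set.seed(62)
  X <- data.frame(x1 = runif(20), x2 = runif(20))
  for (i in 1:50) {
    tr <- random_tree(c("x1", "x2"), cfg)
    back <- prefix_to_tree(tree_to_prefix(tr))
    expect_identical(tree_to_prefix(back), tree_to_prefix(tr))
    expect_equal(eval_tree(back, X), eval_tree(tr, X), tolerance = 1e-12)
  }
  expect_error(prefix_to_tree("(foo x1)"), "unknown operator")
})

test_that("variation operators respect the size limit and the seed", {
  cfg <- gp_config(size_limit = 12L)
  set.seed(63)
  for (i in 1:100) {
    a <- random_tree(c("x1", "x2"), cfg)
    b <- random_tree(c("x1", "x2"), cfg)
    expect_lte(tree_size(crossover(a, b, cfg)), 12L)
    expect_lte(tree_size(mutate(a, c("x1", "x2"), cfg)), 12L)
  }
  # fixed seed => identical offspring
  a <- random_tree(c("x1", "x2"), cfg)
  b <- random_tree(c("x1", "x2"), cfg)
  set.seed(64)
  c1 <- crossover(a, b, cfg)
  set.seed(64)
  c2 <- crossover(a, b, cfg)
  expect_identical(tree_to_prefix(c1), tree_to_prefix(c2))
  # jitter mutation moves a constant, never the structure
  tr <- gp_node("mul", gp_const(1.5), gp_var("x1"))
  set.seed(65)
  mt <- mutate(tr, "x1", cfg, kind = "jitter")
  expect_identical(mt$op, "mul")
  expect_identical(mt$b$name, "x1")
  expect_false(mt$a$value == 1.5)
})

test_that("constant optimization recovers planted coefficients", {
  set.seed(66)
  X <- data.frame(x1 = runif(200, -2, 2), x2 = runif(200, -2, 2))
  # linear: c1 * x1 on y = 3 x1
  tr1 <- gp_node("mul", gp_const(1), gp_var("x1"))
  fit1 <- optimize_constants(tr1, X, 3 * X$x1, seed = 67)
  expect_equal(fit1$constants, 3, tolerance = 1e-6)
  # two constants, noiseless: recovered to 1e-4
  tr2 <- gp_node("add",
                 gp_node("mul", gp_const(1), gp_node("sin", gp_var("x1"))),
                 gp_node("mul", gp_const(1), gp_var("x2")))
  y2 <- 1.5 * sin(X$x1) + 2.5 * X$x2
  fit2 <- optimize_constants(tr2, X, y2, seed = 68)
  expect_equal(fit2$constants, c(1.5, 2.5), tolerance = 1e-4)
  expect_lt(fit2$rmse, 1e-6)
  # a tree without constant slots is a contract violation
  expect_error(optimize_constants(gp_var("x1"), X, X$x1, seed = 69),
               "no adjustable constants")
})

test_that("evolution is reproducible, Pareto-consistent and improves with budget", {
  set.seed(70)
  dat <- data.frame(x1 = runif(300, -3, 3), x2 = runif(300, -3, 3))
  y <- sin(dat$x1) + 2 * dat$x2
  cfg_small <- gp_config(population_size = 40L, budget = 1500,
                         size_limit = 16L, n_random = 2L)
  a1 <- evolve(dat, y, cfg_small, seed = 71)
  a2 <- evolve(dat, y, cfg_small, seed = 71)
  expect_identical(tree_to_prefix(a1$best$tree), tree_to_prefix(a2$best$tree))
  expect_identical(a1$best$fitness, a2$best$fitness)

  # archive members are mutually non-dominated in (fitness, complexity, age)
  m <- cbind(vapply(a1$archive, `[[`, numeric(1), "fitness"),
             vapply(a1$archive, function(i) as.numeric(i$complexity),
                    numeric(1)),
             vapply(a1$archive, function(i) as.numeric(i$age), numeric(1)))
  for (i in seq_len(nrow(m))) for (j in seq_len(nrow(m))) if (i != j)
    expect_false(all(m[j, ] <= m[i, ]) && any(m[j, ] < m[i, ]))

  # archive best is non-increasing along the evaluation budget (shared seed)
  a3 <- evolve(dat, y, gp_config(population_size = 40L, budget = 4000,
                                 size_limit = 16L, n_random = 2L), seed = 71)
  expect_lte(a3$best$fitness, a1$best$fitness)

  expect_error(evolve(dat, y, gp_config(population_size = 40L, budget = 10),
                      seed = 72), "budget")
  expect_error(evolve(dat, y, cfg_small), "seed")
})

test_that("the archive-tournament heuristic also drives error down", {
  set.seed(73)
  dat <- data.frame(x1 = runif(200, -2, 2))
  y <- 2 * dat$x1
  cfg <- gp_config(population_size = 30L, budget = 3000, size_limit = 12L,
                   heuristic = "apt", stop_fitness = 1e-8)
  a <- evolve(dat, y, cfg, seed = 74)
  expect_lt(a$best$fitness, 0.5)
})

test_that("final selection applies the cv-band / complexity / constants rule", {
  mk <- function(cv, complexity, k) {
    tr <- Reduce(function(x, y) gp_node("add", x, y),
                 c(lapply(seq_len(k), function(i) gp_const(i)),
                   list(gp_var("x1"))))
    list(tree = tr, call = tree_to_call(tr), fitness = cv,
         complexity = complexity, age = 0L, cv_error = cv)
  }
  cands <- list(mk(0.10, 20, 3), mk(0.104, 12, 2), mk(0.20, 5, 1))
  sel <- select_final(cands)
  expect_equal(sel$complexity, 12)
  # equal cv, complexities 12 vs 30 -> pick 12
  pair <- list(mk(0.5, 30, 1), mk(0.5, 12, 1))
  expect_equal(select_final(pair)$complexity, 12)
  # a dominated candidate is never selected
  dom <- list(mk(0.1, 10, 1), mk(0.2, 20, 2))
  expect_equal(select_final(dom)$cv_error, 0.1)
  expect_error(select_final(list()), "cv error")
})

test_that("the published equation is expressible and evaluable as a genotype", {
  tr <- dqtc_tree()
  X <- random_scaled_records(200, seed = 75)
  expect_equal(eval_tree(tr, X), eval_dqtc(X), tolerance = 1e-10)
  expect_equal(sort(tree_variables(tr)), sort(eq_labels))
  expect_equal(n_constants(tr), 4L)
  expect_lte(tree_size(tr), 100L)
})
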