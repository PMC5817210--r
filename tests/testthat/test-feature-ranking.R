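test_that("permutation importance separates used from unused inputs", {
  set.seed(41)
  n <- 1000
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  pf <- function(dd) 3 * dd$x1 + 1 * dd$x2
  y <- pf(d) + rnorm(n, 0, 0.1)
  rep1 <- permutation_importance(pf, d, y, repeats = 5L, seed = 42)
  expect_s3_class(rep1, "importance_report")
  expect_true(all(rep1$importance >= 0))
  expect_gt(rep1$importance[["x1"]], rep1$importance[["x2"]])
  expect_lt(rep1$importance[["x3"]], 0.05 * rep1$importance[["x1"]])
  expect_gt(rep1$error, 0)

  # invariant to column order up to the permutation seed
  rep2 <- permutation_importance(pf, d[c("x3", "x1", "x2")], y,
                                 repeats = 5L, seed = 42)
  expect_equal(sort(names(rep2$importance)), sort(names(rep1$importance)))
  expect_equal(rank(-rep2$importance[names(rep1$importance)]),
               rank(-rep1$importance), ignore_attr = TRUE)

  expect_error(permutation_importance(pf, d, rep(1, n), seed = 1),
               "constant")
})

test_that("aggregation weights learners by inverse global error", {
  imp <- c(x1 = 5, x2 = 3, x3 = 2)
  r1 <- structure(list(learner = "a", importance = imp, error = 1,
                       metric = "rmse"), class = "importance_report")
  r2 <- structure(list(learner = "b", importance = imp, error = 2,
                       metric = "rmse"), class = "importance_report")

  single <- scale_and_aggregate(r1)
  expect_identical(single$variable, c("x1", "x2", "x3"))

  both <- scale_and_aggregate(list(r1, r2))
  expect_identical(both$variable, c("x1", "x2", "x3"))
  # normalized shares (.5,.3,.2); weights 1 and 1/2 => totals (.75,.45,.3)
  expect_equal(both$importance, c(0.75, 0.45, 0.3))

  # scale invariance: multiplying one learner's raw vector changes nothing
  r1b <- r1
  r1b$importance <- imp * 1000
  expect_equal(scale_and_aggregate(list(r1b, r2)), both)

  # a learner with huge error contributes negligibly
  r3 <- r2
  r3$error <- 1e9
  r3$importance <- c(x1 = 0, x2 = 0, x3 = 1)
  agg <- scale_and_aggregate(list(r1, r3))
  expect_identical(agg$variable[1], "x1")

  r0 <- r1
  r0$importance <- imp * 0
  expect_warning(scale_and_aggregate(list(r1, r0)), "all-zero")
  expect_error(suppressWarnings(scale_and_aggregate(list(r0))), "zero")
})

test_that("the importance-drop cut-off keeps the prefix above the last big drop", {
  rk <- data.frame(variable = c("a", "b", "c", "d"),
                   importance = c(50, 30, 19, 1))
  sel <- apply_cutoff(rk, threshold = 0.05)
  expect_identical(as.character(sel), c("a", "b", "c"))
  # every qualifying drop is reported as a candidate cut point
  expect_equal(attr(sel, "cutpoints"), c(1L, 2L, 3L))

  flat <- data.frame(variable = letters[1:4], importance = rep(2, 4))
  expect_identical(as.character(apply_cutoff(flat)), letters[1:4])
  one <- data.frame(variable = "a", importance = 3)
  expect_identical(as.character(apply_cutoff(one)), "a")
  expect_error(apply_cutoff(one[0, ]), "empty")

  # share rule alternative
  expect_identical(apply_cutoff(rk, threshold = 0.05, rule = "share"),
                   c("a", "b", "c"))
  expect_identical(apply_cutoff(rk, threshold = 0.25, rule = "share"),
                   c("a", "b"))
})

test_that("a planted additive model selects exactly its active inputs", {
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 1000
    d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
    y <- 5 * d$x1 + 2 * d$x2 + rnorm(n, 0, 0.1)
    fit <- lm(y ~ ., data = d)
    pf <- function(dd) unname(predict(fit, newdata = dd))
    rk <- scale_and_aggregate(
      permutation_importance(pf, d, y, repeats = 5L, seed = s + 100))
    sel <- apply_cutoff(rk)
    ("x1" %in% sel) && ("x2" %in% sel) && !("x3" %in% sel)
  }, logical(1))
  expect_gte(sum(hits), 9L)
})
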