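test_that("packaged summary specifications match the published table", {
  specs <- reference_specs()
  expect_equal(nrow(specs), 49L)
  expect_equal(sum(specs$role == "input"), 48L)

  k <- specs[specs$name == "K", ]
  expect_equal(unlist(k[c("vmin", "q25", "median", "mean", "q75", "vmax")],
                      use.names = FALSE),
               c(3.053, 4.079, 4.268, 4.261, 4.451, 5.363))
  expect_equal(k$vclass, "continuous")

  cyp <- specs[specs$name == "CYP2A6", ]
  expect_equal(cyp$vclass, "constant")
  expect_true(all(cyp[c("vmin", "q25", "median", "mean", "q75", "vmax")] == 0))

  expect_equal(specs$vclass[specs$name == "Sex_Code"], "binary")
  expect_equal(specs$name[specs$role == "output"], "dQTc")
  # quantile knots are monotone for every row except the known typo
  knots <- as.matrix(specs[, c("vmin", "q25", "median", "q75", "vmax")])
  mono <- apply(knots, 1, function(x) !is.unsorted(x))
  expect_identical(specs$name[!mono], "Gut_CYP2C9")
})

test_that("quantile sampler reproduces its knots and respects bounds", {
  s <- quantile_sampler(make_spec("toy", c(0, 1, 2, 3, 4)))
  set.seed(101)
  x <- s$draw(1e5)
  expect_lt(abs(median(x) - 2), 0.02)
  expect_true(all(x >= 0 & x <= 4))

  # Kolmogorov-Smirnov distance to the piecewise-linear CDF
  specs <- reference_specs()
  kr <- quantile_sampler(specs[specs$name == "K", ])
  set.seed(102)
  xk <- kr$draw(1e5)
  F_theory <- approxfun(kr$knots, c(0, 0.25, 0.5, 0.75, 1), ties = "ordered")
  ks <- max(abs(ecdf(xk)(xk) - F_theory(xk)))
  expect_lt(ks, 0.01)
  expect_true(all(xk >= 3.053 & xk <= 5.363))
})

test_that("constant and binary samplers behave as declared", {
  cs <- quantile_sampler(make_spec("flat", rep(0, 5), vclass = "constant"))
  expect_true(all(cs$draw(1000) == 0))

  bs <- quantile_sampler(make_spec("sex", c(0, 1, 1, 1, 1),
                                   vclass = "binary", mean = 0.7718))
  set.seed(103)
  b <- bs$draw(2e4)
  expect_true(all(b %in% c(0, 1)))
  expect_lt(abs(mean(b) - 0.7718), 0.02)
})

test_that("non-monotone knots are rejected unless repaired", {
  specs <- reference_specs()
  bad <- specs[specs$name == "Gut_CYP2C9", ]
  expect_error(quantile_sampler(bad), "non-monotone")
  s <- quantile_sampler(bad, repair = TRUE)
  expect_false(is.unsorted(s$knots))
  set.seed(104)
  expect_true(all(is.finite(s$draw(1000))))
})

test_that("default design carries the published trial structure", {
  d <- default_design()
  expect_equal(d$n_patients, 63L)
  expect_equal(d$total_records, 10360L)
  expect_equal(length(d$arms), 8L)
  expect_equal(sum(d$allocation$n_records), 10360L)
  expect_true(all(seq_len(63) %in% d$allocation$patient_id))
  # deterministic near-equal allocation: remainder goes to low patient ids
  per_patient <- tapply(d$allocation$n_records, d$allocation$patient_id, sum)
  expect_true(all(per_patient %in% c(164L, 165L)))
  expect_equal(unname(per_patient[["1"]]), 165L)
})

test_that("population sampling is reproducible, complete and schema-stable", {
  d <- tiny_design()
  specs <- reference_specs()
  p1 <- sample_population(specs, d, seed = 7)
  p2 <- sample_population(specs, d, seed = 7)
  expect_identical(p1, p2)
  p3 <- sample_population(specs, d, seed = 8)
  expect_identical(names(p3), names(p1))
  expect_false(identical(p1$K, p3$K))

  expect_equal(nrow(p1), d$total_records)
  expect_identical(names(p1),
                   c("patient_id", "arm", specs$name[specs$role == "input"],
                     "dQTc"))
  expect_false(anyNA(p1))
  for (v in specs$name[specs$vclass == "constant"])
    expect_true(all(p1[[v]] == 0))
  expect_true(all(p1$Sex_Code %in% c(0, 1)))
  expect_error(sample_population(specs, d), "seed")
})

test_that("mechanistic mode ties the output to the white-box equation", {
  d <- tiny_design()
  pop <- sample_population(design = d, seed = 21, mode = "mechanistic")
  expect_equal(pop$dQTc, predict_dqtc(pop), tolerance = 1e-12)
})

test_that("the rank-correlation hook induces the requested association", {
  d <- tiny_design(8L, 2000L)
  rc <- matrix(c(1, 0.8, 0.8, 1), 2,
               dimnames = list(c("Age", "Weight"), c("Age", "Weight")))
  pop <- sample_population(design = d, seed = 31, rank_corr = rc)
  expect_gt(cor(pop$Age, pop$Weight, method = "spearman"), 0.6)
  # marginals still anchored to the published knots
  expect_lt(abs(median(pop$Age) - 28), 1)
})
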