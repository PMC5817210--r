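test_that("isolated terms of the canonical parse evaluate as stated", {
  expect_equal(eval_dqtc(zero_record()), 0)

  r <- zero_record()
  r$X10 <- pi / 2
  expect_equal(eval_dqtc(r), 2)

  # only the IKr terms survive; independent arithmetic oracle
  r <- zero_record()
  r$X11 <- 0.5
  cs <- model_constants()
  expect_equal(eval_dqtc(r),
               cs[["C3"]] * 0.5 + sin(0.5 * exp(exp(0.5))),
               tolerance = 1e-12)

  bad <- zero_record()
  bad$X9 <- NaN
  expect_error(eval_dqtc(bad), "non-finite")
  expect_error(eval_dqtc(zero_record()[1:7]), "lacks")
})

test_that("raw-scale prediction composes scaling with the equation", {
  sc <- fit_scaler()
  specs <- reference_specs()
  raw_min <- as.list(setNames(
    specs$vmin[match(c("BSA", "K", "Na", "Ca2", "IKr_inhibition",
                       "IKs_inhibition", "INa_inhibition", "ICa_inhibition"),
                     specs$name)],
    c("BSA", "K", "Na", "Ca2", "IKr_inhibition", "IKs_inhibition",
      "INa_inhibition", "ICa_inhibition")))
  lo <- as.list(setNames(rep(0.1, 8), eq_labels))
  expect_equal(predict_dqtc(raw_min), eval_dqtc(lo), tolerance = 1e-12)
  expect_identical(predict_dqtc(raw_min), predict_dqtc(raw_min))
})

test_that("dQTc increases monotonically with raw IKr inhibition at medians", {
  curve <- response_sweep("IKr_inhibition", "Q3", n_points = 200L)
  expect_true(all(diff(curve$dqtc) > 0))
  expect_equal(range(curve$value), c(0.0047, 1))
})

test_that("packaged quantile scenarios carry the published covariate values", {
  sc <- response_scenarios()
  expect_equal(nrow(sc), 5L)
  q3 <- sc["Q3", ]
  expect_equal(unlist(q3[-1], use.names = FALSE),
               c(1.937, 4.268, 140.445, 2.388, 0.117, 0, 0.001, 0.002))
  q1 <- sc["Q1", ]
  expect_equal(q1$BSA, 1.422)
  expect_equal(q1$Na, 135.144)
  expect_equal(q5 <- sc["Q5", ]$ICa_inhibition, 0.522)
})

test_that("response sweeps span the observed range and honour structure", {
  sw <- response_sweep("K", "Q1", n_points = 50L)
  expect_equal(sw$value[1], 3.053)
  expect_equal(sw$value[50], 5.363)
  expect_true(all(is.finite(sw$dqtc)))

  # every INa term carries an ICa factor: with X14 = 0 the sweep is flat
  r <- zero_record()
  r$X11 <- 0.4
  base <- eval_dqtc(r)
  for (x13 in seq(0.1, 0.9, by = 0.2)) {
    r$X13 <- x13
    expect_equal(eval_dqtc(r), base, tolerance = 1e-12)
  }

  # calcium enters only through 2*sin^2: its sweep moves dQTc by <= 2 ms
  ca <- response_sweep("Ca2", "Q4", n_points = 100L)
  expect_lte(diff(range(ca$dqtc)), 2)

  expect_error(response_sweep("Age", "Q3"), "not an equation input")
})

test_that("channel comparison is well-posed and affine-invariant", {
  cmp <- channel_comparison()
  expect_equal(nrow(cmp$curve), 101L)
  expect_true(is.finite(cmp$slope) && is.finite(cmp$r_squared))

  # a channel against itself is the identity line
  self <- suppressWarnings(
    channel_comparison(channel_a = "IKr_inhibition",
                       channel_b = "IKr_inhibition"))
  expect_equal(self$slope, 1, tolerance = 1e-12)
  expect_equal(self$r_squared, 1, tolerance = 1e-12)

  # slope is invariant under affine rescaling of the model output
  f <- parse_candidates()[["canonical"]]$fun
  g <- function(X, C) 3.7 * f(X, C) - 11
  cmp2 <- channel_comparison(eval_fun = g)
  expect_equal(cmp2$slope, cmp$slope, tolerance = 1e-10)
})

test_that("parse candidates enumerate the ambiguity and select deterministically", {
  cands <- parse_candidates()
  expect_length(cands, 24L)
  expect_true("canonical" %in% names(cands))

  # term-by-term value at the all-zero scaled record: every reading
  # vanishes except those whose exponent absorbs X9 as a factor, where the
  # exponential collapses to e^0 = 1 and the sine contributes sin(1)
  z <- zero_record()
  cs <- model_constants()
  for (cd in cands) {
    expected <- if (grepl("e^(C4*X14*X9)", cd$description, fixed = TRUE))
      sin(1) else 0
    expect_equal(cd$fun(z, cs), expected, tolerance = 1e-12)
  }

  s1 <- select_parse()
  s2 <- select_parse()
  expect_identical(s1$selected$id, s2$selected$id)
  expect_equal(nrow(s1$scores), 24L)
  expect_true(all(s1$scores$score <= 3))
})

test_that("the raw-input reconstruction yields a near-two linear channel ratio", {
  # under the alternative convention (equation consumes raw values) the
  # best-scoring readings are strongly linear with slope magnitude near 2.6:
  # closer to the reported two-fold ICaL/IKr effect ratio than any reading
  # under the scaled convention, but still outside the 1.5-2.5 band
  raw <- select_parse(convention = "raw")
  best <- raw$scores[which.max(raw$scores$r_squared), ]
  expect_gt(best$r_squared, 0.99)
  expect_gt(abs(best$slope), 2.5)
  expect_lt(abs(best$slope), 2.7)
  expect_true(grepl("sin(X14)*X9", raw$selected$description, fixed = TRUE))

  scaled <- select_parse()
  expect_true(max(raw$scores$r_squared) > max(scaled$scores$r_squared))
})

test_that("IKr response dominates: numeric gradient is positive on the box", {
  set.seed(91)
  X <- random_scaled_records(2000, seed = 91)
  h <- 1e-5
  up <- X
  up$X11 <- X$X11 + h
  dn <- X
  dn$X11 <- X$X11 - h
  grad <- (eval_dqtc(up) - eval_dqtc(dn)) / (2 * h)
  expect_true(all(grad > 0))
})
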