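# Shared fixtures: tiny designs, scaled-record builders and planted targets.

eq_labels <- c("X6", "X8", "X9", "X10", "X11", "X12", "X13", "X14")

zero_record <- function() {
  as.list(stats::setNames(rep(0, 8), eq_labels))
}

random_scaled_records <- function(n, seed) {
  set.seed(seed)
  X <- as.data.frame(matrix(stats::runif(n * 8, 0.1, 0.9), n))
  names(X) <- eq_labels
  X
}

tiny_design <- function(n_patients = 4L, total_records = 64L) {
  default_design(n_patients = n_patients, total_records = total_records)
}

# A spec row in the shape reference_specs() uses.
make_spec <- function(name, knots, vclass = "continuous",
                      mean = stats::median(knots)) {
  list(name = name, vmin = knots[1], q25 = knots[2], median = knots[3],
       mean = mean, q75 = knots[4], vmax = knots[5], vclass = vclass)
}
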