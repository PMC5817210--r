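---
title: "Methods: virtual QTc trials, the white-box dQTc equation, and symbolic regression"
author: "qtcgp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virtual QTc trials, the white-box dQTc equation, and symbolic regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(qtcgp)
```

## The problem

Drug-induced prolongation of the heart-rate-corrected QT interval (QTc) is
the standard clinical surrogate of torsadogenic risk. The change from
baseline, **dQTc** (ms), depends not only on how strongly a drug and its
co-medications inhibit cardiac ion channels — chiefly IKr (hERG), but also
IKs, peak INa and L-type ICa — but on the patient's physiology: plasma
potassium, sodium and calcium, body surface area, enzyme abundances
governing drug exposure. `qtcgp` implements an analysis chain that asks
*which covariates drive dQTc and through what functional form*, using
simulated terfenadine drug–drug-interaction trials as the study system:
terfenadine alone and with seven metabolic inhibitors, 63 virtual patients,
10,360 records, 48 candidate covariates.

The original record-level data came from proprietary simulators and is not
available. Everything in this package therefore runs on a synthetic
stand-in calibrated to the published per-variable summary; the package's
claims are about the *machinery* (generator, preprocessing, ranking,
symbolic regression, evaluation, model analyses), not about re-estimating
the original fit statistics, which are unreachable without the source data.

## The virtual-population generator

`reference_specs()` packages, verbatim, the published six-number summary
(min, Q25, median, mean, Q75, max) of all 48 inputs and the dQTc output.
`quantile_sampler()` turns one row into a sampler:

* **continuous** — a piecewise-linear inverse CDF through the probability
  knots (0, .25, .5, .75, 1) at the five quantile values. Draws can never
  leave `[min, max]`, and the five knots are matched in distribution. The
  printed *mean* is deliberately not targeted: when the mean and the
  quantiles disagree (heavily zero-inflated CYP abundance columns), the
  quantiles win because they define the inverse CDF.
* **constant** — seven CYP columns are identically zero in the source
  trials and are generated as exact zeros.
* **binary** — the sex code is Bernoulli with the published mean 0.7718.

One published row (`Gut_CYP2C9`) is internally inconsistent — its printed
minimum (8210) exceeds its printed first quartile (1430), almost certainly
a transcription slip in the source table. The packaged table keeps the
printed values; the sampler treats non-monotone knots as a validation
error unless `repair = TRUE` (sort the five knots), which the population
generator uses for this one row.

`default_design()` fixes the trial structure: 63 patients, 8 arms
(terfenadine-alone is treated as the eighth cross-validation group, since
only seven interacting drugs are named), 10,360 records allocated
deterministically — `floor(10360/63)` records per patient, remainder to
the lowest ids, each patient's records spread near-equally over arms. No
per-patient or per-arm breakdown was published, so any reproducible
allocation is as defensible as any other; determinism was the deciding
property.

`sample_population()` draws covariates **independently** by default. The
published summary carries no joint structure, and inventing correlations
would manufacture findings, so none are defaulted; a Gaussian-copula hook
accepts a user rank-correlation matrix when joint structure is wanted
(e.g. anthropometric consistency between age, weight, height and BSA,
which the default does *not* enforce — a documented limitation). The dQTc
column is either drawn from its own marginal (`"marginal"`) or computed
through the white-box equation (`"mechanistic"`), which makes the
generator a self-consistent oracle for testing the evaluation chain.

What passing tests on this stand-in do **not** show: behaviour under the
real data's joint distribution, within-patient repeated-measures
correlation (records are exchangeable here), or per-arm inhibition
profiles (a per-arm multiplicative shift hook exists but defaults to no
shift, keeping the printed marginals).

## Preprocessing

* **Noise augmentation** (`add_noise`): each numeric cell `x` becomes
  `x * (1 + u)`, `u ~ U(-0.05, 0.05)`, with two noised replicates by
  default. "±5 % amplitude" is read as a bounded multiplicative band: a
  relative band preserves the many structural zeros, and "amplitude"
  implies bounded support rather than, say, Gaussian noise. The noised set
  is used for stability testing of a fitted model by default; appending
  it to training data is equally supported. Both the inputs and the
  output are noised by default ("each variable value"); `exempt = "dQTc"`
  gives the other reading.
* **Scaling** (`fit_scaler`): `scaled = 0.1 + 0.8 (x - min)/(max - min)`
  per variable. Default bounds are the published population-level min/max
  (reproducible and fold-independent); empirical per-data bounds are an
  option. Out-of-range inputs extrapolate linearly on purpose — the
  channel-effect sweep pushes ICa inhibition to 1, far beyond its
  observed maximum of 0.5217. Constant columns pass through as zero. The
  dQTc output keeps a scaler entry for optional scaled-target runs, but
  the packaged model emits raw milliseconds (below).
* **Folds** (`make_loio_folds`): grouped 8-fold assignment keyed by arm
  label — train on seven drug combinations, test on the held-out one, so
  every fold measures extrapolation to an unseen interaction, not
  record-level interpolation. Keying by label makes folds invariant to
  row order.

## Feature ranking

The ranking contract has three parts: per-learner importance, aggregation,
cut-off. The original study aggregated importances from a large zoo of
regression learners; the zoo is replaceable plumbing, so the package ships
one self-contained estimator — permutation importance around any
user-supplied predictor — and keeps the aggregation arithmetic exact:
normalize each learner's importance vector to sum one, weight by inverse
global error (RMSE or MSE), sum, sort. Inverse-error weighting is the
natural reading of "scaling by global performance"; the exact original
weighting is not printed.

The cut-off rule trims the ranking where consecutive importances drop by
more than 5 % of the total importance sum. Every qualifying drop is a
candidate cut point (that is precisely how one ranking yields several
nested candidate input vectors); `apply_cutoff()` returns the prefix above
the *last* qualifying drop — the most inclusive cut, and the only reading
consistent with the rule's worked behaviour on rankings whose leading
drops are large — with all cut points attached as an attribute. An
importance-share variant (`rule = "share"`) is available.

## The GP engine

Genotypes are expression trees over `{add, mul, neg, sin, exp_protected}`
with variable and constant leaves — exactly the operator vocabulary the
final published equation uses, which keeps the search space honest: the
engine can express the known solution but gets no operators the solution
does not need. `exp_protected` clamps its argument to `[-50, 50]` so no
genotype can overflow. Complexity is the node count, bounded by
`size_limit` (10–100; oversized crossover/mutation products are rejected
and resampled).

Two survivor-selection heuristics are provided, both approximations of the
cited search strategies (whose internal defaults were never printed):

* `"afc"` — age–fitness–complexity Pareto: parents are drawn at random,
  offspring inherit the older parent's age, a couple of fresh random
  individuals (age 0) are injected each generation, and survivors are the
  non-dominated-sorted fill of the parent+offspring pool under
  (training RMSE, complexity, age). Age layering protects young lineages
  from being crowded out by converged ones.
* `"apt"` — archive-based Pareto tournament: parents win size-4
  tournaments by (fitness, complexity) dominance.

Every `1000 × population_size` fitness evaluations (and once at the end),
the current elite is cross-validated under the 8-fold scheme and its
constants are randomly reinitialized and refitted. Constant refitting
(`optimize_constants`) is seeded multi-start derivative-free minimization
of training RMSE: Nelder–Mead simplex for two or more constants, Brent
line search for one, soft bounds at ten times each constant's initial
magnitude via a quadratic penalty. An archive of mutually non-dominated
individuals (fitness, complexity, age-at-insertion) is maintained
throughout.

`select_final()` operationalizes the published multivariate criterion
(generalization error, complexity, number of adjustable parameters) as:
Pareto-filter, treat cv errors within 5 % relative of the best as
equivalent, then minimize complexity, then constant count. The 5 % band is
a design choice that makes "comparable error, prefer simpler" executable.

The published evolution budget (10^8 steps on a server grid) is far beyond
desk scale; the budget is a configuration knob. The engine's adequacy is
demonstrated on planted targets instead: at a 200,000-evaluation budget it
re-discovers `y = sin(x1) + 2 x2` (500 records, noiseless) to RMSE < 0.01
in at least 8 of 10 seeds — the test suite runs exactly that experiment —
and recovers planted constants on noiseless data to 1e-4.

## The white-box equation and its reconstruction

The published model is a single equation with four fitted constants
(C1 = −14.09525, C2 = 7.706551, C3 = 46.69071192, C4 = 4.587024) over
eight inputs: BSA (X6), K (X8), Na (X9), Ca2 (X10) and the four fractional
channel inhibitions IKr/IKs/INa/ICa (X11–X14). Two things about it are
not recoverable from the printed text and had to be reconstructed:

**Grouping.** The printed formula lost its parentheses typographically.
`parse_candidates()` enumerates the 24 readings spanned by the four
ambiguity axes (extent of the first sine; `2 sin²(X10)` vs `2 sin(X10²)`;
extent of the exponent; `C3·X11` inside vs outside its sine) rather than
silently discarding them. The packaged canonical parse is

    dQTc = sin(X14·X9) + C2·X13·X14·X8·sin(X6) + X14·X8
         + sin(C1·X12·X14²) + X11·X14
         + sin(e^(C4·X14)·X9 + X11·e^(e^X11)) + C3·X11 + 2·sin²(X10)

Note one structural fact the test suite pins: readings whose exponent
absorbs X9 as a factor do *not* vanish at the all-zero record (the
exponential collapses to e^0 = 1, leaving sin(1)); the other sixteen
readings evaluate to exactly zero there.

**Scale convention.** The equation is taken to consume inputs on the
⟨0.1, 0.9⟩ scale and to emit raw milliseconds. Scaled inputs: sines and
exponentials of raw Na ≈ 140 mM would oscillate meaninglessly, and the
preprocessing explicitly scaled the data. Raw-millisecond output: with
scaled inputs the dominant C3·X11 term spans ≈ 4.7–42 ms across the IKr
range, matching the observed dQTc quartiles (1.7 / 6.6 / 14.7 ms), which
a scaled output could not.

**The channel-effect comparison and its gap.** `channel_comparison()`
sweeps IKr and ICa inhibition over the raw grid 0, 0.01, …, 1 (through the
scaler; ICa extrapolates beyond its observed maximum by design), holds the
other inputs at the published medians, and regresses the ICa sweep on the
IKr sweep by OLS. The reported finding for this analysis is a strong
linear relationship with the ICa effect about twice the IKr effect. Under
the canonical parse and scaled convention the package computes a slope of
≈ 0.06 with R² ≈ 0.38 — nowhere near that: with scaled inputs, IKr acts
through the large linear C3·X11 term (tens of ms) while every ICa term has
an O(1) coefficient, so no reading of the formula can make the ICa sweep
twice the IKr sweep. The corresponding acceptance-level test is left
failing rather than weakened, because the discrepancy is informative: the
printed constants, the stated sweep protocol and the two-fold conclusion
are not jointly consistent with any enumerated reading under the scaled
convention. `select_parse(convention = "raw")` documents the nearest
reconstruction: if the equation consumes *raw* values and the first sine
is read as `sin(X14)·X9`, the comparison becomes strongly linear
(R² ≈ 0.995) with slope ≈ 2.6 — qualitatively close to the reported
two-fold effect, though the slope sits just outside the "roughly twice"
band and the reported *opposite signs* of the two effects are not
reproduced by any reading. Both score tables are one function call away; the
canonical parse remains the packaged default because the scaled convention
has the stronger physical rationale.

The response analysis (`response_sweep`) reproduces the published
protocol's structure: one input swept across its observed range, the
other seven pinned at one of five packaged quantile scenarios (the exact
published scenario values). Only scenario inputs and qualitative shapes
are in scope — the published response curves themselves were never
tabulated. Useful structural consequences that *are* tested: dQTc is
strictly increasing in IKr inhibition at the medians (the C3 term
dominates the bounded sine derivative everywhere on the data range),
calcium moves dQTc by at most 2 ms (it enters only through `2 sin²`), and
the INa sweep is exactly flat when ICa inhibition is zero on the scaled
axis (every INa term carries an X14 factor).

## Evaluation

`nrmse()` is RMSE divided by the *observed* response range of the
evaluation split, ×100; the observed-range normalization (not a
theoretical range) is pinned by test, and a fixed global range is
available for cross-fold comparability. `r_squared()` is `1 − SSres/SStot`.
`cv_evaluate()` reports per-fold NRMSE/R², their mean, a pooled NRMSE over
concatenated held-out predictions (the published headline error does not
say whether folds were pooled or averaged, so both are reported), and an
optional noised-set stability score. The original headline statistics
(8-fold NRMSE 3.97 %, R² 0.923, and the screening-model error table) are
not reproducible here and are not claimed: they require the original
data set.

## Problem sizes and numerical choices

The test suite runs at sizes chosen to exercise every claim meaningfully
on a single CPU: 10^5 sampler draws for the calibration checks (Monte
Carlo error of a sample median there is ~0.001, an order below the
asserted tolerances), 10,360-record generation for the design contract,
2,000 records for constant recovery, 10 × 200,000 evaluations for the GP
planted-target experiment, 1,000 trees × 1,000 records for the dual-route
evaluator agreement at 1e-10. Other fixed choices: Nelder–Mead
`reltol = 1e-12` with one restart from the incumbent; uniform constant
initialization on [−5, 5]; crossover probability 0.7; subtree mutation
depth 2; archive capped at 50 by fitness; all randomness flows through
explicit integer seeds, and functions that need randomness refuse to run
without one.

## Known limitations

* Marginal fidelity only: no joint structure, no repeated-measures
  correlation, no per-arm pharmacology in the default generator.
* The equation's grouping and scale convention are reconstructions; the
  channel-effect two-fold claim is not reproduced by any enumerated
  reading (see above) and the corresponding check is deliberately red.
* The feature-ranking stage ships one importance estimator, not the
  original multi-learner zoo; only the aggregation arithmetic is exact.
* The GP heuristics approximate the cited strategies' published
  descriptions, not their unpublished internal defaults.
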