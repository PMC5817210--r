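Package: qtcgp
Title: Virtual-Trial Simulation and Symbolic Regression of Drug-Induced QTc Change
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing which physiological and drug-related covariates
    drive drug-induced QTc prolongation in simulated drug-drug-interaction
    trials of terfenadine. Provides a quantile-calibrated virtual-population
    generator (piecewise-linear inverse-CDF sampling from published summary
    statistics), trial preprocessing (multiplicative noise augmentation,
    min-max scaling to the 0.1-0.9 interval, leave-one-inhibitor-out folds),
    performance-weighted feature-ranking aggregation with a drop-based
    cut-off rule, a genetic-programming symbolic-regression engine with
    age-fitness-complexity Pareto selection and derivative-free constant
    refitting, the published white-box delta-QTc equation with quantile
    response sweeps and an IKr-versus-ICaL channel-effect comparison, and
    normalized-RMSE / R-squared evaluation over grouped cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
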