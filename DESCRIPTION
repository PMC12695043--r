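Package: hctree
Title: Honest Causal Trees for Subgroup Discovery in Two-Arm Trials
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits honest causal trees to patient-level data from two-arm
    randomized trials to discover subpopulations with heterogeneous
    treatment effects. Splitting uses the expected-mean-squared-error
    criterion for treatment-effect estimation with a per-arm minimum leaf
    size; trees are pruned along the weakest-link cost-complexity path by
    cross-validation on a transformed-outcome risk. Includes the subgroup
    statistics commonly reported around such trees (Welch leaf contrasts,
    Fisher exact and Wilcoxon rank-sum comparisons, Mantel and linear
    trend tests across ordered leaves, Pearson correlations), CSV input
    with last-observation-carried-forward outcome imputation, a synthetic
    two-arm trial generator with planted threshold-defined effects, and a
    command-line pipeline producing tree rules and summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
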