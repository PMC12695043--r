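---
title: "Honest causal trees for trial subgroup discovery: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Honest causal trees for trial subgroup discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A two-arm randomized trial estimates one average treatment effect, but the
effect of a biologic such as rituximab on lung function in systemic
sclerosis-associated interstitial lung disease (SSc-ILD) is plausibly
heterogeneous: baseline inflammation and pneumocyte-injury markers may
separate responders from non-responders. `hctree` implements the
recursive-partitioning approach to this question: an *honest causal tree*
that splits patients on baseline covariates so that the within-leaf
difference in mean outcome between arms — the leaf's conditional average
treatment effect — is as heterogeneous across leaves, and as reliably
estimable within leaves, as possible.

The outcome throughout is the change from baseline in the percentage of
predicted forced vital capacity, written ΔppFVC, at a target visit week
(default week 24), in percentage points. Missing target-week measurements
are imputed by last observation carried forward (LOCF) before the outcome
is derived.

## The splitting criterion

For a candidate partition with leaves $\ell = 1, \dots, L$, arm-wise leaf
means $\bar y_{1\ell}, \bar y_{0\ell}$, sample variances
$s^2_{1\ell}, s^2_{0\ell}$, effect estimates
$\hat\tau_\ell = \bar y_{1\ell} - \bar y_{0\ell}$, and a trial-wide treated
share $p$, the partition's score is the negated estimated expected mean
squared error for treatment-effect estimation:

$$
\widehat{-\mathrm{EMSE}} \;=\;
\frac{1}{n}\sum_\ell n_\ell\,\hat\tau_\ell^{\,2}
\;-\;
\left(\frac{1}{N_{tr}}+\frac{1}{N_{est}}\right)
\sum_\ell \left(\frac{s^2_{1\ell}}{p}+\frac{s^2_{0\ell}}{1-p}\right).
$$

The first term rewards effect heterogeneity; the second penalizes leaves
whose arm-wise means are noisy, which is the "honest" ingredient: it prices
in the variance a fresh estimation sample would face. The package sets
$N_{est} = N_{tr} = n$, i.e. a penalty factor of $2/n$; the source analysis
tool does not print its exact risk function, so this criterion is a
declared variant and exact reproduction of any particular small-sample tree
is not claimed. Because both terms scale as $1/n$, the choice of $n$ used
to normalize does not affect which split wins.

Splitting details, all deterministic:

* every midpoint between adjacent distinct observed values of every
  covariate is a candidate (a 0/1 covariate yields the single threshold
  0.5); records with `feature >= threshold` go to the high side,
* a candidate is admissible only if both children keep at least
  `min_per_arm` patients of *each* arm (default 5),
* the winner must improve on the unsplit node (`gain > 0`); ties are broken
  by covariate catalog order, then by the smaller threshold,
* $p$ is fixed at the root's empirical treated share for the whole fit —
  randomization is trial-wide, and node-level shares are far too unstable
  at trial-sized $n$,
* covariate missingness is an error at fit time; there are no surrogate
  splits, mirroring an analysis that reported none.

Growth recurses depth-first until no admissible positive-gain split exists.
Leaves are labelled 1..L depth-first with the high side first, so Leaf 1 is
the subpopulation above the first cut.

## Pruning

The grown tree is cut back along the standard weakest-link cost-complexity
path, with per-node risk $R(t) = -\widehat{-\mathrm{EMSE}}$ of the node's
leaf set on the full training scale. The path starts at the full tree
($\alpha = 0$), ends at the root, and has strictly increasing $\alpha$.

The penalty is chosen by `n_folds`-fold cross-validation (default 5),
stratified by arm and seeded, evaluated at the geometric means of
consecutive path $\alpha$ values. The validation risk uses the
*transformed outcome*
$y^*_i = w_i y_i / p - (1 - w_i) y_i / (1 - p)$,
an unbiased single-observation proxy for the individual treatment effect
under known randomization probability: for each fold the risk is
$\sum_{i \in \mathrm{val}} (y^*_i - \hat\tau_{\mathrm{train}}(x_i))^2$,
summed over folds and normalized by the same quantity for the root-only
tree. The published analysis says only that it minimized "the normalized
cross-validation error"; the transformed-outcome risk, the root-only
normalization, and the minimum-risk rule (no 1-SE rule; ties go to the
stronger pruning) are declared choices of this package.

Leaf effects of the pruned tree are reported on *all* patients reaching
each leaf (`estimate_mode = "full_sample"`), matching how subpopulation
effects are usually presented; an `"honest_half"` mode (structure and
pruning from one arm-stratified half, effects from the other) is available
for strict honest inference.

## Subgroup statistics

Around the fitted tree the package provides the comparisons such analyses
report:

* `leaf_contrast()`: within-leaf difference in mean ΔppFVC between arms
  with a 95% CI and two-sided p. The two-sample procedure is Welch's
  unequal-variance t (Welch–Satterthwaite df) — the source analysis does
  not name its method, and Welch is the default-safe choice when leaf arm
  variances differ.
* `fisher_exact_2x2()`: two-sided by the probability-sum convention (sum of
  hypergeometric probabilities no larger than the observed table's), the
  common statistical-package convention, not doubling of the one-sided p.
* `wilcoxon_rank_sum()`: exact Mann–Whitney null distribution when both
  samples have $\le 10$ observations without ties, otherwise a normal
  approximation with tie and continuity corrections.
* `mantel_trend()`: the Mantel–Haenszel trend statistic
  $\chi^2 = (N-1) r^2$ on the patient-level expansion, 1 df. This variant —
  not Cochran–Armitage — reproduces the published leaf-trend p-values
  (0.079, 0.173) from the printed count rows, and is invariant to affine
  rescaling of the scores (defaults 1..L).
* `linear_trend()`: two-sided slope t-test of the least-squares regression
  of the value on the leaf score (a regression slope test, not an ANOVA
  contrast — a declared choice).
* `pearson_correlation()`: plain product-moment correlation.

No multiplicity adjustment is applied anywhere, matching the source
analysis. Display percentages are rounded half-up to one decimal; p-values
are kept at full precision and printed to 3 decimals by the TSV writers.

## The synthetic trial generator

Patient-level data from the motivating trial are not public, so the
package ships a generator whose defaults *are* the published world and
serve as ground truth for every recovery experiment:

* $n = 48$ patients, treated share $25/48$, allocated by a permuted draw
  so small trials hit the 25/23 split exactly;
* a planted three-leaf effect: $\tau = 8.01$ when CRP $\ge 0.055$ mg/dl,
  $\tau = 2.47$ when CRP $< 0.055$ and KL-6 $\ge 364$ U/ml, and
  $\tau = -6.85$ otherwise, with placebo-arm drifts $-6.40$, $-3.70$ and
  $6.12$ — the published subpopulation effects and placebo means;
* residual noise sd 5 percentage points. The published per-leaf 95% CIs
  (widths of roughly 7–8 points at per-arm sizes around 5–12) imply
  within-leaf arm-level sds of about 4–6 points, so 5 is the realistic
  middle of that range;
* covariates drawn independently: binaries at the published prevalences,
  continuous variables from right-skewed log-normal families with medians
  at the published values (spread set from the published ranges); CRP is
  zero-inflated (point mass at 0 with probability 0.5, else log-normal)
  and rounded to 2 decimals, KL-6 rounded to integers, so that
  midpoint-threshold recovery lands on cuts like 0.055 and half-integers;
* missing week-24 ppFVC injected into `3/23` of control patients,
  reproducing the published missingness (three patients, all placebo).

Visit weeks are 0, 12 and 24. The week-12 value is drawn with the *same*
mean structure as week 24 (drift fully realized, fresh noise): the planted
leaf effects are defined as effects on the analyzed, post-LOCF outcome, so
carrying week 12 forward leaves them unbiased. A generator whose drift
accrued linearly would make LOCF systematically shrink the planted
contrast — a bias that is a property of LOCF, not of the estimator under
test, and would conflate the two.

Only CRP and KL-6 carry effect by default; the other 26 covariates are
pure noise features, which is exactly what makes end-to-end recovery a
meaningful test that the tree ignores irrelevant structure. What a green
recovery test does **not** establish: behavior under correlated
covariates, non-threshold (smooth) effect heterogeneity, informative
missingness, or within-patient longitudinal correlation — none of which
the generator emulates.

The "constant-effect null" used by the pruning tests sets
`leaf_effects = c(2, 2, 2)` and `control_means = c(0, 0, 0)`: the
treatment effect is constant *and* there is no outcome-mean heterogeneity,
the cleanest world in which a pruned tree should collapse to its root.

## Numerical and degenerate-case conventions

* Thresholds are midpoints of adjacent observed values; a record exactly at
  a threshold routes to the high side.
* Arm-wise variance in a node with a single patient of that arm (possible
  only when `min_per_arm = 1`) is recorded as 0 with a degenerate flag.
* Welch contrast with both arm variances zero: the CI collapses to the
  point difference, p is 0 for a non-zero difference and 1 otherwise.
* Linear trend with zero residual variance: p is 0 for a non-zero slope,
  1 for a flat fit. Mantel trend with a constant outcome: statistic 0,
  p 1 (not an error).
* `gain > 0` is tested strictly; all tie-breaks are deterministic, so a
  refit under the same seed is bit-identical.
* Values are written to CSV with 15 significant digits; a
  load → write → load cycle is value-identical to at least 12.

## Limitations

* The headline tree of the motivating 48-patient analysis cannot be
  re-derived exactly: its data are non-public and its exact risk/CV-error
  functions unprinted. The package's claims are therefore calibrated on
  printed-table statistics (which it reproduces exactly) and on parameter
  recovery in the planted synthetic world.
* No forests or smooth CATE learners, no propensity modelling (assignment
  is known), no mixed-model or multiple-imputation missing-data handling
  beyond LOCF, and no rendering of figures — outputs are tables and JSON.
* Units are metadata only; the package never rescales (the source tables
  themselves mix mg/l and mg/dl labels for CRP — the running text's mg/dl
  is used).
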