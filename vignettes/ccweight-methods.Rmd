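---
title: "Methods: longitudinal body-weight analysis in a CC F1 knockout panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal body-weight analysis in a CC F1 knockout panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccweight)
```

## The study design ccweight models

ccweight analyses longitudinal body weight (BW) in an F1 panel obtained by
crossing males heterozygous for a knockout allele (here a *Smad4*
heterozygous knockout on a C57BL/6J background) with females from a set of
Collaborative Cross (CC) recombinant inbred lines. Each animal carries four
attributes: its CC line, sex, genotype (0 = wild-type, 1 = heterozygous
mutant), and a weight series on a fixed schedule of 14 weeks of age —
biweekly from week 6 to 16, then monthly to week 48. Because mice within a
CC line are genetically identical, between-line variance of a trait is
genetic variance, which is what makes the broad-sense heritability
decomposition below meaningful.

The cohort container (`BWCohort`) is a `SummarizedExperiment`: the assay is
the weeks x mice weight matrix, `colData` holds line/sex/genotype, and the
schedule travels in the metadata. Missing weights (animals terminated under
welfare endpoints) are `NA`; records stay in the cohort, flagged
incomplete, and the machine-learning stages use complete cases only. No
imputation is performed anywhere.

## The synthetic cohort generator

No per-animal data are shipped with this package, so every downstream stage
is driven by `simulateCohort()`. The generator is first-class, tested code,
and its defaults are fixed study conditions, not tuning knobs:

* **Design**: 10 lines x 2 sexes x 2 genotypes x 10 mice per cell (400
  mice), matching a panel of ~391 animals at ~9.8 per group.
* **Mean curve**: a 3-parameter logistic in week of age,
  `A / (1 + exp(-r (t - t0)))` with `A = 42` g, `r = 0.13`/week and
  `t0 = 6` weeks. A logistic was chosen over Gompertz because the growth
  dynamics being emulated are described only qualitatively; the logistic is
  the simplest sigmoid with a controllable plateau. These values put week-6
  means near 21 g and week-48 line means in roughly the 32–50 g range once
  line effects are added, the ranges the design calls for.
* **Effects on the asymptote** (all in grams): line random effect
  `N(0, 3^2)`; line-specific genotype effect drawn once per line from
  `N(1.5, 2.5^2)` — so the mutant shift is positive on average but negative
  for some lines, reproducing the sign-varying line-by-genotype pattern;
  fixed male shift +3; per-animal effect `N(0, 1.5^2)`.
* **Dynamics rules**: after week 40, female per-visit mean increments are
  multiplied by 0.15 (a near plateau with a modest residual increase);
  males of one designated line (default IL6018) lose a fixed 0.8 g per
  visit after week 32. Both rules are applied to the mean curve before
  noise.
* **Noise and floor**: i.i.d. `N(0, 0.5^2)` measurement noise per
  observation; weights are truncated at a 1 g floor.
* **Seeding**: one root seed is split into per-line and per-mouse
  substreams by a documented rolling-hash scheme (`childSeed()`), so adding
  a line or mouse never reshuffles existing animals' draws.

What the generator does *not* emulate: dropout/termination patterns (no
missingness is generated unless you introduce it), litter and cage effects,
autocorrelated within-animal noise, and any real line's actual growth
curve. Tests passing on synthetic cohorts therefore certify the
*machinery* — estimators, cross-validation, bookkeeping — not claims about
any specific real line.

`simulateTraitData()` is the second, deliberately minimal mode: grouped
values `y_il = mu + b_l + e_il` with `Var(b) = Vg`, `Var(e) = Ve`. It exists
so the heritability estimator can be checked against a known
`H2 = Vg / (Vg + Ve)`.

One structural property of trajectory mode is worth knowing: because the
line, genotype and individual effects act on the logistic *asymptote*, they
scale the whole curve proportionally and cancel out of the percent-gain
ratio `(BW_t - BW_6)/BW_6`. Percent-gain traits from trajectory-mode
cohorts therefore have essentially zero between-line variance (the absolute
decline rule and measurement noise are the only non-proportional terms),
and `heritabilityTable()` correctly reports H2 near 0 on them. Real panels
show heritable percent gain because lines also differ in growth *rate* and
*shape*, which this generator deliberately does not vary. Heritability
parameter recovery is therefore tested in trait mode, where the generative
H2 is known exactly; trajectory mode exercises the bookkeeping (strata,
complete cases, shape contracts).

## Percent weight gain and group comparisons

The gain trait is `%dBW t-6 = 100 (BW_t - BW_6) / BW_6`, computed per mouse
from the week-6 baseline; it is undefined when either weight is missing
(reported, never silently dropped) and is invariant to rescaling all
weights. Per-line, per-week genotype contrasts use a two-sided Welch
(unequal-variance) two-sample t-test, with figure-style stars (`*` for
0.01 <= p < 0.05, `**` for p < 0.01) and deliberately no multiple-testing
correction — the stars annotate individual timepoints, they are not a
family-wise inference. When both arms are constant the Welch statistic is
undefined; the package reports t = 0, p = 1 for equal constants and p = 0
for distinct ones.

## Broad-sense heritability

Within each sex x genotype stratum, a trait is grouped by line and
decomposed by textbook fixed-effects one-way ANOVA about the grand mean.
With `k` lines and effective per-line size `n0`, the variance components
are

* `Ve = MS_within`,
* `Vg = max(0, (MS_between - MS_within) / n0)`,
* `H2 = Vg / (Vg + Ve)` (0 by convention when both vanish).

For unbalanced designs `n0 = (N - sum(n_i^2)/N) / (k - 1)`, the standard
unbalanced one-way surrogate, which reduces to the common group size when
balanced. `varianceComponents()` also accepts an explicit `n`, so published
ANOVA summary rows can be converted exactly as printed regardless of how
their `n` was derived. Negative `Vg` estimates are truncated to zero, the
usual method-of-moments convention. Parameter recovery is verified by
simulation: with `Vg = Ve = 1` over 200 lines of 50, the mean estimate sits
within 0.05 of the closed-form 0.5 (and within 0.03 of 0.9 for
`Vg = 9, Ve = 1`); problem sizes were chosen to make the Monte-Carlo error
comfortably smaller than those bands.

## Genotype classification benchmark

`benchmarkLine()` asks how predictable the genotype is from sex plus the 14
weights, per line. Six classifiers are scored: decision tree (max depth
10), Gaussian naive Bayes, 5-nearest neighbours, random forest (100
trees), a radial-kernel support-vector classifier with default settings,
and logistic regression. The estimators are library-backed (rpart,
e1071, class, randomForest, stats::glm); the cross-validation harness, the
held-out scoring and the AUC are this package's own.

Scoring is the mean ROC-AUC over 4-fold cross-validation repeated 3 times
(12 fold-scores). Folds are stratified by genotype because lines can have
as few as ~24 mice with imbalanced classes; unstratified folds would
regularly lose a class. Held-out scores are class-1 probabilities where the
estimator provides them and the decision value for the SVC; KNN's score is
the fraction of neighbour votes for class 1, which is coarse but faithful
to a default 5-NN classifier. The AUC is computed as Mann–Whitney
concordance with mid-rank tie handling and is cross-checked against a
brute-force pairwise count and an independent library implementation in the
tests. Mice are put in a canonical (id-sorted) order before fold
assignment, making results invariant to input row order; one root seed
derives the repeat shuffles and every stochastic fit. Features are passed
unstandardized by default (a `standardize` flag exists). Fold geometry
requires at least 2 mice per class; a fold that still loses a class is
reshuffled once, then reported as an error.

## Chained linear-regression forecaster

To forecast a trajectory from a prefix, `fitChain()` builds one OLS model
per schedule week after the last observed week; the model for target week
`w` regresses `w` on sex, genotype and *every* schedule week before `w`. At
prediction time the chain feeds its own predictions forward: weeks beyond
the last observed one enter later models as predicted values. Training uses
teacher forcing — observed predecessors — which is the standard
regressor-chain reading; a `trainOnChained` flag trains on in-sample
chained predictions instead, for sensitivity analysis.

The OLS solver is SVD-based minimum-norm least squares, because chain
designs are routinely rank-deficient (adjacent weeks are nearly, and in
synthetic fixtures exactly, collinear); it agrees with the normal equations
to 1e-8 on full-rank problems. Fitting a target with `p` predictors
requires at least `p + 2` training records.

Evaluation (`evaluateChain()`) is 5-fold cross-validation over the
complete-case mice of a line, pooling *all* out-of-fold (mouse,
target-week) cells into a single `R^2 = 1 - SSE/SST`, with SST about the
pooled mean of the actual values. Pooled R^2 can be negative — chains fit
on small, structureless lines predict worse than the pooled mean, and the
tests assert this sign behaviour on a seeded fixture. Per-target-week R^2
values are returned as diagnostics. Sexes and genotypes are pooled within a
line and enter only as features.

## Correlation structure

`correlationMatrix()` computes the 14 x 14 Pearson matrix of weights across
weeks within one line x sex x genotype stratum, pairwise-complete with the
per-cell n recorded (pairwise rather than listwise, so one missing week
does not discard a mouse from every cell). Cells with under 3 pairs or a
constant week are rendered as missing, never as zero. Heatmaps use an
unclustered diverging palette anchored at -1, 0, +1.

## Pipeline and reproducibility

`runPipeline()` runs simulate (or read) → summarize → heritability →
classify → forecast → correlate, writes one CSV per stage plus the fully
resolved config for provenance, rejects unknown config keys before any
stage runs, and is end-to-end deterministic under a fixed root seed fanned
out per stage. This package is a library, not a shell tool, so the
orchestration surface is this function (plus the vignette and README)
rather than an executable.

## Numerical conventions and limitations

* Weeks are integer weeks of age; weights are grams (round-tripped through
  CSV at full precision; 4 decimals is the intended data precision).
* Sex is encoded F = 0, M = 1 in feature matrices.
* Degenerate inputs are explicit, classed conditions (`not benchmarkable`,
  `not evaluable`, `undefined correlation`, `insufficient data`), never
  silent NA propagation.
* Test and vignette problem sizes (e.g. 60-mouse benchmark lines, 200 x 50
  trait simulations, 20 Monte-Carlo replicates) were chosen so each check's
  sampling error is small relative to its acceptance band.
* Known limitations: no mixed-model/REML heritability or confidence
  intervals, no hyperparameter tuning or calibration in the benchmark, no
  nonlinear forecasters, no changepoint modelling of the two-phase growth
  some lines show, and no modelling of missingness mechanisms.
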