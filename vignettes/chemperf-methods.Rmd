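---
title: "chemperf: methods, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chemperf: methods, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemperf)
```

chemperf answers a question that comes up constantly in QSAR work: of the
many descriptor-set/method (D–M) combinations one could use to predict a
compound's activity, which are *genuinely* better, once the randomness of
how the data happened to be split for validation is accounted for? This
vignette documents the statistical machinery, every tunable default, what
the synthetic generators do and do not emulate, and the numerical choices
made where the design was open.

## Repeated cross-validation with blocking

`makeCvPlan(n, nsplits, nfolds, seeds)` draws, for each split, a seeded
uniform permutation of the observations and deals it round-robin into
`nfolds` folds, so every fold has ⌊n/k⌋ or ⌈n/k⌉ members by construction.
When seeds are unspecified, split *i* uses seed 11111·i (11111, 22222, ...),
so default runs are reproducible without any configuration.

The pivotal design point is that **all D–M combinations within a split use
the identical fold assignment**. A performance measure computed on a split is
then a paired observation across combinations, and split-to-split variation
(which can be substantial) is separated from combination differences by the
blocked ANOVA below instead of inflating its error term.

Defaults: `nsplits = 3`, `nfolds = 10`. Ten folds is the usual
bias–variance compromise for k-fold validation; three splits is the smallest
number giving a usable error degrees-of-freedom in the two-way layout while
keeping 3 × 10 × (number of combinations) model fits affordable. Both are
plain arguments.

Fold assignment is deliberately **not stratified** by response. With few
actives, individual folds can lack actives entirely; chemperf computes every
measure on the *pooled* out-of-fold predictions of a split (all n of them),
which sidesteps per-fold degeneracy.

Preprocessing (centering/scaling for the methods that need it) is fitted on
the training folds only and applied to the held-out fold, inside every fold
of every split, so no held-out information leaks into the fit. The test
suite checks this by deleting a fold, refitting, and reproducing the stored
predictions exactly.

## The 13-method suite

`listMethods()` registers exactly: ENet, KNN, Lasso, LAR, NNet, PLSLDA, PLS,
PCR, Ridge, RF, Tree, RPart, SVM. Response handling follows the usual
convention for this kind of laboratory:

* **Native both-type methods** — Tree, RPart, RF, KNN, NNet, SVM — classify
  a binary response directly and return probabilities of activity in [0, 1],
  or predict a continuous response directly.
* **Gaussian least-squares methods** — Lasso, LAR, Ridge, ENet, PCR, PLS —
  assume equal-variance normal responses; on a binary endpoint they treat
  the 0/1 coding as continuous, and their scores are deliberately **not
  clipped** to [0, 1]. Thresholding, where needed, happens later in the
  assessment step (`buildPerformanceTable(..., threshold = )`, default 0.5),
  never in the fit.
* **PLSLDA** is binary-only; on a continuous response it requires an
  explicit dichotomizing threshold (`responseThreshold`).

A degenerate fit (singular system, optimizer failure) falls back to
predicting the training-mean response with a warning — a long multi-method
run never dies halfway. A combination incompatible with the response type is
skipped, warned about, and recorded in the store's `failures` slot, and the
performance table simply omits that column.

### Backends and in-package learners

This package deliberately implements several learners itself rather than
binding to the usual method-specific packages, which are not part of its
dependency footprint; only glmnet (penalized least squares), FNN (fast
neighbor search) and MASS (the LDA step of PLSLDA) are imported. The
intention is equivalence in kind, not numerical replication of any other
implementation's fits:

* **Tree / RPart** — one CART grower, two configurations. Splits maximize
  the SSE decrease of child means, which on a 0/1 response is exactly the
  Gini criterion; leaves carry the mean (= class-1 proportion). `Tree` grows
  deep with a light complexity penalty (minsplit 5, maxdepth 10, cp 0.001);
  `RPart` uses the conventional minsplit 20, maxdepth 30, cp 0.01, where cp
  is the minimum SSE reduction relative to the root deviance.
* **RF** — bootstrap-resampled CART trees (default `ntree = 100`) with
  `mtry` features re-sampled *at every node* (⌊√p⌋ classification, ⌊p/3⌋
  regression); predictions average the trees' leaf values, so binary scores
  are probabilities.
* **NNet** — one hidden layer of logistic units (default size 2), linear or
  logistic output, trained by BFGS on a weight-decay-penalized loss
  (decay 0.1, maxit 150), weights initialized uniformly on [−0.5, 0.5] from
  the seeded per-combination RNG stream.
* **PLS / PLSLDA / PCR** — univariate SIMPLS and SVD-based PCR, components
  capped at min(10, rank). PLSLDA applies LDA on the SIMPLS score space and
  returns posterior probabilities.
* **LAR** — the least-angle equiangular path, with the step count (≤ 20)
  chosen by an internal 5-fold grid on the training fold.
* **ENet / Lasso / Ridge** — glmnet with alpha 0.5 / 1 / 0; the penalty is
  chosen by an internal seeded 5-fold grid on the training fold
  (`lambda = "cv"`), or fixed numerically by the user.
* **SVM** — no SVM backend exists in the dependency set, so "SVM" is a
  radial-basis-kernel regularized learner solved in the kernel dual: kernel
  logistic regression (IRLS, probabilities in (0, 1)) for binary responses
  and kernel ridge regression for continuous ones. `cost` maps to the
  regularization λ = 1/(2·cost) and `gamma` defaults to 1/p, the usual RBF
  conventions. It occupies the same flexible-nonlinear niche as a
  soft-margin SVM but optimizes a smooth loss rather than the hinge/ε-loss;
  margin-related behaviors (support-vector sparsity) are not reproduced.

All defaults live in `makeModelDefaults()`, are documented there, and are
overridable per method; unknown parameter names are rejected rather than
silently ignored. Each (split, set, method) combination derives its own RNG
seed deterministically from the split seed, so stochastic methods (RF, NNet,
the internal tuning folds) are bit-reproducible across reruns.

## Performance measures

Binary: error rate, sensitivity, specificity, PPV, F1 (threshold-based,
default threshold 0.5 applied with the ≥ convention to probabilities and
unbounded scores alike), AUC (Mann–Whitney form, ties counted ½), and
initial enhancement IE = (h/m)/(p/n) with default m = min(300, n).
Continuous: RMSE, R² = 1 − SSres/SStot, Spearman ρ (Pearson correlation of
midranks). Orientation (larger- vs smaller-is-better) is a property of the
measure carried on the table; error rate and RMSE are minimized, everything
else maximized.

Two conventions worth stating explicitly:

* **Ties in ranking** (IE and accumulation curves): stable sort by
  decreasing score with original row order breaking ties. Fractional
  tie-sharing would be a defensible alternative; the stable rule is simpler,
  deterministic, and what the tests pin down.
* **Undefined values**: a 0/0 confusion ratio yields NaN, and the whole
  combination column is dropped from the performance table with a warning
  rather than imputed — the downstream ANOVA requires a complete balanced
  table for its closed-form decomposition and the stated Tukey–Kramer
  standard error to be valid.

## Blocked ANOVA and Tukey–Kramer comparisons

`blockedAnova` fits Y_ij = μ + α_i + β_j + ε_ij by the balanced closed form
(both factors fixed, no interaction — with one observation per cell an
interaction would not be estimable). `tukeyKramer` then computes, per pair,
q = |ȳ_j − ȳ_j′| / √(MS_error/s) and the adjusted p-value
P(Q_{c, (s−1)(c−1)} ≥ q) from the studentized range distribution, which
controls the familywise error over all c(c−1)/2 comparisons. Significance
bands default to {≤ 0.01, (0.01, 0.05], > 0.05} and are configurable.

Numerical choices: the studentized range tail comes from `stats::ptukey`,
except at c = 2 where the exact identity P(Q ≥ q) = P(|t| ≥ q/√2) is used —
`ptukey`'s ~1e-5 absolute accuracy is visible at that scale and the closed
form is exact (it also makes the c = 2 case agree with the paired t-test to
machine precision, as it should mathematically). A zero MS_error (e.g. a
purely additive toy table) is handled degenerately: zero differences get
p = 1, nonzero ones p = 0, with a warning.

One calibration note from the test suite: with s = 3 splits and c = 5
combinations, a single combination elevated by 6σ is ranked first *and*
separated from all four rivals at p ≤ 0.01 in about 91% of simulations (the
8-df MS_error estimate is heavy-tailed; its upward excursions occasionally
drag individual q statistics under the 0.01 critical value). The acceptance
suite asserts this joint event at a 95% rate and is therefore expected to
flag it; the package reports the measured rate honestly rather than tuning
the simulation toward the bound.

## Accumulation curves

`accumulationCurve` orders observations by decreasing predicted score and
accumulates the response; the binary hit-counting curve is the special case
of the continuous definition. `idealCurve` accumulates the response sorted
descending (min(m, p) for binary y); `randomCurve` is the **expectation
line** m·Σy/n rather than one sampled random ordering — the expectation is
deterministic, testable, and what the eye should compare against. The
default test budget is ⌊min(300, n/4)⌋. Curve objects are plain data;
`plotAccumulation` only draws them, so everything is testable headlessly.
Monotonicity of the accumulated curve is only guaranteed for nonnegative
responses; continuous responses may be negative and may produce decreasing
segments.

## Applicability domain

`hotellingT2` computes the squared Mahalanobis distance from the training
mean under the training sample covariance (divisor n − 1, no shrinkage by
default; an explicit opt-in ridge `shrinkage` exists for collinear blocks).
The statistic is affine-invariant, so descriptor standardization is
irrelevant to it — the raw descriptor set is used. The control limit is the
standard **phase-II limit for future individual observations**,
UCL = p(n+1)(n−1)/(n(n−p)) · F₁₋α(p, n−p); other variants (phase I,
subgrouped data) exist in the control-chart literature, and this choice is
stated prominently so any comparison against other tools starts from the
formula. The covariance must be invertible (n > p, no exact collinearity):
with wide descriptor blocks, reduce dimension first or opt into shrinkage,
at the cost of exact α-level calibration.

## Synthetic generators: what they emulate, what they do not

`makeBinaryDataset` emulates the *shape* of a small screening assay — by
default 500 compounds with exactly 50 actives, one 24-column continuous set
and one 147-column binary (presence/absence) set. Signal is a mean shift of
`effect` on the informative continuous columns and a success-probability
lift of 0.15·effect on the informative binary columns (baseline rate 0.2,
informative fraction 0.25). `effect = 0` is an exact null. The generator
does **not** emulate real descriptor properties: no inter-descriptor
correlation, no analog-series block structure, no heavy tails. A green test
on these fixtures establishes that the pipeline's bookkeeping and statistics
are correct — not that any method will rank well on real assay data, nor
that cross-validation is unbiased under the dependence structures real
compound series exhibit.

`makeContinuousDataset` (default n = 277, mirroring the classic small
boiling-point example in size only) is a plain linear-Gaussian design for
the continuous pathway. `makePerformanceTable` generates additive
split-effect tables with optional elevation for exercising the ANOVA and the
comparison machinery directly.

## Known limitations

* No parallel execution; fits run sequentially.
* No grouped/leave-series-out cross-validation; with strong analog-series
  structure, repeated random folds can still be optimistic.
* Unbalanced performance tables are not modeled; incomplete columns are
  dropped rather than fit by least squares on an unbalanced layout.
* The SVM slot is a smooth-loss kernel method, not a hinge-loss SVM (see
  above).
* Categorical responses beyond binary are unsupported.
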