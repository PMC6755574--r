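# chemperf

A modeling laboratory for QSAR-style problems in cheminformatics and drug
discovery. Given compounds described by one or more named *descriptor sets*
(blocks of continuous or binary features) and a binary (active/inactive) or
continuous (larger = more active) endpoint, chemperf:

1. fits a suite of **13 machine learning methods** (elastic net, k-nearest
   neighbors, lasso, least angle regression, neural network, PLS-LDA, PLS,
   principal components regression, ridge, random forest, two recursive
   partitioning variants, and a radial-kernel SVM-type learner) to every
   descriptor set under **repeated, seeded k-fold cross-validation**, where
   every descriptor-set/method (D–M) combination within a split shares the
   identical fold assignment — the split is a *blocking factor*;
2. scores the pooled out-of-fold predictions with cheminformatics-oriented
   performance measures (initial enhancement, AUC, sensitivity, specificity,
   PPV, F1, error rate; RMSE, R², Spearman ρ for continuous endpoints) and
   **accumulation (hit-enrichment) curves** with ideal and random references;
3. decides which D–M combinations differ *significantly* via a blocked
   two-way ANOVA and **Tukey–Kramer multiplicity-adjusted pairwise
   comparisons**, visualized as a multiple-comparisons-similarity (MCS)
   matrix;
4. assesses **applicability domain** for external compounds with a phase-II
   Hotelling T² control chart.

## The statistics in brief

For each split *i* and D–M combination *j*, one measure value `Y_ij` is
computed on that split's pooled out-of-fold predictions, and the blocked
model

    Y_ij = μ + α_i + β_j + ε_ij

is fit (α = split/block effect, β = combination effect, one observation per
cell). Pairwise differences of combination means are tested with the
studentized range statistic q = |ȳ_j − ȳ_j′| / √(MS_error / s) against
Q(c, (s−1)(c−1)), controlling the familywise error over all c(c−1)/2
comparisons — 153 comparisons for the typical 2-descriptor-set × 9-method
layout of 18 combinations.

Initial enhancement at *m* tests is the hit rate among the top-*m* ranked
compounds divided by the base rate of actives, IE = (h/m)/(p/n) — the
fold-improvement over random screening (default m = 300). Accumulation
curves plot Σy over the first *m* tests in decreasing-score order, up to
⌊min(300, n/4)⌋ tests by default.

For applicability domain, T²(x) = (x − x̄)ᵀ S⁻¹ (x − x̄) with training mean
x̄ and covariance S, compared against the phase-II limit for future
individuals UCL = p(n+1)(n−1)/(n(n−p)) · F₁₋α(p, n−p).

## Worked example

```r
library(chemperf)

# synthetic dataset shaped like a small screening assay:
# 200 compounds, 40 actives, a continuous and a binary descriptor set
cml <- makeBinaryDataset(n = 200, nActive = 40, nContinuousDesc = 8,
                         nBinaryDesc = 20, effect = 1.2, seed = 1)
plan <- makeCvPlan(nObs(cml), nsplits = 3, nfolds = 5)   # seeds 11111, 22222, 33333
params <- makeModelDefaults()
params$RF$ntree <- 50
store <- runRepeatedCV(cml, methods = c("RF", "KNN", "Lasso", "SVM"),
                       plan = plan, params = params)

tbl <- buildPerformanceTable(store, measure = "ie", m = 40)
blockedAnova(tbl)
```

```
Blocked two-way ANOVA (Y_ij = mu + alpha_i + beta_j + eps_ij)
                Df   Sum Sq    Mean Sq   F value       Pr(>F)
split            2 0.328125 0.16406250  5.444444 1.781795e-02
D-M combination  7 2.384766 0.34068080 11.305556 8.250892e-05
residual        14 0.421875 0.03013393        NA           NA
```

The split main effect (p ≈ 0.018) shows fold assignment alone moves initial
enhancement — exactly why it is treated as a blocking factor. The D–M effect
is highly significant, so some combinations really do perform differently:

```r
comp <- tukeyKramer(tbl)
comp
```

```
Tukey-Kramer comparisons of 8 D-M combinations ( 28 pairs ), measure: ie
  best -> worst: ContinuousSet_Lasso > ContinuousSet_SVM > BinarySet_RF > ContinuousSet_RF > BinarySet_SVM ...
  pairs with p <= 0.01 : 4
```

An IE of 2.8 means the top-ranked 40 compounds contain 2.8× as many actives
as a random pick of 40. `plotMCS(comp)` renders the best-to-worst-ordered
significance matrix; `mcsMatrix(comp)` returns it as data. Here
ContinuousSet_Lasso is the nominal best, but its advantage over
ContinuousSet_SVM or BinarySet_RF is *not* significant — the defensible claim
is only that it beats the BinarySet KNN/Lasso combinations.

Accumulation curves and the applicability domain:

```r
groups <- curveSeries(store, "descriptors", splits = 1)
plotAccumulation(groups[[1]])

chart <- controlChart(descriptorSets(cml)$ContinuousSet,
                      newDescriptors, alpha = 0.01)
outlierIndices(chart)   # external compounds whose predictions are extrapolations
```

A thin command-line wrapper over the same functions lives at
`system.file("scripts", "chemperf.R", package = "chemperf")`, with
subcommands `fixture`, `fit`, `assess`, `curves`, `mcs` and `ad`; `fit`
reads a JSON config and writes a run manifest recording seeds, parameters
and a fold-assignment digest alongside the predictions CSV.

## Acceptance script

`scripts/acceptance.R` rebuilds a complete 3-split × 18-combination
performance table with the package's own generator, runs the blocked ANOVA
and the full Tukey–Kramer pairwise pass, and reports the number of
multiplicity-adjusted comparisons produced as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Scope notes

chemperf consumes *precomputed* descriptor tables (CSV or matrices); it does
not compute chemical descriptors from structures. Responses are binary 0/1
or continuous; categorical endpoints with more than two levels are not
supported. See `vignettes/chemperf-methods.Rmd` for the modeling details,
default parameters and known limitations.
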