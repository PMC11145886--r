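---
title: "Discriminating similar disease states from plasma proteomes with correlation-cluster sentinel features"
author: "ProteoSentinel authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating similar disease states from plasma proteomes with correlation-cluster sentinel features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Plasma proteomes of closely related vascular diseases — here, descending
thoracic aortic aneurysm (DTAA) versus Stanford type B dissection of the
same vessel — can be so similar that per-protein differential statistics
find almost nothing: after false-discovery control, a single protein may
pass an adjusted-p threshold while the two conditions remain clinically
very different. ProteoSentinel implements an analysis strategy for this
regime: instead of asking which individual proteins differ, it asks how
well the two states can be *classified* from the quantified proteome, and
which groups of correlated proteins carry that classification.

The pipeline takes a DIA-style protein (or peptide) intensity matrix and
sample metadata and runs, in order:

1. **Cleaning** — complete-case feature filtering (any missing or exact-zero
   intensity removes the protein), removal of multi-accession protein
   groups, removal of samples with incomplete demographics or duplicated
   quantity columns, log2 transform, and empirical-Bayes batch correction
   (ComBat) across digestion plates.
2. **Univariate statistics** — per-protein pooled two-sample t-tests with
   Benjamini–Hochberg adjustment and log2 fold changes (disease minus
   control), plus exact contingency-table tests (Fisher 2×2 and its
   Freeman–Halton r×2 generalization) and the Wilcoxon rank-sum test for
   cohort characteristics.
3. **Correlation clustering** — Spearman correlations between proteins on
   the training partition only, dissimilarity `d = 1 - rho`, Ward
   agglomeration, and a cut at a linkage-distance threshold; one randomly
   chosen *sentinel* protein represents each cluster.
4. **Model selection** — a stratified 80/20 split; for each linkage
   threshold and each classifier family (gradient boosting, SVC, random
   forest, extra-trees, logistic regression, k-NN), a random hyperparameter
   search scored by stratified 5-fold cross-validated F1 on the minority
   class; the argmax (family, threshold) cell is refit on all training data
   and evaluated once on the held-out samples with accuracy, precision,
   recall, F1 and precision-recall AUC.
5. **Permutation importance** — on the held-out set, each sentinel column is
   shuffled repeatedly and the mean decrease in accuracy recorded; sentinels
   with positive importance are traced back to their full correlated
   clusters for reporting and enrichment export.

The point of the clustering step is decorrelation. Trained on correlated
features, a model can spread or arbitrarily concentrate its reliance across
a correlated group, and single-feature importance then under- or
over-states the group. One representative per cluster makes permutation
importance interpretable at the cluster level, and the sentinel-to-cluster
map restores the full protein list afterwards.

## A worked example

```{r, eval = FALSE}
library(ProteoSentinel)

cfg <- pipelineConfig(
  simulation = simConfig(seed = 42),
  thresholds = c(0.5, 1, 1.5, 2),
  families   = c("SVC", "LR", "RF"),
  n_iter     = 25, seed = 42, out_dir = "run42")
res <- runPipeline(cfg)

res$evaluation$report
chosenCell(res$sweep)
head(res$importance_positive)
```

All artifacts (cleaning report, volcano table, cluster membership, sweep
grid, test report, importance ranking, top-cluster protein list, manifest)
are written under `out_dir`; the manifest records every derived stage seed
so a run can be reproduced exactly.

## The synthetic-data generator

Real cohort data for this problem are not redistributable, so the package
ships a generator whose defaults emulate the statistical structure the
analysis assumes, with ground truth for recovery tests. On the log2 scale,
feature $f$ of block $b$ in sample $j$ is

$$x_{fj} = \mu_f + \sigma\left(\sqrt{c}\,F_{bj} + \sqrt{1-c}\,\epsilon_{fj}\right),$$

with $F_{bj}, \epsilon_{fj} \sim N(0,1)$, $c$ the within-block correlation
and $\sigma$ the total per-feature SD. The class effect is a shift of
$F_{bj}$ by `effect_size` in disease samples, for the designated informative
blocks only — the signal is carried by latent block factors, not by any
single protein, which is exactly the regime the sentinel strategy targets.
Batch effects are affine per plate on the log2 scale; the matrix is then
exponentiated, and zeros and missing cells injected.

Default parameters, chosen once:

| parameter | default | rationale |
|---|---|---|
| `n_samples`, `class_counts` | 137 = 75 + 62 | cohort scale and imbalance of the motivating study |
| `n_blocks`, `block_size` | 20 × 10 | 200 features, desk-scale, visibly blocked correlation structure |
| `within_block_correlation` | 0.8 | strong but not degenerate block correlation |
| `informative_blocks`, `effect_size` | {1, 2}, 1.5 | two block-level signals, detectable but not trivial at n = 137 |
| `n_batches` | 3 | three digestion plates |
| `batch_location_shift`, `batch_scale_factor` | 0.5, 1.05 | modest plate-level location/scale drift |
| `missing_rate`, `zero_rate` | 0.002, 0.001 | combined per-cell loss 0.003, so complete-case survival $(1-0.003)^{137} \approx 2/3$, the attrition a real DIA protein matrix showed under the same rule |
| `multi_id_fraction` | 0.17 | about one in six protein groups carries multiple accessions |
| `baseline_mean`, `noise_sd` | 20, 1 | plasma-like log2 intensities and dispersion |

What the generator does **not** emulate: intensity-dependent
missingness (its missing cells are uniform), heavy-tailed or
feature-specific noise, nested correlation (blocks within blocks), and any
relationship between demographics and the proteome. Tests passing on this
generator therefore show the pipeline's *mechanics* are right — leakage-free
training, correct decorrelation, calibrated null behavior, recoverable
block-level signal — not that a particular real cohort is classifiable.

## Design choices

**Pooled t-test by default.** The t-test variant is not dictated by the
analysis; the pooled-variance Student test is the default and Welch is
available via `var_equal = FALSE`. Both are two-sided.

**Signed dissimilarity.** `d = 1 - rho` keeps anti-correlated proteins
apart; for decorrelation purposes one can argue they belong together, so
`absolute = TRUE` switches to `1 - |rho|`.

**Ward on a non-Euclidean dissimilarity.** `1 - rho` does not in general
embed in Euclidean space. Ward linkage is applied to it anyway, as a
pragmatic and widely used convention; the Lance–Williams recursion is
algebraically self-consistent for any symmetric non-negative input, merge
heights remain monotone, and the package makes no minimum-variance claim.
Ties on the merge distance break toward the lexicographically smallest node
pair, so trees are fully deterministic. A useful, non-obvious consequence of
Ward's size dependence: duplicating every feature scales every positive
merge height by exactly $\sqrt 2$, so cluster counts are preserved at
$\sqrt 2$-scaled thresholds, not at identical ones.

**Threshold grid.** The default grid is 0 to 5 in steps of 0.25, covering
everything from all-singletons to a handful of clusters on typical
correlation trees; any vector can be supplied.

**Feature scaling.** SVC, logistic regression and k-NN are scale-sensitive
and receive z-scored features; the standardization statistics are computed
on the training partition (or training folds, inside CV) and frozen for
prediction. Tree ensembles consume raw values.

**Search spaces.** Per family, fixed and seeded: SVC — cost and gamma
log-uniform over $10^{\pm 2}$ and $10^{-3}..10^1$, kernel in
{linear, radial, polynomial}, degree 2–3; logistic regression —
elastic-net with log-uniform lambda and alpha in {0, 0.5, 1}; GB — 20–150
rounds, log-uniform learning rate 0.01–0.3, depth 2–6, row/column
subsampling 0.6–1; RF/ET — 100–300 trees, mtry fraction 0.2–1, minimum
node size 1–10 (ET additionally 1–3 random splits); k-NN — odd k from 1 to
25.

**Minority-class focus.** With imbalanced classes the positive class
defaults to the minority label; F1 drives both CV selection and the sweep
argmax, and the test report adds precision, recall and PR AUC. PR AUC is
computed as step-wise average precision with tied scores grouped — no
trapezoidal interpolation, which is optimistic on PR curves. Average
precision has a small positive finite-sample bias under random scores
(order $\log n / n$), which the calibration tests account for.

**Permutation importance.** Computed on the held-out set with the refitted
chosen model; accuracy (not F1) is the permuted metric. Each feature gets
independent fresh permutations per repeat; the baseline is computed once;
ranking ties break by feature id. With only two test samples a shuffle is
the identity or a swap with equal probability, giving the exact closed-form
expectation 1/2 for a perfect single-feature model — one of the package's
exactness tests.

**Batch correction.** `combatCorrect()` delegates to the parametric
empirical-Bayes ComBat implementation in `sva`, without covariates by
default (a `preserve_group` option keeps the class label as a covariate;
whether to protect biology during correction is a judgment call left to the
user). Mean-only correction is available. Note that EB shrinkage
intentionally leaves per-feature batch-mean residuals at the scale of the
estimation noise — roughly $\sqrt{2/n_b}\,\sigma$ for $n_b$ samples per
batch — rather than zeroing them; the injected shift is removed in
aggregate, and a second correction pass changes cells by an order of
magnitude less than the first. Exact zero residuals and strict idempotence
are properties of per-feature mean centering, not of the EB model.

**Exact tests.** The 2×2 Fisher test sums hypergeometric probabilities of
all margin-fixed tables not exceeding the observed table's probability
(relative tolerance $10^{-12}$). The Freeman–Halton r×2 test enumerates
first-column row counts depth-first with a dynamic-programming table count
checked against a cap ($10^7$ by default) before enumerating; above the cap
a seeded Monte Carlo estimate over margin-conditioned tables
(`r2dtable`) is available. Zero-margin rows are dropped; a degenerate
margin returns p = 1.

**Seed discipline.** One global seed per run; every stage (split, fold
assignment, per-cell search, sentinel draw, shuffles) derives its own seed
from it by a fixed integer hash, so any stage can be reproduced in
isolation and runs are byte-identical end to end.

## Problem sizes used by the test suite

The packaged checks run the full pipeline at the generator's default study
scale (137 samples, 200 features) with a reduced search — three families
(SVC, LR, RF), four thresholds (0.5–2), 25 random-search iterations — ten
seeds for signal recovery and twenty light-weight runs (LR, one threshold)
for null calibration. These sizes were chosen as the smallest at which the
block-recovery and null-calibration properties are statistically
meaningful; unit tests use a 60-sample, 30-feature configuration.

## Known limitations

- Ward-on-`1 - rho` is a convention, not a metric guarantee; rival choices
  (average linkage, `1 - |rho|`) can regroup borderline proteins.
- A single random sentinel per cluster is faithful to the method it
  implements but adds sentinel-draw variance; with small test sets the
  permutation importance of a true signal cluster can fall below zero in
  some splits.
- The exact Freeman–Halton enumerator is for r×2 tables (two cohorts);
  general r×c enumeration is out of scope.
- The pipeline exports protein lists for enrichment tools but performs no
  enrichment itself.
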