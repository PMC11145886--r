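# ProteoSentinel

Classification-oriented analysis of plasma proteomics intensity matrices
for discriminating two closely related disease states — built for the
setting where standard per-protein statistics find (almost) nothing, yet
the proteome still separates the conditions. The motivating application is
descending thoracic aortic aneurysm (DTAA) versus Stanford type B
dissection from DIA mass-spectrometry plasma protein quantities, but any
features × samples intensity matrix with a two-class label fits.

It is aimed at proteomics/metabolomics analysts who want the full chain —
cleaning, differential statistics, decorrelated machine-learning feature
selection, and cluster-level importance — as tested, seeded, reusable
functions rather than a one-off notebook.

## The method

Proteins are heavily correlated in plasma, which makes per-feature
importance of a classifier unstable and misleading. The pipeline
decorrelates first and interprets at the cluster level:

1. **Clean**: drop every feature with a missing or exact-zero intensity,
   drop multi-accession protein groups (`;`-joined ids), drop samples with
   incomplete demographics or duplicated quantity columns, `log2`
   transform, ComBat empirical-Bayes batch correction across plates.
2. **Test**: per-protein pooled two-sample t-tests with Benjamini–Hochberg
   adjustment; log2 fold change = mean(log2 disease) − mean(log2 control);
   exact Fisher (2×2) and Freeman–Halton (r×2) tests and Wilcoxon rank-sum
   for cohort characteristics.
3. **Cluster**: on the 80% training partition only, Spearman correlations
   ρ between all protein pairs, dissimilarity d = 1 − ρ, Ward linkage
   (d(A∪B,C) = √(((n_A+n_C)d²_AC + (n_B+n_C)d²_BC − n_C d²_AB)/ΣN)), flat
   clusters at a linkage-distance threshold t, and one randomly drawn
   **sentinel** protein per cluster.
4. **Select**: sweep t over a grid × six classifier families
   (GB, SVC, RF, ET, LR, KNN), each tuned by seeded random hyperparameter
   search with stratified 5-fold CV optimized on minority-class F1; the
   argmax cell is refit on all training samples and evaluated once on the
   held-out 20% (accuracy, precision, recall, F1, PR AUC as average
   precision).
5. **Interpret**: permutation importance on the test set — mean decrease in
   accuracy over 10 independent shuffles per sentinel — filtered to
   positive scores and mapped back to full correlated clusters; the top-k
   clusters' members are exported for pathway/enrichment tools.

A synthetic-data generator with block-latent-factor structure
(`simConfig()` / `generateDataset()`) emulates the cohort scale (137
samples, 75/62 imbalance, 200 proteins in 20 correlated blocks, 3 digestion
plates, sporadic missing/zero cells) and provides ground truth for recovery
and null tests.

## Worked example

```r
library(ProteoSentinel)

cfg <- pipelineConfig(
  simulation = simConfig(seed = 42),      # study-scale synthetic cohort
  thresholds = c(0.5, 1, 1.5, 2),
  families   = c("SVC", "LR", "RF"),
  n_iter     = 25, seed = 42, out_dir = "run42")
res <- runPipeline(cfg)

res$evaluation$report
#> TestReport (positive class = DTAA)
#>   accuracy 0.815 | precision 0.769 | recall 0.833 | F1 0.800 | PR AUC 0.831

chosenCell(res$sweep)[, c("family", "threshold", "n_clusters", "mean_cv_f1")]
#>    family threshold n_clusters mean_cv_f1
#> 12     RF         2         13  0.8075287

head(res$importance_positive[, c("feature_id", "mean_pi")])
#>   feature_id    mean_pi
#> 1     P00005 0.22222222
#> 2     P00016 0.14444444
#> 3     P00126 0.08148148
#> 4     P00067 0.07037037
#> 5     P00189 0.04074074
#> 6     P00107 0.02222222
```

Reading the output: the sweep chose a random forest at linkage distance 2,
where the 200 simulated proteins collapse to 13 decorrelated clusters; the
held-out minority-class F1 is 0.80. The two top positive-importance
sentinels, P00005 and P00016, are members of simulated blocks 1 and 2 —
exactly the two blocks whose latent factors carry the class effect in this
dataset — so the cluster-level importance ranking recovered the planted
signal. `run42/` contains the cleaning report, volcano table, cluster
membership, sweep grid, test report JSON, importance table, top-cluster
protein list and a seed manifest.

A thin command-line wrapper with subcommands `run`, `simulate`, `clean`,
`stats`, `sweep`, `importance` is installed at
`system.file("scripts", "proteosentinel.R", package = "ProteoSentinel")`.

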