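# txensemble

Ensemble meta-classification of differential isoform expression calls.

## The problem

Differential isoform expression analysis (DIEA) asks whether individual
transcript isoforms change abundance between conditions. The many available
DIEA pipelines disagree with each other and, worse, report incompatible
significance metrics: some emit a *p*-value and an FDR-adjusted *q*-value per
transcript, some a posterior probability of differential expression (PPDE),
and some a probability of positive log ratio (PPLR, where 0.5 means no
evidence and values near 0/1 indicate down-/up-regulation). Because no direct
relation exists between these metrics, classical *p*-value combination cannot
merge them. `txensemble` instead treats the tools' heterogeneous scores as a
per-transcript feature vector and trains a supervised meta-classifier against
simulated ground truth, producing a single meta-prediction of differential
expression that combines the strengths of the individual tools.

The package is for bioinformaticians who run several transcript-level DE
tools and want a principled, reproducible way to integrate and benchmark
their outputs.

## What is inside

- **Score harmonization** (`read_tool_table()`, `harmonize()`): per-tool
  features on a common "larger = more DE" scale — capped −log₁₀ *p* and
  −log₁₀ *q* for PQ tools, PPDE passed through, PPLR folded to evidence
  2·|PPLR − 0.5| plus a signed direction; missing transcripts get
  no-evidence imputation (p = q = 1, PPDE = 0, PPLR = 0.5).
- **Meta-classifiers** (`fit_model()`, `predict()`): a from-scratch
  **rotation forest** (per tree: random feature subsets, per-subset PCA on a
  class-and-row subsample, block-diagonal orthonormal rotation, CART on the
  rotated data) plus unified wrappers for SVM, random forest and XGBoost,
  all emitting calibrated scores in [0, 1]; models persist via
  `save_model()` / `load_model()`.
- **Model selection** (`random_grid_search()`, `cross_validate()`): random
  hyperparameter search scored by stratified k-fold CV accuracy.
- **Score-level simulator** (`sim_preset()`, `simulate_scores()`): a
  shared-latent-signal model of six heterogeneous pipelines over a
  20,000-transcript universe with presets `set1`/`set2`/`set3`
  (500/1000/2000 DE transcripts, half up- and half down-regulated),
  exactly seeded and deterministic.
- **Evaluation and ranking** (`metric_report()`, `rank_methods()`,
  `best_per_metric()`): accuracy, sensitivity, specificity, NPV, PPV,
  rank-based AUC and directional true-positive rates; method comparison by
  per-metric ranks aggregated as rank-sum / number of methods.
- **CLI** (`run_cli()`, `inst/cli/txensemble.R`): `simulate`, `harmonize`,
  `train`, `predict`, `evaluate`, `rank` subcommands with seeded,
  manifest-tracked outputs.

## Worked example

Simulate the `set2` condition, train an XGBoost meta-classifier on half the
transcripts, and compare it with the six simulated tools on the held-out
half:

```r
library(txensemble)

sim <- simulate_scores(sim_preset("set2", seed = 42))
sim$truth
#> <ground_truth> 20000 transcripts (500 up, 500 down, 19000 none)

fm <- harmonize(sim$tables, sim$truth$transcript_id)
x  <- feature_values(fm); y <- is_de(sim$truth)
set.seed(42); test <- sample(c(TRUE, FALSE), nrow(x), replace = TRUE)

model <- fit_model(model_spec("xgboost", seed = 42), x[!test, ], y[!test])
scores <- predict(model, x[test, ])
```

Evaluating the meta-classifier and each tool (at q ≤ 0.05 / PPDE ≥ 0.95 /
PPLR evidence ≥ 0.9) on the held-out transcripts and ranking them:

```
           method accuracy sensitivity specificity   npv   ppv   auc
1    xgboost_meta    0.993      0.9459       0.996 0.997 0.918 0.999
2     sleuth_like    0.955      0.0842       1.000 0.954 1.000 0.913
3     tuxedo_like    0.958      0.1683       1.000 0.958 0.955 0.930
...
           method accuracy sensitivity specificity npv ppv auc score
1    xgboost_meta        1           1           4   1   4   1   1.7
2     sleuth_like        3           6           1   6   1   3   2.9
3     tuxedo_like        2           5           3   5   3   2   2.9
```

The meta-classifier recovers ~95% of the truly DE transcripts at 99.6%
specificity and takes the top aggregated rank (1.7): integrating six
imperfect, heterogeneous voters beats every individual one. Each tool's
`score` column keeps its continuous evidence, so the AUC column reflects
ranking quality independent of the binarization cutoffs.

The same comparison for a *published* benchmark table ships with the
package: `rank_methods(benchmark_metric_table())` aggregates the ten
methods' six metrics into a single ranking (XGBoost first at 1.9).

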