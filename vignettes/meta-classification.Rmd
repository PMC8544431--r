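---
title: "Meta-classification of heterogeneous differential isoform expression scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-classification of heterogeneous differential isoform expression scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txensemble)
```

## The integration model

Transcript-level differential expression tools disagree not only in their
calls but in the *kind* of evidence they report. `txensemble` groups tools
into three metric families:

* **PQ** — a *p*-value and an FDR-adjusted *q*-value per transcript;
* **PPDE** — a posterior probability of differential expression in [0, 1];
* **PPLR** — the probability of a positive log ratio, where 0.5 means no
  evidence and the two tails encode direction.

No closed-form combination (e.g. Fisher's method) applies across these
scales, so the package takes a supervised route: each transcript's scores
across all tools become a feature vector, and a binary classifier is trained
on data where the DE status is known (simulated data, or any experiment with
an accepted truth set). The classifier's output score in [0, 1] is the
meta-prediction; 0.5 is the call cutoff.

### Feature encoding

The feature map must put all families on a comparable "larger = more
evidence" scale while losing nothing a tree or kernel model could use:

* PQ → `-log10(p)` and `-log10(q)`, capped at `cap` (default 10) so p = 0
  maps to the cap instead of infinity. Both enter: the *p* carries the raw
  test evidence, the *q* the multiplicity-adjusted one, and tree ensembles
  are indifferent to the redundancy.
* PPDE → passed through unchanged (already a calibrated evidence scale).
* PPLR → folded evidence `2|PPLR - 0.5|` in [0, 1] plus a separate signed
  direction feature `sign(PPLR - 0.5)`. Folding makes the evidence axis
  monotone; the direction feature preserves the sign information that
  folding discards.

Transcripts a tool fails to report receive that tool's *no evidence* values
before the transform (p = q = 1, PPDE = 0, PPLR = 0.5): the absence of a
call is treated as the absence of evidence, never as missing data, so the
feature matrix is always complete. A consequence worth knowing: an imputed
transcript can never be called DE by that tool under any sensible cutoff.

Feature columns are ordered by tool name, so the matrix is invariant to the
order score tables are supplied in.

### Binarizing individual tools

For tool-versus-meta comparisons each tool is reduced to calls with
family-specific cutoffs, inclusive at the boundary: q ≤ 0.05, PPDE ≥ 0.95,
folded PPLR evidence ≥ 0.9. These are configurable defaults chosen as the
conventional working thresholds of each family, not tuned values. Note the
asymmetry they imply: the q cutoff controls FDR across the experiment,
whereas a posterior cutoff is per-transcript — with a diffuse posterior
calibration some null transcripts will exceed 0.95 by chance, which is
visible in the simulator's PPDE tools (their specificity sits near 0.93
rather than 0.999).

## The simulator

The generator emulates the *outputs* of six heterogeneous pipelines rather
than their inputs: read-level simulation with an RNA-seq read simulator
plus six alignment/quantification pipelines is days of compute, while
everything the integration layer consumes is the per-transcript score
tables and the truth labels.

Each transcript *t* carries a latent signal `s_t = mu * d_t` with direction
`d_t` in {+1, −1, 0}; the condition presets fix the composition exactly
(`set1`/`set2`/`set3`: 500/1000/2000 DE transcripts out of 20,000, half up
and half down, counts exact rather than stochastic). Tool *k* observes

    z_tk = s_t + e_tk,   e_tk ~ Normal(0, 1 + tau_k^2)

independently across tools: a unit-variance baseline measurement noise plus
a tool-specific component `tau_k^2`. Writing the total null variance as
`1 + tau^2` keeps the PQ p-value map — the two-sided tail probability of
`z` under Normal(0, 1 + tau^2) — *exactly* calibrated, so null p-values are
exactly uniform (a property the test suite checks with Kolmogorov–Smirnov
statistics across seeds). q-values are the Benjamini–Hochberg adjustment of
the p column; PPDE tools report `plogis(a|z| - b)` with a = 2, b = 2
(logistic midpoint at |z| = 1, giving realistic class overlap); the PPLR
tool reports `pnorm(z / sd(z))`.

Because the signal is shared and the noise is not, tool scores are strongly
correlated on DE transcripts (through the signed scores — the latent effect
has constant magnitude, so the correlation lives in the direction) and
independent on nulls. That is precisely the statistical structure that makes
meta-classification worthwhile: six conditionally independent noisy looks at
the same signal.

Defaults were fixed once, as follows:

* `effect_mean = 3.0`: a moderate effect giving individually imperfect
  tools (per-tool AUC 0.86–0.93 at `set2` scale) — strong enough to learn
  from, weak enough that integration has room to help.
* Per-tool noise `tau`: 0.8/0.6/1.1 for the three PQ profiles, 0.9/1.1 for
  the PPDE profiles, 1.0 for PPLR. Distinct values ensure no tool dominates;
  the levels were chosen so tool-level accuracy and AUC land in the broad
  range reported for real pipelines on comparable simulations. One known
  departure from real pipelines: with a 5% DE prevalence, BH at q ≤ 0.05
  leaves the PQ tools' binarized *sensitivity* low (≈ 0.1–0.2) even though
  their rankings (AUC ≈ 0.9) are good; real PQ pipelines on strong
  fold-changes report much higher sensitivity. The meta-vs-tool comparison
  is insensitive to this because it uses all six metrics.
* One pseudo-random stream per tool, derived from the master seed by a fixed
  affine map modulo 2^31 − 1, so appending a profile never changes the other
  tools' scores.
* Per-tool dropout (transcripts a pipeline fails to report) defaults to 0
  and is configurable.

What the simulator does *not* emulate: count overdispersion, length and
coverage biases, correlated errors between pipelines that share an aligner,
and miscalibrated posteriors. Passing tests on simulated data therefore
demonstrate the integration machinery works where its assumptions hold, not
that a trained model transfers to an arbitrary real dataset — retraining
against a truth set matched to the data at hand is the intended workflow.

## The classifiers

Four families sit behind one interface (`model_spec()` + `fit_model()`):
SVM (RBF by default), random forest, XGBoost, and a rotation forest
implemented in the package.

**Rotation forest.** Per tree: randomly partition the features into subsets
of size M (default 3); for each subset, select a random subset of classes
(each retained with probability 0.75), subsample 75% of their rows without
replacement, and compute the PCA of that sample restricted to the subset's
features; assemble all loading matrices into a block-diagonal rotation;
train a full-depth CART tree on the *entire* dataset rotated by it.
Prediction averages the trees' class probabilities. All components are
retained, so every rotation is orthonormal (checked to 1e−8 in the tests)
and the rotated problem is informationally equivalent to the original — the
randomized rotations only diversify the axis-aligned splits available to
each tree. The PCA uses the eigendecomposition of the covariance matrix
rather than an SVD of the data so that rank-deficient subsets still yield a
complete orthonormal basis. With one tree, one subset spanning all features
and full fractions, the model collapses to a single tree on the globally
PCA-rotated data, which the tests verify against an independently composed
PCA + tree.

**Common output scale.** Tree ensembles report probabilities natively;
XGBoost uses its logistic objective; SVM decision values are passed through
a logistic link fitted on the training decision values, which both maps to
[0, 1] and fixes the sign convention. Labels are scores ≥ 0.5.

**Class imbalance.** `set1` is 2.5% positive, so balanced class weighting
is the default everywhere (inverse-frequency case weights for the tree
learners and SVM, `scale_pos_weight` for XGBoost), and all cross-validation
folds are stratified.

**Determinism and persistence.** A fit is a pure function of (spec, data):
the spec's seed drives every random draw, XGBoost runs single-threaded.
Models persist as a versioned archive (format tag, spec, feature names,
training metadata, fitted state; XGBoost stored in its portable raw form)
and a loaded model predicts identically to the saved one.

**Hyperparameter search.** `random_grid_search()` samples n_models
combinations from the expanded grid (without replacement when possible),
scores each by stratified k-fold CV accuracy, and returns the best with
ties to the earlier trial. The cost is exactly n_models × k fits — the
linear scaling in the number of trained classifiers that makes random
search predictable — and every trial lands in the log. Default grids are
small and shipped as data (`default_grid()`).

Default sizes worth noting: random forest uses 100 trees (a desk-scale
default for ~20,000 × 10 feature matrices; accuracy plateaus well before
that here), rotation forest 10 trees of unlimited depth, XGBoost 100 rounds
at depth 4.

## Evaluation and ranking

`metric_report()` computes accuracy, sensitivity, specificity, NPV, PPV, a
rank-based AUC (pairwise concordance with ties at ½, invariant under
monotone transforms), and two directional rates: the fraction of truly
up-regulated transcripts called DE and the same for down-regulated — DE
calling is direction-agnostic, so these diagnose directional asymmetries.
Zero-denominator metrics return `NA` rather than erroring; evaluation takes
the class prevalence from its input data and applies no correction.

`rank_methods()` turns a methods × metrics table into a single ordering:
within each metric, rank descending with ties broken by input row order;
aggregate each method as rank-sum divided by the **number of methods**. The
divisor follows the convention of the benchmark table bundled with the
package (`benchmark_metric_table()`), whose published aggregated scores are
reproduced exactly by this formula — e.g. the XGBoost row's ranks
(1, 1, 9, 6, 1, 1) sum to 19, giving 1.9 across 10 methods. Row-order
tie-breaking is likewise forced by that table: its RF and RTF rows tie on
accuracy at 0.9807 and resolve 4-then-5 in row order. Methods with an
undefined metric are excluded from ranking with a warning; imputing a rank
for an undefined quantity would be arbitrary.

## Problem sizes and runtime choices

The test suite exercises the full study conditions where they are the point
— preset composition, null p-value uniformity (20 seeds × 20,000 nulls),
the held-out meta-versus-tools comparison (20 seeds of `set2`), and CV
stability (5 seeds × 10 folds at `set2` scale) — and desk-scale reductions
(a few hundred to a few thousand transcripts at `set2` prevalence)
everywhere the property under test does not depend on n. The
meta-vs-tools protocol: split the universe in half at random, train XGBoost
and random-forest meta-classifiers on one half, evaluate all eight methods
(two metas + six binarized tools) on the other, rank with
`rank_methods()`, and ask whether both metas score at or below the best
individual tool; this holds in well over 70% of seeds.

## Known limitations

* The simulator's Gaussian, constant-magnitude effect model is deliberately
  minimal; see above for the real-data features it omits.
* Probability calibration beyond the SVM logistic link is out of scope.
* The evaluator trusts its input prevalence; it does not reweight metrics
  to a reference class balance.
* Converters from the native output formats of specific pipelines
  (sleuth, Cuffdiff, EBSeq, BitSeq, RSEM) are an extension point: the
  package consumes the normalized TSV schema documented in
  `read_tool_table()`.
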