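---
title: "Adaptive cluster-guided SFE: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive cluster-guided SFE: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acgsfe)
```

## The problem and the model

Microarray-style two-class datasets pair thousands of features (genes) with
tens of samples. A wrapper feature selector — one that scores candidate
feature subsets by the cross-validated accuracy of a classifier — can in
principle capture feature interactions that univariate filters miss, but at
these sample sizes the cross-validated score is itself a noisy, easily
overfit objective: greedy search finds "lucky" noise features whose
validation accuracy exceeds that of the truly informative ones, and the
selected sets differ wildly between runs.

`acgsfe` implements a hybrid that constrains the wrapper with two filter
stages computed once per dataset on the training partition:

1. **Feature clustering.** Features are embedded as rows of their Pearson
   correlation matrix and grouped by Ward's minimum-variance linkage, so
   that features with similar correlation profiles — co-regulated or
   redundant genes — share a cluster. The number of clusters is chosen by
   scoring every candidate `k` in a range driven by the
   feature-to-observation ratio with min–max-normalized Davies–Bouldin and
   mean-Silhouette indices, minimizing
   `0.5 * normalized_db + 0.5 * (1 - normalized_sil)`.
2. **Adaptive intra-cluster regularization.** Within each cluster, features
   are ranked by their mutual information (MI) with the class label
   (joint-histogram estimate, natural log). A per-cluster cap — up to
   `ceiling(3 * 1.5) = 5` features early in the search, exactly 1 at the end
   of the budget — retains only the top-ranked candidates.

The wrapper around these is the single-agent SFE scheme: a binary mask is
perturbed by a *non-selection* operator that deselects a linearly decaying
number of random selected features, rescued by a *selection* operator that
guarantees at least one selected feature, and proposals are accepted
greedily when their stratified k-fold 1-NN validation accuracy is at least
the incumbent's (ties accepted — this matters for plateau traversal and is
deliberately `>=`, not `>`).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `FEs_max` | 6000 | fitness evaluations per run (one per iteration) |
| `Run_max` | 30 | independent runs per dataset |
| `UR_max`, `UR_min` | 0.3, 0.001 | endpoints of the linear non-selection-rate decay (fraction of all `D` features eligible for deselection) |
| `SN` | 1 | bits switched on by the rescue operator |
| `k_folds` | 5 | stratified CV folds inside the training partition |
| `knn_k` | 1 | neighbors in the KNN fitness/test classifier |
| `mi_bins` | 10 | equal-width histogram bins for the MI estimate |
| `split_seed` | 42 | seed of the shared 80/20 split and folds |
| `test_fraction` | 0.2 | held-out proportion |
| `regularize_scope` | `"all"` | candidate set of the regularization (below) |
| `mode` | `"acgsfe"` | `"sfe"` disables clustering + regularization |

The bin count for MI deserves a note: histogram MI estimates on a few dozen
samples carry an upward bias that grows with the number of bins, so the
*ranking* — the only thing the regularization consumes — is what matters,
not the absolute values. Ten equal-width bins is a conventional default and
is exposed in `search_config()` so sensitivity can be tested. Labels are
never binned, and the log base (nats) only rescales scores uniformly.

## The regularization candidate set

`regularize_scope` controls which features compete within a cluster:

* `"all"` (default): every member of the cluster is a candidate. The
  regularized mask is then a deterministic function of the MI ranking and
  the per-cluster cap draw, and the wrapper's role reduces to choosing —
  through greedy acceptance across the shrinking-cap schedule — *how many*
  top-ranked features per cluster to keep. This is what produces the
  method's signature behavior: independent runs converge to identical or
  near-identical small subsets (pairwise Jaccard at or near 100 %), with
  selected-feature counts that barely vary across runs.
* `"selected"`: only the cluster members currently selected in the
  wrapper's proposal compete, making regularization a pure pruning step and
  the search a genuine stochastic hill climb. This variant explores through
  single-feature insertions and in our experiments is markedly less stable
  and recovers planted informative features far less reliably, because the
  greedy acceptance on an overfit validation score blocks the informative
  insertions. It is retained because it is the natural "wrapper-first"
  reading of the design, and because the contrast between the two scopes is
  itself informative.

The default is `"all"` precisely because the stability and
feature-count behavior it produces matches what this family of methods is
valued for; users who want the wrapper-dominant variant can switch scopes
with one argument.

## Splitting and randomness

All splitting is deterministic given one integer seed. The holdout uses
per-class `round(n_c * fraction)` (round-half-to-even) with the largest
class adjusted by the residual so the global test size is
`round(n * fraction)` — on a 40/22 class layout at 20 % this yields a
12-sample test set, on 58/19 a 15-sample one. Folds deal each shuffled class
round-robin, so per-fold class counts differ from proportionality by at most
one sample.

Each run derives two private RNG streams from its seed (operators,
regularization draws), and the split has its own stream; the streams are
implemented by swapping `.Random.seed` states, so package code never
perturbs — and is never perturbed by — the user's session RNG, and toggling
the regularization does not shift the operator draws. One uniform draw is
consumed per cluster per iteration whether or not the cluster has
candidates, which keeps the draw sequence aligned across scope variants.

## Numerical choices and degenerate inputs

* **Ward composition.** "Ward clustering of the correlation matrix" is
  realized as `hclust(dist(corr_rows), method = "ward.D2")`: Euclidean
  distance between correlation-profile rows is the only composition
  compatible with Ward's variance criterion, and `ward.D2` matches the
  standard squared-increase merge rule.
* **Cluster-range clamp.** For tiny ratios the range formula yields
  `max_clusters < 2`; it is clamped to 2 since the candidate range starts
  there.
* **Min–max degeneracy.** If all candidate `k` share one Davies–Bouldin (or
  Silhouette) value, its normalized value is defined as 0 — a constant term
  cannot discriminate, and this avoids 0/0.
* **Uncomputable indices** (e.g. coincident embedding points) become `NaN`
  and the candidate is skipped; if every candidate is invalid the minimum of
  the range is returned. Ties in the combined score break to the smallest
  `k` (coarser grouping, fewer per-cluster caps).
* **Singleton silhouette** is 0 by the standard convention; a zero-diameter
  embedding takes the `NaN` pathway.
* **Constant features** get correlation 0 against everything, keeping the
  embedding complete; a constant feature also collapses to a single MI bin
  and scores 0.
* **Rounding.** The non-selection count rounds half away from zero;
  deselection samples distinct indices (flipping an index twice is
  meaningless). `Nvar` is the total feature count, not the selected count.
* **MI tie-breaks** go to the smaller feature index, making rankings stable
  and runs reproducible.
* **Train accuracy** for the overfitting RMSE is 1-NN resubstitution on the
  training partition (the fitted reference set includes the query points, so
  it is 100 % unless duplicate points carry conflicting labels). This makes
  the per-run RMSE `|100 − test accuracy|` in practice, which is exactly the
  worst/best/mean structure the metric is meant to expose.
* **F-measure positive class** defaults to the minority class — the
  convention of interest on imbalanced designs — and is configurable.
* **Empty masks** are never evaluated: the rescue operator runs after
  non-selection and again after regularization (under `"selected"` scope a
  non-empty input cannot be emptied by regularization, but the guard is kept
  for uniformity).

## What the synthetic generator emulates — and what it does not

`generate_synthetic()` draws each feature as
`noise_sd * (sqrt(rho) * f_b + sqrt(1 - rho) * eps)` with standard-normal
block factors `f_b`, giving exact within-block correlation `rho` in
expectation and independent blocks; informative features add an
`effect_size`-standard-deviation mean shift for class-1 samples and are
dealt round-robin across blocks. Defaults emulate a Colon-sized study
(62 × 2000, imbalance ratio 1.82, 20 blocks).

One property of the construction matters when choosing `block_rho`: the
class shift itself induces correlation `e²/4 / (1 + e²/4)` between every
pair of informative features (0.5 at effect size 2). If `block_rho` does not
dominate this, the informative features form their own correlation cluster
instead of joining their blocks, concentrating them in one cluster and
changing what the per-cluster caps can retain. The default `block_rho = 0.8`
keeps the planted block structure dominant.

The generator does **not** model heteroscedastic measurement noise, batch
effects, heavy-tailed intensities, or correlated class-conditional
covariance differences. Tests that pass on this fixture therefore
demonstrate the algorithmic properties (recovery, stability, caps,
determinism), not performance claims about any particular real dataset.

## Problem sizes used in the test suite

The packaged checks run scaled-down study conditions chosen to exercise
every code path while keeping the suite quick: recovery fixtures of 500
features × 60 samples with 5 planted informative features at effect 2.0,
searched with 500-evaluation budgets across 10 seeded runs; cluster-count
recovery on 3 planted blocks (ρ = 0.9, 100 samples); and mini-runs of
40–80 evaluations for invariant replays. The full-scale defaults
(6000 evaluations × 30 runs) are what `search_config()` ships with.

## Known limitations

* Binary classification only; no multi-class extension.
* 1-NN is the only fitness classifier (by design — it is maximally
  sensitive to feature quality), so conclusions about subset quality are
  conditional on nearest-neighbor geometry.
* The feature-correlation embedding is `O(D²)` in memory; at `D ≈ 20,000`
  the correlation matrix alone is ~3 GB, so ultra-high-dimensional data may
  need a pre-filter before clustering.
* Under the default `"all"` scope the final subset size is bounded by
  `num_clusters × 5`, and more tightly by the cap schedule at the
  evaluations where proposals were last accepted; datasets needing larger
  signatures than the cluster count allows will be under-selected.
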