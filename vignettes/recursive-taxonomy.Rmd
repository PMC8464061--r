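---
title: "Ensemble recursive K=2 partitioning: model, parameters, and design choices"
author: "k2tax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble recursive K=2 partitioning: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(k2tax)
```

## The problem

Standard hierarchical clustering of expression data selects one global
feature set and one global geometry, yet the structure of interest is often
nested: the genes that separate major lineages are not the genes that
separate closely related subtypes within a lineage. `k2tax` builds a binary
taxonomy over *items* — individual observations, or pre-labeled groups of
observations such as single-cell clusters — by estimating one K = 2
partition at a time, each from features selected *within* the current
branch, so every split is driven by the dominant local contrast rather than
by the global variance structure.

## One partition

At a node holding N items the partition is an ensemble estimate. For each of
`p` perturbations (default 100):

1. **Feature bootstrap.** The features of the node's submatrix are resampled
   with replacement, so each perturbation sees a reweighted feature set.
2. **Variability-based selection.** The top `round(sqrt(F))` features by a
   dispersion statistic — MAD (default), SD, or a one-way between/within
   group F ratio — computed only over the node's observations. The square
   root rule makes the selected fraction shrink with dimension: 3.2% of
   1,000 features, 1.0% of 10,000. Ties rank in feature order. Because row
   statistics are invariant under row duplication, the statistic vector is
   computed once per node and indexed by each bootstrap, which reproduces
   per-perturbation selection exactly at a fraction of the cost.
3. **K = 2 clustering.** Observation mode: hierarchical clustering of the
   Euclidean distance matrix with Ward's method (run as `ward.D2`;
   `average`, `complete`, `single` are selectable), cut at K = 2. Group
   mode: constrained K = 2 k-means in which all observations sharing a
   label are must-linked (see below). Labels are coded ±1 with an arbitrary
   per-perturbation sign.

The p dichotomies are aggregated into the cosine similarity matrix
`Q[i, j] = (X_i · X_j) / p`, the Hamann similarity `(matches −
mismatches)/p` of the two ±1 vectors, equal to the correlation of the
assignment vectors in standardized form (`r = 1 − d²/(2p)`). The aggregate
partition is the K = 2 cut of hierarchical clustering on the distance
`1 − Q`.

### Partition stability

With eigenvalues `λ₁ ≥ … ≥ λ_N` of `Q` and cumulative variance fractions
`v_k = Σ_{l≤k} λ_l / N`, the stability of the partition is

```
PS = max_k (v_k − k/N)
```

the largest excess of explained variance over the null in which items are
linearly independent (`Q = I`, `v_k = k/N`). `PS = 0` when perturbations are
random; `PS = 1 − 1/N` when every perturbation induces the same bipartition
(0.5 at N = 2). `stability_min` can stop recursion on unstable nodes; the
default 0 leaves stopping to `min_items` (3 in observation mode, 2 in group
mode — a two-group node is always a meaningful forced split, while splitting
two observations is rarely informative).

### Branch heights

For a node reached by partitions `1..m` with stabilities `PS₁..PS_m`
(including the node's own — the node *is* the m-th partition) the raw
height is `log(N_m) + Σ log(PS_l)`; a single per-tree constant shifts all
partition-node heights so their minimum is exactly 1. Unstable, deep, or
small partitions therefore hang low. Leaves carry no partition; they are
displayed at half their parent's height, which keeps heights strictly
decreasing on every root-to-leaf path while leaving the partition-node
scale untouched.

## Group mode and the must-link reduction

With complete must-link blocks, the constrained k-means objective
decomposes exactly: assigning all members of group g (size `w_g`, centroid
`c_g`) to a center `μ` costs `w_g·‖c_g − μ‖²` plus a constant. Constrained
k-means over observations is therefore *identical* to weighted k-means over
group centroids with weights equal to group sizes. For the group counts this
mode is built for (G ≤ 12 at a node) the weighted within-cluster
sum-of-squares is minimized exactly by enumerating all `2^(G−1) − 1`
bipartitions; Lloyd iterations from weighted k-means++ starts — retained
for larger G — can converge to a local optimum from every restart on small
weighted configurations, and an exact minimizer is both cheaper and
deterministic here.

## Degenerate and edge cases

* A perturbation in which all items coincide in the selected-feature space
  cannot be split; the bootstrap is redrawn up to 10 times, then the
  perturbation is dropped. A node dropping more than half its perturbations
  becomes a leaf with stop reason `degenerate`.
* Eigenvalues within `1e-10` of zero are clipped before cumulative sums;
  matrices asymmetric beyond `1e-8` are rejected.
* Selection ties break by feature order; the aggregate split labels the side
  containing the first item `+1` (the cosine matrix is invariant to
  per-perturbation sign flips, so this is presentation only).
* Seeds: one master seed; per-node and per-perturbation seeds derive from an
  integer hash of the node path and perturbation counter (mod 2³¹−1), so
  results do not depend on traversal order and two runs with the same
  configuration serialize byte-identically.

## Subgroup annotation

Each internal node compares its two child subgroups:

* **Differential expression** uses a moderated t: per-feature pooled
  variances `s²_g` (df `d`) are shrunk toward a prior fitted by moments on
  `log s²` — `e_g = log s²_g − ψ(d/2) + log(d/2)`, prior df from the inverse
  trigamma of `var(e) − ψ′(d/2)`, prior variance from `exp(mean(e) +
  ψ(d₀/2) − log(d₀/2))` — giving the posterior `(d₀s₀² + ds²)/(d₀ + d)` and
  `d + d₀` error df. A side with fewer than two observations falls back to
  the ordinary t with a warning. The implementation is checked against the
  independent `limma` routines in the test suite.
* **Signatures** keep features with FDR `< 1e-10`, own-side mean `> 0.5`
  (log2 scale) and positive effect, capped at 50 by q-value then |t|. The
  expression threshold applies to the signature's own subgroup.
* **Over-representation** of a signature in user gene sets is the one-sided
  upper-tail hypergeometric p, BH-corrected across sets.
* **Projection scores** summarize a gene set per observation as the mean
  in-set rank minus mean out-of-set rank, scaled by its maximum `F/2` to
  `[−1, 1]`. Scores depend only on within-observation ranks, hence are
  invariant to any monotone transform of one observation's values; sets
  with fewer than two present features are flagged missing. This rank
  statistic is deliberately simple — exactly testable and
  transform-invariant — rather than a kernel-smoothed ECDF statistic.
* **Phenotype tests**: Student's t (equal variances) or Wilcoxon rank-sum
  for continuous variables, Fisher's exact test for categorical ones
  (seeded simulated p with 10⁵ draws when the exact network algorithm
  exceeds its workspace); constant variables are flagged with p = 1; BH
  across variables per partition.

## The simulator

`simulate_hierarchy()` emulates the structure the method is designed to
recover: a random *balanced* binary tree over terminal clusters (each split
as even as possible, membership random), signal features allocated to
internal branches proportionally to the number of terminal clusters below
them (at least one each), and each branch's features separating that
branch's two sides by exactly `effect_size` (±`effect_size`/2 per side,
sign per feature), plus i.i.d. Gaussian noise. Defaults: 300 observations,
10,000 features, 4 terminal clusters, signal fraction 0.1, noise SD 1.0,
effect size 1.0.

Two aspects of this design deserve emphasis. If tree shapes are drawn
uniformly (mostly caterpillars) and branches receive equal one-sided
shifts, the noiseless between-cluster distances tie exactly and the
hierarchy is not identifiable by any distance-based method — recovery then
fails for reasons unrelated to the algorithm. The balanced shape and
subtree-proportional allocation make the generating hierarchy the unique
nested structure consistent with the data, which is the property the
recovery benchmarks are meant to probe. What the simulator does **not**
emulate: count noise and mean–variance coupling, library-size and batch
effects, correlated gene modules, unbalanced cluster sizes, or label noise
in the group assignment. Passing recovery benchmarks on this generator
shows the partitioning machinery works where nested structure exists; it
does not certify performance on real single-cell data.

## Evaluation metrics

* **Baker's gamma** between two trees: for every leaf pair, the number of
  partitions separating the root from the pair's lowest common ancestor;
  the statistic is the Spearman rank correlation of the two pairwise-depth
  vectors (1 = identical structure; invariant to child swaps and leaf
  order). LCA partition depth, not cophenetic height, so trees with
  different height conventions compare cleanly.
* **Conditional entropy** of phenotype labels under a K-cluster tree cut:
  `Σ_c (n_c/N) H(labels | c)` in bits; lower is purer. Cuts open nodes in
  decreasing height order (ties by node id), so entropy is non-increasing
  in K.
* **Benchmark**: group-mode runs against Ward's linkage on per-group mean
  profiles (all features), scored by Baker's gamma against the generating
  tree, with a paired two-sided Wilcoxon signed-rank test per grid cell and
  BH FDR across cells.

## Problem sizes in the shipped checks

The packaged tests exercise the simulation study at 200 observations ×
2,000 features with 4 and 8 terminal clusters, noise SD 0.5–2.0, 5
replicates per cell and 100 perturbations per partition, plus a 10-seed
recovery check at noise SD 1.0; unit and property tests run at a few dozen
observations and a few hundred features. These sizes were chosen so the
whole suite runs on a laptop in minutes while still spanning the noise
regimes of interest. At this reduced scale the Ward baseline — which
averages every feature over all of a group's observations — is a very
strong competitor in the highest-noise cells, where sqrt-selection over
2,000 features at 200 observations can no longer distinguish signal from
noise; the ensemble method's advantage re-emerges as observation and
feature counts grow.

## Known limitations

* Observation-mode trees over n observations cost roughly `p ×
  O(n² · sqrt(F))` per node; thousands of observations call for group mode.
* The stability score compares against a linear-independence null; strongly
  unbalanced splits with tiny sides can score high on few informative
  perturbations.
* Heights are a display heuristic derived from stabilities, not a distance
  scale; compare trees with Baker's gamma, not heights.
* The moderated t assumes roughly normal, homoskedastic log-scale
  expression within sides; counts should be transformed upstream.
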