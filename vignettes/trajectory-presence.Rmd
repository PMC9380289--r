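---
title: "Testing for the presence of a trajectory: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing for the presence of a trajectory: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajpresence)
```

## The model

Developmental processes leave a geometric signature in dimension-reduced
single-cell data: cells ordered along a lineage form a connected, mostly
one-dimensional (possibly branching) structure — a trajectory. The test
implemented here quantifies the evidence for such a structure without
attempting to reconstruct it.

The observable is the shape of the Euclidean minimum spanning tree (MST)
built on k-means cluster centers. Clustering first is essential: the MST
on raw cells is dominated by local density fluctuations, whereas the k
centers summarize the cloud's mesoscale geometry. Three statistics
characterize where the tree sits on the path-to-star spectrum:

* **D1**, the number of degree-one (leaf) nodes. Minimal, 2, on a path
  graph; maximal, k − 1, on a star.
* **D2**, the number of degree-two nodes. Maximal, k − 2, on a path;
  0 on a star with at least four nodes (on three nodes path and star
  coincide, so the hub of the 3-star still has degree two).
* **Lmax**, the number of edges in a longest simple path (the
  unweighted tree diameter). Maximal, k − 1, on a path; 2 on a star.

All three are extremized simultaneously exactly on the path graph, the
signature of a clean linear trajectory, which is why the test uses the
lower tail for D1 and the upper tail for D2 and Lmax.

## The null and the p-value

The null hypothesis is "no trajectory", operationalized as "no
dependence between features": every feature column is independently
shuffled across cells. This preserves each marginal exactly — the
permuted cloud occupies the same bounding box with the same per-axis
spread — while destroying all inter-feature structure. Each of the B
replicates re-runs the entire pipeline (clustering included) on a
permuted matrix; all three statistics are read off the same replicate
tree, which makes the three nulls consistent and costs one clustering
per replicate instead of three.

P-values use the add-one empirical formula, lower tail
p = (1 + #{s ≤ obs}) / (1 + B), ties counting as extreme. This keeps
p strictly positive and the test valid (never anti-conservative), at
the price of conservatism when the discrete statistic takes few values.
The test suite checks both properties on structureless Gaussian data:
the p-value distribution is never stochastically smaller than uniform
(one-sided Kolmogorov–Smirnov), and rejection rates at the 5% level
stay at or below nominal. A two-sided uniformity check is not
meaningful here: an integer statistic at moderate k supports only a
handful of p-values, so the distance to a *continuous* uniform is
bounded below by the largest point mass no matter how valid the test
is.

## The cluster sweep and the median

A single k is uninformative at the extremes: with very few clusters any
MST is close to a path, with very many the centers tile the noise and
any MST is branched. The default sweep 5 ≤ k ≤ 35 (31 values) brackets
the informative mesoscale; the median of the per-k p-values is the
reported summary. Two caveats are inherited by design: the median is a
summary, not a calibrated p-value (no multiplicity correction across k
or across statistics is applied), and evidence for a trajectory of n
points concentrates at k where the per-cluster occupancy and the
cluster spacing match the structure's scale — for small n a narrower,
higher-k window is often more informative than the full default range.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `kMin`, `kMax` | 5, 35 | cluster sweep bounds; `kMin` ≥ 3 (no tree shape below 3 nodes), `kMax` ≤ n − 1 |
| `nPermutations` | 1000 | permutation count B; resolves p down to ~1/(B+1); ≥ 19 so p = 0.05 is attainable |
| `seed` | 0 | master seed; every draw in the pipeline derives from it |
| `pcaDims` | auto | PCs kept before testing: 2 when p > 10, none otherwise; always overridable |
| `statistics` | D1, D2, Lmax | subset to compute |
| `nRestarts` (k-means) | 10 | k-means++ restarts, best within-cluster SS kept |

PCA centers columns but does **not** scale them to unit variance:
the test's geometry is Euclidean distance in the embedding, and
rescaling features would change it. Component signs are fixed (largest
absolute loading positive) for reproducibility.

## Determinism and numerical choices

Reports are bit-reproducible from `(X, config)`. The seed stream for
every (k, replicate, purpose) cell is derived by an integer mixing
function of the master seed, so permutation b at k = 12 draws the same
shuffle whether or not other cells were computed. Design details that
are load-bearing for determinism:

* **k-means** is Lloyd's algorithm with k-means++ seeding, 10 restarts,
  assignment ties broken towards the lowest center index, and
  convergence on assignment stability (cap 300 iterations). Seeding
  operates on a canonical lexicographic row ordering, so results do not
  depend on the order cells are stored in. A cluster that empties is
  re-seeded at the point farthest from its assigned center, so exactly
  k non-empty clusters (hence k MST nodes) are guaranteed whenever the
  data contain k distinct rows; fewer distinct rows raise a
  degenerate-input error.
* **Prim's MST** breaks equal-weight ties towards the lexicographically
  smallest (min id, max id) node pair. Equal weights occur for
  duplicated centers and grid-like layouts, and tie resolution can
  change D1/D2/Lmax, so the rule is part of the contract. Duplicate
  centers are legal (zero-weight edges).
* **Lmax** counts edges, never weight sums, and is computed by the
  two-sweep BFS method, cross-checked in the test suite against
  all-pairs distances on random Prüfer trees.
* The observed statistic at each k uses the same k-means seed stream as
  the permutation replicates (replicate index 0).

Where the choice was genuinely open, the package picks one and records
it here: the permutation is applied to the matrix that enters
clustering (post-PCA); `permuteBeforePCA = TRUE` shuffles the raw
matrix and re-runs PCA per replicate instead, which is slower and in
practice nearly indistinguishable — after column shuffling the PCA
rotation is close to an orthogonal relabeling, which Euclidean MST
geometry ignores. Even-length sweeps use the midpoint-average median.
D1 is stored unsigned, with trajectory-direction encoded in the tail of
its test rather than a sign flip of the statistic.

## The synthetic generators

`simulateTrajectory()` produces 2-D (optionally padded to higher
`dims`) point clouds from geometric backbones: a gentle sine curve
(`linear`), a root splitting into three branches (`multifurcating`),
two branches merging into a shared segment and re-splitting
(`converging_diverging`), an open 270° arc plus a disjoint segment
(`disconnected_looping`), and a uniform hypercube (`none`). Points are
allocated to branches proportionally to arc length, positioned
uniformly along them, and blurred with isotropic Gaussian noise.

The per-kind noise presets (0.02 for every trajectory kind, on
backbones of extent ~1) are a fixed calibration: small enough that the
trajectory remains detectable across the default sweep, large enough
that the cloud is visibly noisy. The calibration target — linear
trajectories at median p < 0.05 and structureless data at median
p > 0.5 with B = 99 — is exercised by the test suite's power-ordering
check.

The generators emulate the *geometry* consumed by the test, not
single-cell measurement: there is no count noise, library-size
variation, dropout, or cluster-granular population structure
(`liftToExpression()` adds only a linear map to a wide noisy matrix for
I/O tests). Passing tests therefore demonstrate the statistical
machinery on clean geometric ground truth; on real data, embedding
quality and preprocessing choices (normalization, feature selection,
batch correction — all deliberately out of scope) can dominate the
outcome, as the contrast between noisy and clean real datasets in the
literature shows.

## Problem sizes used by the test suite

The shipped tests run the full pipeline at reduced scale, chosen to
exercise every contract while keeping the default suite fast: the
report-shape check uses 300 points with B = 100 over the default
5..35 sweep; null calibration uses 200 Gaussian datasets of 200 points
at k = 10, B = 99; the power-ordering check uses 50 paired replicates
of 200 points over k in 10..22 at B = 99 (the window where mesoscale
structure dominates for that n). Oracle equivalence uses 100 random
12-point clouds (Prim vs Kruskal) and 200 random Prüfer trees
(two-sweep vs all-pairs).

## Known limitations

* k-means is a pragmatic partitioner, not an ideal one; regions of a
  curved trajectory are not guaranteed to be tiled in order, and
  alternative partitioners are a natural extension point.
* The median-p summary has no analytical null; per-k p-values are
  exchangeable-valid individually but dependent across k.
* Discrete statistics make the per-k tests conservative at small k and
  small B.
* The test decides *existence* only: it assigns no pseudotime, no
  branches, and no uncertainty on either.
* Disconnected structures are flagged as strongly as connected ones
  (each component contributes linear segments); "trajectory present"
  must not be read as "single connected lineage".
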