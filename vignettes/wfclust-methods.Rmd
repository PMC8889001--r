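---
title: "Multi-scale Weber–Fechner clustering: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale Weber–Fechner clustering: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wfclust)
```

## The model

Clustering here is a multi-scale observation process.  A pairwise
similarity `sim(x, y)` is fixed by the coding (below), and an observation
scale `s` is identified with a similarity threshold `sim_min^s`: at scale
`s` two points are "perceived together" iff `sim(x, y) >= sim_min^s`, and a
cluster is a connected component of the graph linking all such pairs.  The
threshold starts at the global minimum pairwise similarity `sim_min` — so
scale 1 joins everything into one component — and grows by a constant
fraction per scale,

$$\mathrm{sim}_{min}^{s+1} = (1+\lambda)\,\mathrm{sim}_{min}^{s},$$

the Weber–Fechner law with the threshold as the background stimulus and
`λ · sim_min^s` as the just-noticeable difference.  Scales beyond the
maximum pairwise similarity `sim_max` are pointless (every point becomes
isolated), which fixes the number of scales in closed form:

$$s_{end} = \left\lfloor \log_{1+\lambda}
  \frac{\mathrm{sim}_{max}}{\mathrm{sim}_{min}} \right\rfloor ,$$

clamped to at least 1 when the bounds are so tight that the floor is 0.
Both bounds are estimated from the data (`estimateSimilarityBounds`), so λ
is the only free parameter: smaller λ gives more, finer-stepped scales.

Because the per-scale edge sets shrink as `s` grows, the partitions are
nested (exactly so in DM mode; see below), and the result is a cluster tree
(`buildHierarchy`): the parent of a scale-`s` cluster is the scale-`(s-1)`
cluster containing its members.

## The two codings

**SD (grid) coding** serves low-dimensional data.  Similarity is
`1/δ(x, y)` with `δ` the Chebyshev (L∞) distance, so the threshold
`sim_min^s` corresponds to a distance threshold `δ^s = 1/sim_min^s`.  Each
point is assigned to the half-open grid cell of side `δ^s` containing it
(anchored at the per-dimension data minima; the anchor and the boundary
convention are our choice — any fixed convention works) and points in the
same or Chebyshev-adjacent cells are linked.  Grouping by cell key and
probing the `3^d − 1` neighbour keys costs `O(n·3^d)`, linear in `n` for
fixed `d`; we refuse SD beyond `d = 12`, where `3^d` neighbour enumeration
stops being sensible, and route to DM instead (`selectCoding`).  Grid
adjacency *is* the similarity criterion — pairs with `δ(x,y) < δ^s` are
always linked, linked pairs always satisfy `δ(x,y) < 2δ^s`, and no
post-verification of the true distance is performed.  A consequence worth
knowing: for λ < 1 the grids of successive scales do not tile each other,
so SD partitions are not strictly nested; `buildHierarchy` assigns the
majority parent and counts these events (`repairedParents`), rather than
altering the per-scale partitions.  The integer cell coordinates are the
canonical code; `sdSpliceCodes` optionally exports the interleaved-bit
(splicing/decomposable) representation, whose prefixes recover coarser
scales when λ = 1.

**DM (dimension-marker) coding** serves high-dimensional data.  Each point
becomes the set of its informative dimensions and similarity is the Jaccard
index.  Three marking rules are provided because "informative" depends on
the data type: `nonzero` (sparse counts, e.g. detected genes per cell — the
default for sparse input), `top_m` (largest-magnitude coordinates) and
`binned` (equal-width quantisation of each dimension, default 8 bins per
dimension — the default for dense input, where Jaccard then measures the
fraction of dimensions in identical bins).  Thresholded pair retrieval uses
`k = 256` MinHash signatures with LSH banding; bands `(b, r)` are chosen
per threshold `t` so the S-curve midpoint `(1/b)^{1/r}` does not exceed
`t/2` (the factor 2 is a recall margin), and every candidate is verified
with the exact Jaccard similarity, so false positives are impossible.  At
thresholds so low that no banding of 256 rows is sensitive enough — or
where the best choice degenerates to single-row bands — candidates come
instead from the shared-marker inverted index (a sparse posting-list
self-join), which is exact for any positive threshold.  In `runWFC`,
candidates from all scheduled thresholds are pooled and verified once, so
the per-scale edge sets are nested by construction and DM hierarchies never
need parent repair; the test suite asserts this instead of repairing.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `lambda` | 1 | Weber fraction; step between scales. Smaller λ ⇒ more scales, finer hierarchy, more time. |
| `policy` | `weber_fechner` | threshold update; `hyper_exponential` (`(1+λ)^{(s-1)^2}`) reaches `sim_max` in ~`sqrt(L)` scales but skips structure; `linear` is a baseline. |
| `k` | 256 | MinHash signature length; recall of banding grows with k. |
| `bandSafety` | 0.5 | banding tuned at `bandSafety·t`; lower ⇒ fewer false negatives, more candidates to verify. |
| `bruteCutoff` | 512 | below this n, DM uses exact all-pairs Jaccard. |
| `sampleSize` | 2000 | above this n, similarity bounds are estimated from a seeded sample (nearest neighbours within the full data for SD). |

All randomness (bound sampling, the MinHash hash family) is governed by the
single `seed` argument, and the caller's RNG state is left untouched.

## Numerical choices and degenerate inputs

`s_end` is computed in log space with a `1e-9` relative guard before the
floor, so a ratio of exactly `2^25` at λ = 1 yields 25 and not 24.
Thresholds are anchored at `sim_min^1 = sim_min` for every policy (the
grossest scale must link the most dissimilar pair).  Threshold comparisons
carry a `1e-12` absolute slack.  Identical-point datasets have no nonzero
distance and are rejected ("zero similarity range"); duplicate points among
distinct ones are linked at every scale.  Empty marker sets are rejected at
encoding time with the offending rows listed.  The DM `sim_min` is clamped
below by `1/(2D)` — for binary Jaccard any nonzero similarity already
exceeds this, so the clamp only guards hypothetical degenerate inputs.
Cluster labels are canonicalised to the smallest member point index, making
partitions invariant to point order; metric tie-breaks (majority class,
best cluster per class) go to the smaller index.

## The synthetic generators

`makeMixture` emulates a benchmark of 3000 two-dimensional points with
planted hierarchical overlap: a uniform box (550 points over 20×20)
containing a sine curve (400) and a dense Gaussian (600, σ = 0.7); a line
segment (250) passing ~2.5σ from a second Gaussian (600); and a free third
Gaussian (600).  The densities were chosen once for contrast — Gaussian
cores ≈ 200 points per unit², box ≈ 1.4 — so that bridges through sparse
components break at coarser scales than the Gaussian cores fragment, and
then frozen; tests and the acceptance script treat the spec as fixed study
conditions.  What passing shows: WFC separates density-contrasted,
partially overlapping structures across scales on clean 2-d data.  What it
does not show: performance on real scRNA-seq noise structure, batch
effects, or billion-record inputs — no desk-scale fixture can.

`makePlantedBinary` plants Jaccard structure for the DM path: 5 clusters ×
100 points, code length 500, disjoint 30-marker cores, core markers dropped
with probability 0.1, background dimensions marked at rate 0.01.  The
within/between Jaccard expectations follow in closed form from the flip
model (`expectedPlantedJaccard`, ratio-of-expectations approximation) and
the generator is tested against them.

## Problem sizes used in tests

The suite exercises: SD-vs-brute-force oracle equality on 20+ random
datasets (n ≤ 400, d ≤ 3); LSH recall/false-positive audits on 10 planted
datasets of n = 500 at every scheduled threshold; the full 3000-point
mixture at λ ∈ {0.5, 1}; and 100 random contingency tables against
explicit-loop purity/F1 oracles.  These sizes were chosen so each property
is checked at a scale where its exact oracle is computable.

## Known limitations

* SD hierarchies for λ < 1 may contain majority-repaired parents (reported,
  never silent); DM hierarchies are exactly nested.
* The `linear` policy's scale count grows like `sim_max/sim_min` and is
  refused above 10^5 scales.
* DM similarity is binary Jaccard; weighted (multi-set) Jaccard for count
  data is out of scope.
* Bounds estimated by sampling (n > `sampleSize`) can shift the schedule
  slightly between sample sizes; the seed fixes them exactly.
* No soft assignments, no streaming, no distributed execution.
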