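---
title: "Methods: partially synthetic generation and validation in a 2D embedding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: partially synthetic generation and validation in a 2D embedding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psdg)
```

## The problem

Clinical tables assembled at different centers rarely share a full feature
set: one registry records patient age, another does not; one has the
diagnostic label, another lacks it. `psdg` addresses the situation where a
*complete reference table* `D_r` exists somewhere and an *incomplete
table* `D_i` — same schema minus one or more columns — needs those columns
filled, either with a single best value per cell (imputation) or with
every plausible value per row (partially synthetic augmentation). A
design constraint throughout is that the two tables may live at different
institutions and raw rows must never travel.

## The procedure and its assumptions

The method screens candidates rather than sampling from a fitted model.
For one missing feature `x`:

1. The admissible candidate set of `x` is derived from the reference:
   integer features enumerate the closed observed range (so an observed
   span 35–92 yields 58 candidates even if interior ages are unobserved),
   ordinal/categorical/binary features enumerate their observed admissible
   levels, and continuous features are quantized into `M` uniform bins
   whose midpoints form the grid.
2. Every incomplete row is expanded over the grid: `|D_g| = N_i × M`,
   exactly. Expansion order is deterministic (source row, then ascending
   candidate value), which makes whole runs byte-reproducible.
3. A 2D Euclidean embedding is trained on the standard-scaled reference
   features and both reference and candidates are projected through it.
4. Each candidate's value is compared with the mean of `x` over its `k`
   nearest reference points in the embedding; the absolute disparity is
   banded into the reliability score `r_c ∈ {1, 0.9, …, 0.5, 0}` in
   multiples of the band width `ε`. Candidates with `r_c ≥ r_min` are
   validated.
5. If the label is also missing, per-class cluster areas (centroid plus
   density-validated radius) in the reference embedding assign it;
   points outside every area are dropped.

The implicit statistical assumption is that `x` varies *smoothly across
the embedding*: the k-NN mean of `x` over embedding neighbors is only an
informative anchor if rows that are close in the embedded feature space
have similar `x`. Separable class clusters are likewise assumed for
step 5. Data without those properties will validate few candidates or
assign few labels — the method degrades by emptiness, not by fabricating
confident nonsense, which is the behavior one wants from a screening
filter.

## The embedding backend

The pipeline requires only a contract from its embedding: a 2D Euclidean
map trained on the reference that supports a deterministic out-of-sample
transform, so `D_g` can be projected through the *same* function as
`D_r`. The package treats the backend as pluggable behind that contract
and ships two:

* **`pca`** (default) — a seeded principal-component projection onto the
  first two components with a fixed sign convention. For the 3–6 column
  tables this method targets, two components retain most of the variance,
  the out-of-sample transform is exact and pure, refits are
  bit-identical, and the serialized state is tiny (a 2-column rotation).
  Those properties make the determinism and two-party guarantees easy to
  state and test.
* **`laplacian`** — a nonlinear neighbor-graph embedding: a fuzzy k-NN
  graph with smoothed local connectivity (per-point bandwidths solved so
  each point's effective neighborhood mass is `log2(k)`), symmetrized by
  the probabilistic t-conorm, embedded by the trailing eigenvectors of
  the symmetric normalized graph Laplacian; new points are placed at the
  membership-weighted mean of their nearest training points'
  coordinates. It illustrates the backend contract with a genuinely
  nonlinear map and is exercised by the same determinism, continuity and
  serialization tests as the default.

Two further choices deserve a note. The **label is excluded from
embedding training**: generated rows in the label-missing cases have no
label yet must be projected through the same map, so the map must be
label-free; on the shipped fixtures class clusters still separate from
features alone, which is exactly the regime the method assumes. And a
**seed is mandatory** — there is no unseeded mode, because projection
reproducibility is a methodological requirement, not a convenience.

## Tunable parameters

| Parameter | Default | Units / scale | Role |
|---|---|---|---|
| `k` | 10 | reference rows | neighborhood size for the `x̄_{i,k}` mean; also the k-NN baseline's `k`, keeping the comparison symmetric |
| `epsilon` | grid default | original feature units | disparity band width; 1 for integer/ordinal kinds (one year for an age-like feature), half the minimum level gap for categorical/binary, the bin width for quantized features |
| `r_min` | 1 | score | validation threshold; validated sets are nested in it |
| `density_threshold` | 6 | points per unit embedding area | cluster-area criterion; fitted radii are non-increasing in it |
| `r_start`, `r_step`, `r_max` | 0.05, 0.05, max member distance + one step | embedding units | radius search grid |
| `n_neighbors` | 15 | rows | embedding graph size (graph backend) |
| `n_levels` | 10 | bins | quantization resolution for continuous grids |

`epsilon` always lives on the **original feature scale** even though the
embedding consumes normalized features: disparity is a statement about
the feature's own units ("within one year"), not about normalized space.
For binary features under a 0/1 encoding note that `ε = 1` would make
every candidate score 1; the grid default of half the level gap (0.5) is
the discriminating choice, and passing `epsilon = 1` explicitly
reproduces the permissive convention where wanted.

## Density, radii, and ties

"Density" for cluster validation is defined per unit area,
`count / (π r²)`, so a *higher* threshold yields a *smaller* validated
area — the direction in which a threshold sweep behaves like a
strictness dial. A raw-count reading (monotonically increasing in `r`,
hence behaving oppositely) is available via `density = "count"` for
comparison. The radius is searched on an explicit grid and defined as
the largest grid radius still meeting the threshold, which makes the
"until density falls below" rule deterministic and order-invariant.

Tie handling is specified everywhere rather than left to sort
internals: k-NN ties at the k-th distance break by ascending reference
id (distances compared exactly as the stored floats, via a
locale-independent radix order); a point inside several cluster areas
goes to the nearest centroid, with exact distance ties to the
lexicographically smallest label; the imputation selection rule is
highest `r_c`, then smallest disparity, then smallest candidate value.
Score bands are closed on the right (`f = 2ε` scores 0.9), and any
disparity beyond `6ε` scores 0 and can never validate.

## Numerical and serialization choices

Standard scaling uses the population (divide-by-N) standard deviation,
fixed and documented; constant columns are rejected at fit time rather
than silently producing infinities. All CSV and JSON artifacts render
doubles with 17 significant digits, which is sufficient for IEEE-754
round-trips: save/load of an embedding model reproduces projections
bit-identically, the two two-party scoring routes produce byte-identical
files, and two executions of any pipeline under the same configuration
and seed produce byte-identical outputs. The missing marker is `NA`
internally and the empty string in CSV.

Mixed missingness is deliberately rejected by the core data model
(a feature must be missing in every row or none): rows with differing
patterns belong to `run_imputation()`, which partitions by pattern first
and runs the uniform pipeline per subset. Iterative full synthesis adds
each newly generated feature to the reference feature set and refits the
embedding per iteration; the default generation order is descending
absolute correlation with the label on the reference.

## The fixture generator

`fixture_spec()` generates the structure the method assumes and nothing
more: classes are Gaussian components in a 2D latent space (means
`class_separation` within-class standard deviations apart), observed
features are full-rank affine images of the latent position plus noise,
and the hidden feature is affine in the latent position with its own
noise, rounded/clipped to its declared kind and range. The default spec —
1500 rows, three features, two classes, an integer age-like hidden
feature on 35–92 — makes a five-group rotation produce groups of exactly
300 rows. Real registries differ in ways the generator does not emulate:
heavy-tailed and multimodal marginals, label noise, feature
interactions beyond affine structure, and missingness that is
informative rather than uniform. Green tests on these fixtures therefore
demonstrate the *mechanics* (exact arithmetic, nesting, determinism,
oracle agreement, baseline ordering in the favorable regime), not
performance on any particular clinical dataset.

Evaluation in `rotation_validate()` holds each of `n` equal random
groups out as the reference in turn, blanks the evaluation feature in
the remainder, and counts a validated candidate as *correctly imputed*
when it equals the held-out truth after snapping the truth onto the
candidate grid (exact match for integer grids, bin-midpoint match for
quantized ones). Counts are averaged across rotations. The mean and
k-NN baselines run on the identical splits; the k-NN baseline measures
distance in the normalized known-feature space, mirroring the
normalization applied before embedding.

## Problem sizes used by the test suite

The suite runs the expansion arithmetic at full registry scale
(24,728 × 58 candidates — expansion is cheap), the oracle-equivalence
checks at 200 reference points × 50 queries, the monotonicity suites on
1500-row fixtures across three seeds, the baseline-dominance rotation at
500 rows × 5 groups × 3 seeds, and the protocol-shape check at
1500 rows × 5 groups. These sizes exercise every documented contract
while keeping a full run in the low minutes on one CPU; all of them are
the package's own choices and can be scaled up freely in user code.

## Known limitations

* Performance depends on a reference that actually covers the incomplete
  population; a biased or narrow reference silently narrows what can
  validate.
* Only one feature is expanded at a time; joint candidate grids over two
  simultaneously missing features are out of scope (iterative generation
  covers the sequential case).
* Validated augmentation rows are *plausible*, not draws from a coherent
  joint distribution; downstream uses that need calibrated uncertainty
  should treat `r_c` as a screening band, not a probability.
* Cluster areas are circles around centroids; elongated or nested class
  geometries will under-assign labels.
* The multiple-imputation hook returns per-cell top-n candidates only;
  pooling rules are intentionally left to the analyst.
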