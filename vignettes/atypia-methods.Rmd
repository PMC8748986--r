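---
title: "Methods: 3D nuclear morphometry and atypia scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D nuclear morphometry and atypia scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atypia3d)
```

`atypia3d` quantifies keratinocyte nuclear atypia from 3D instance
segmentations of epidermis. This vignette is the package's account of
its models, its numerical choices, and what its synthetic benchmark
does and does not demonstrate.

## The shape model

A segmented nucleus is star-convex: a center $c$ and $n$ ray lengths
$r_1,\dots,r_n$ along a fixed set of unit directions ($n = 96$ by
default, matching the representation used by 3D star-convex detectors).
The directions are placed on a Fibonacci sphere — deterministic,
quasi-uniform, and reproducible across platforms — and triangulated by
the convex hull of the direction points, giving $2n-4$ spherical
triangles ($188$ at $n=96$) whose solid angles tile $4\pi$.

Volume is the sum of signed tetrahedra $(c, p_i, p_j, p_k)$ over the
ray-endpoint mesh and area the sum of its triangle areas. Compactness,
$(36\pi V^2)^{1/3}/A$, compares the area of the volume-equivalent
sphere to the actual area: 1 for a sphere (the isoperimetric equality
case), lower for flat or irregular nuclei. Because the mesh is an
inscribed polyhedron, $V$ and $A$ sit *below* their smooth-surface
limits by a discretization deficit that scales like $1/n$: at 96 rays a
sphere's mesh volume is 6.1% and its area 3.2% below the analytic
values (we verified the same numbers with an independent qhull
implementation). Compactness is far less biased (0.991 for a sphere at
96 rays) because the volume and area deficits largely cancel. Users
comparing absolute volumes across software should expect this
representation-level offset; ratios and rankings are unaffected. For
ingestion of voxel label volumes, where the ray count is free, 256–384
rays bring the deficit under 2%.

Directional boundary queries (`radial_extent()`) interpolate the three
ray lengths of the spherical triangle containing the query direction
with normalized barycentric weights. This choice is continuous in the
direction, exact at the stored directions, and exactly $r$ for a
constant-ray shape; a planar-mesh ray cast would instead dip below $r$
between nodes, which we considered and rejected because border
distances would then acquire the mesh deficit twice.

## The neighbor graph

Cells fill the epidermis, so adjacency is modeled by the Delaunay
triangulation of nucleus centers (the dual of the Voronoi partition),
keeping edges with center distance strictly below 50 µm — beyond that,
two keratinocyte nuclei cannot plausibly be adjacent cells. The
triangulation is computed by an incremental Bowyer–Watson algorithm
with a symbolic vertex at infinity (compiled code under `src/`; no R
package on CRAN provides 3D Delaunay without qhull). Correctness is
tested against a brute-force empty-circumsphere oracle and against the
Poisson–Delaunay mean-degree law $48\pi^2/35 + 2 \approx 15.54$.

Numerical choices: a deterministic seeded jitter of amplitude
$10^{-4}$ µm is applied to coordinates *only* for the triangulation
(distances are measured on the raw coordinates), which resolves
collinear/coplanar/cospherical degeneracies reproducibly; with fewer
than 5 nuclei, or if the configuration is degenerate beyond jitter, the
complete graph filtered by the cutoff is used. Pruning happens before
feature computation: features only ever see kept edges. No correction
is applied at the field-of-view boundary (matching how such pipelines
are run in practice); nodes on the convex hull are flagged so users can
run their own sensitivity checks.

The border-to-border distance of an edge is
$\max(0,\; d - \rho_i(u) - \rho_j(-u))$ where $\rho$ are the radial
extents along the center line — the cheapest definition consistent with
"gap between the two nuclear surfaces", clamped at 0 for overlapping
surfaces. A minimal mesh-to-mesh distance would be tighter for strongly
non-convex pairs but costs orders of magnitude more and changes
nothing for near-convex nuclei.

## Features and image metrics

Thirteen features per nucleus: volume, compactness, their ratio, the
neighbor count, mean center and border distances, the mean per-edge
border/center ratio (bounded in $[0,1]$; low values mean the nucleus
fills its cell), and the mean, population standard deviation and
self-to-neighborhood ratios of neighbor volumes and compactness.
Population (divide-by-$n$) standard deviations keep the value defined
at a single neighbor (0 rather than NA). Isolated nuclei (degree 0)
get missing neighbor features; they are excluded from
machine-learning training and scoring (their count is logged) and the
rule's neighborhood criterion is treated as unmet — we prefer exclusion
over inventing an imputation scheme. Image metrics are cell density
(count over the en-face x–y field of view, the imaged skin surface) and
means/standard deviations of the cell features, neighbor-distance means
taken over cells with at least one neighbor.

## Atypia scores

All four scorers emit per-cell scores in $[0,1]$; the image score is
the unweighted mean over its scored cells, with no thresholding —
averaging probabilities preserves graded severity information that hard
labels would discard (a binarized variant can be had by thresholding
`cell_scores` downstream).

- **Rule**: atypical if at least 2 of {volume > 280 µm³, compactness
  < 0.592, neighborhood mean volume > 156 µm³}. The reference values
  are top-decile calibrations on a large clinical cohort; since they
  are cohort-derived, the default mode recalibrates each threshold as
  the 10% tail quantile (type-7, linear interpolation) of the training
  folds, and the fixed reference values are available as
  `thresholds = "fixed"`.
- **Isolation forest**: 100 trees, subsample 256, depth cap
  $\lceil\log_2 256\rceil$, anomaly score $2^{-\bar h/c(\psi)}$;
  implemented in the package (no R implementation was available) and
  checked on analytic cases. Raw scores are oriented so higher = more
  anomalous and min–max mapped to $[0,1]$ using *training-fold*
  statistics, clamped on the held-out fold.
- **Logistic regression** on z-normalized features (training-fold mean
  and SD), unpenalized maximum likelihood (`stats::glm`); the effective
  regularization ("none") is recorded in the model object since other
  implementations silently add weak L2.
- **Gradient-boosted trees** (`xgboost`): 200 rounds, depth 5, row
  subsample 0.5, single-threaded with a fixed seed for bit
  reproducibility. No tuning anywhere — weak labels are noisy by
  construction and tuning against them would overfit label noise.

Weak supervision propagates the image diagnosis to every cell: all
nuclei of pathological images (subclinical AK, AK, Bowen) are labeled
atypical, all nuclei of healthy images healthy. Cross-validation is
stratified at the *image* level (5 folds; all cells of an image share a
fold; each fold's healthy proportion within one image of the global
one), so every cell is scored by a model that never saw its image. One
master seed derives the fold, forest and boosting seeds.

## Evaluation

Image scores against diagnosis labels: rank-based (Mann–Whitney,
midrank ties) AUC with pathological as the positive class, on three
subsets — healthy vs all pathological, vs AK + Bowen, vs subclinical AK
— with method-to-method Pearson correlations restricted to the same
subset. Image metrics are compared healthy vs pathological with the
pooled-variance Student t-test (two-sided; positive = larger in
pathological skin; Welch available via `var_equal = FALSE`). The reader
consensus normalizes each reader's six 0–4 criterion scores by 24 and
averages readers (normalize-then-average equals average-then-normalize
here; we normalize first so per-reader scores are comparable).

## The synthetic tissue generator

The generator produces the statistical structure the analysis assumes,
at desk scale:

| parameter | default | rationale |
|---|---|---|
| field of view | 0.3 × 0.2 mm, slab 100 µm | ~600 nuclei/image: large enough for stable image means, small enough that a 60-image cohort runs in minutes; slab is epidermis-scale |
| healthy density | 10,000 mm⁻² | 3D spacing ~21 µm, comfortably under the 50 µm cutoff so graphs are rich |
| hard-core distance | 7 µm | nuclei cannot interpenetrate (~6.6 µm diameter at the median volume) |
| volume law | lognormal, median 150 µm³, GSD 1.3 | positive, right-skewed, median consistent with keratinocyte nuclei |
| compactness target | mean 0.75, SD 0.08 | the 0.592 bottom-decile reference threshold implies a broad sphericity distribution |
| atypical component | enlarged ×2.5, roughness ×2 | a mixture, not a whole-population shift: lesions contain atypical cells among normal ones |
| class presets | atypical fraction 0.04 / 0.15 / 0.35 / 0.60, density 10–7,000 mm⁻² | healthy background of irregular nuclei; graded severity SAK < AK < Bowen; lesional skin is sparser |
| subject variability | volume median GSD 1.12, density GSD 1.10, compactness SD 0.03, severity GSD 2.0 | images of one class differ the way subjects and lesions do; without this, image-level AUCs saturate at 1.0 and severity ordering is meaningless |

Counts are Poisson (a hard-core-thinned Poisson process), centers
placed by rejection sampling (shortfalls at infeasible packings are
logged), surfaces are spheres modulated by a smooth random degree-2
angular field whose amplitude is calibrated numerically (a cached
amplitude→compactness curve, inverted per cell) so realized compactness
matches the target on average, and rays are rescaled so each realized
mesh volume equals its lognormal draw exactly. Everything is
deterministic given the seed.

What the generator does *not* emulate: imaging physics (speckle,
depth-dependent contrast), segmentation errors (missed, split, merged
nuclei), epidermal stratification (depth-dependent morphology),
dermal structures, and spatial clustering of atypical cells within a
lesion. Passing tests on synthetic cohorts therefore demonstrate the
*pipeline's* correctness and its statistical behavior under the assumed
tissue model — not clinical performance on real images.

## Benchmark design and problem sizes

The test suite exercises analytic cases (spheres, cubes, regular
tetrahedra), oracle equivalences (convex-hull volume, brute-force
feature recomputation, pair-counting AUC, closed-form Pearson/t), a
5,000-point Poisson–Delaunay degree check, and three 60-image cohorts
(~36,000 nuclei each) scored by all four methods under 5-fold CV:
a strong-effects cohort (homogeneous Bowen-severity lesions; all
methods reach held-out AUC ≥ 0.95), a null cohort (identical presets
for both labels; AUC stays in a chance band), and a mild
subclinical-AK-like cohort whose AUC falls strictly between — the
field-of-cancerization regime where per-image heterogeneity (severity
GSD 2.0) keeps discrimination genuinely imperfect. A 40-image graded
cohort checks that mean rule scores increase healthy → SAK → AK →
Bowen. These sizes keep the full suite within a coffee break on one
CPU while leaving the statistical assertions comfortably powered.

## Known limitations

- Absolute volumes/areas carry the inscribed-mesh deficit (~6%/3% at
  96 rays); thresholds calibrated on one ray count should not be reused
  on another without recalibration.
- The border distance is measured along the center line only; for
  strongly non-convex nuclei it overestimates the true surface gap.
- The logistic fit is unpenalized: on perfectly separable weak labels
  coefficients diverge (scores still rank correctly); implementations
  with default L2 will give slightly different coefficients.
- Isolation-forest scores are only min–max comparable within a
  training fold, not across cohorts.
- The generator's atypical component is spatially unclustered; graph
  features may be more informative on real lesions where atypia
  aggregates.
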