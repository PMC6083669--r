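---
title: "Evaluating vegetation point clouds against a reference scene"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating vegetation point clouds against a reference scene}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cloudtruth)
```

## The problem

Structure-from-motion and multi-view-stereo pipelines turn overlapping
photographs of vegetation into dense 3-D point clouds. For trees these
reconstructions fail in characteristic ways: parts of the crown are missing
(errors of omission), sky or grass is reconstructed as spurious structure
attached to or floating near the tree (errors of commission), whole
components are duplicated ("ghosts"), and every reconstruction lives in its
own arbitrary scale and orientation. Judging reconstruction quality by eye
does not rank software pipelines; `cloudtruth` provides the quantitative
machinery: alignment to a reference, nearest-neighbour discrepancy maps,
an artefact census by connected components, and a single scalar quality
score, the area under an ROC curve swept over a separation-distance
threshold.

Because real reference scenes are hard to come by, the package also ships a
synthetic scene generator and a degrader. Together they produce a labelled
ground-truth scene and simulated "reconstructions" whose every defect is
known, so the entire evaluation chain is testable end to end without any
photogrammetric software or imagery.

## The synthetic scene

`assemble_scene(scene_params())` builds a labelled reference cloud:

* a **tree** (labels 1 trunk, 2 branches, 3 foliage): a recursive
  branching skeleton — each node spawns `branches_per_node` children tilted
  `branch_angle_deg` from the parent axis with seeded azimuth jitter,
  lengths shrinking by `branch_length_ratio` — with points sampled on
  cylinder surfaces and in ellipsoidal foliage blobs at the terminal tips;
* a **ground plane** (label 0): a grid over
  `ground_extent`² with Gaussian vertical roughness
  (`grass_noise_sd`) imitating grass;
* eight **target cubes** (labels 10–17), brightly coloured, ringing the
  tree. Their sampling is antipodally symmetric, so each cube's point
  centroid equals its placement position exactly — they are the alignment
  anchors.

Defaults emulate a field survey of a 16-unit tall deciduous tree imaged
from a 20-unit-radius circular flight (hence a 40-unit ground extent),
about 2×10⁵ points in total. The skeleton is uniformly rescaled so the
crown top sits at `tree_height`; branch radii are `trunk_radius` tapered by
the length ratio per depth. Two sampling-density choices are deliberate:

* cylinder sampling never drops below ~30 points per unit length, and
* foliage blobs default to 1200 points in a semi-axis `1.3 ×` tip-length
  ellipsoid,

so that at the package's operating segmentation scale (a level-8 octree,
256 cells across the scene) the tree is one connected component, as a dense
reconstruction of a real, contiguous crown would be. What the generator
does **not** emulate: imaging radiometry, occlusion-driven density
variation, wind motion, or the specific geometry of any real tree species.
Passing tests on this scene therefore demonstrate correctness of the
*evaluator*, not performance of any reconstruction pipeline on real data.

The scene-width normalizer is defined as the larger of the x- and y-extents
of the assembled reference bounding box; every relative threshold below
refers to it.

## The degrader

`degrade(scene, degrade_spec(...))` turns the reference into a simulated
reconstruction carrying the artefact classes observed in practice, each
under a fresh label ≥ 100 and recorded in a manifest:

* **omission**: spherical holes carved around random tree points, then
  random tree-point removal until at least `omission_fraction` of the tree
  is gone;
* **floating clusters**: truncated-Gaussian sky blobs; centres sit on a
  seeded grid whose spacing guarantees pairwise separation of twice the
  cluster diameter (diameter = 5 × `floating_cluster_sd`, the 2.5-sd
  truncation), in a slab above the crown that clears the scene by the same
  margin — disconnected by construction, yet inside the evaluation bounds;
* **attached ring**: a horizontal torus at the 75th percentile of foliage
  height whose default major radius is the 95th percentile of the crown's
  radial extent *at that height*, so it touches the crown and segments as
  an attached artefact;
* **ghost**: an offset, relabelled copy of a named component;
* **jitter, thinning, pose**: iid Gaussian coordinate noise, Bernoulli
  subsampling, and a similarity transform emulating the arbitrary frame of
  an unaligned reconstruction.

Operators apply in the fixed order omission → thin → jitter → ghost →
attached → floating → pose, so noise never blurs artefact geometry and
misalignment affects the whole output. An all-default spec is the
byte-exact identity. Everything is deterministic in `seed`.

## Alignment

Photogrammetric clouds carry arbitrary scale, so alignment estimates a full
similarity transform `y = s R x + t`. `estimate_similarity()` is the
closed-form SVD solution of the least-squares problem over corresponding
points, with the determinant correction that forces a proper rotation;
correspondences come from the eight target-cube centroids matched by label
(`align_to_targets()`) or from an explicit table. `icp_refine()` optionally
polishes the fit by alternating nearest-neighbour correspondence (with a
rejection cutoff, default 5% of scene width, for robustness against
artefact points) with the closed-form fit; it never returns a transform
whose correspondence RMS exceeds the previous iterate's. The initial guess
must be within the convergence basin — in practice, target-based
initialization always is.

## Distance maps

`nn_distances()` computes exact one-sided nearest-neighbour distances with
a kd-tree (never approximate: evaluation numbers must reproduce bit for
bit). Model→reference distances expose commission; reference→model
distances expose omission. `classify_distances()` normalizes by scene
width and bins into the conventional five colour classes — blue, green,
yellow and red with edges at 0.0075, 0.015 and 0.0225 of unit scene width,
purple beyond — using half-open `[lower, upper)` intervals; a value exactly
at an edge belongs to the class above. The red class extends to twice the
last edge (0.045); that outlier cutoff is this package's choice, made
explicit in `distance_class_scheme(outlier_factor = )`.

## Artefact segmentation

`connected_components()` reproduces the octree connected-components census:
the cloud's own bounding box is divided at `octree_level` (level 8 → 256
cells per axis; the voxel edge is the largest bbox extent divided by
2^level), occupied voxels are connected under 26-neighbourhood, and
clusters below `min_cluster_points` go to a residue bucket. 26-connectivity
is the least-fragmenting rule; it is stated in every report rather than
claimed identical to any external tool. `classify_clusters()` names the
largest cluster **main** (ties to the lowest id, with a warning) and calls
every other cluster **attached** when its minimum point distance to main is
within `gap_threshold` — default twice the voxel edge, "touching at grid
resolution" — and **floating** otherwise.

`census()` adds the omission side: the fraction of reference points farther
than `omission_threshold` from any model point. The threshold sets what
"present" means, and two regimes are useful. At the default (equal to
`gap_threshold`) the census measures *contiguous voids* — holes the size of
the grid resolution or larger. Individually removed points are invisible at
that scale, because their surviving neighbours are closer than the
threshold; to count them, pass a threshold below the reference point
spacing (for exact-copy degradations any tiny value, e.g. `1e-9`, recovers
the removed fraction exactly). The recovery tests use the second regime and
compare against the manifest's all-points removal fraction.

## The ROC/AUC statistic

A 2×2 confusion table needs a negative class, and point sets have none, so
the package discretizes space: a voxel grid (default edge = scene width /
256, matching the level-8 census scale) over the reference bounding box
padded 10% per side, so sky artefacts fall in the negative class. A voxel
is **positive** when a reference point lies within half a voxel diagonal of
its centre — the reference-occupied neighbourhood — and negative otherwise.
At separation distance `r` the model *predicts* positive wherever a model
point lies within `r` of the voxel centre; at `r = 0` the predicted set is
empty. TP/FP/FN/TN follow, with `TP+FN` and `FP+TN` conserved across the
sweep. The construction realizes the three anchor properties the curve
must satisfy: it passes through (0,0) at `r = 0`; it reaches (1,1) once
`r` exceeds the scene size; and a flawless reconstruction passes near
(0,1), since every positive voxel is predicted before any negative one.
`roc_curve()` sweeps 64 geometrically spaced radii from a quarter voxel to
the scene diagonal (resolving the knee while bounding cost), prepends and
appends the anchors, and `auc()` integrates by the trapezoid rule over FPR
(ties keep the maximum TPR), clamped to [0, 1]. The report also carries
simple point-based completeness/correctness rates as diagnostics; they are
one-sided quantities and are deliberately not called an ROC.

Whether confusion should be counted on points or on a discretized grid is
genuinely open; the grid reading is the one that yields a well-defined TN
and satisfies all anchor properties, and it is documented rather than
claimed canonical. Numerical choices worth knowing: nearest-neighbour
queries are exact (kd-tree with bounding-box pruning; voxel sweeps
warm-start each query from the neighbouring voxel's result, which bounds
but never alters the answer); the positive-voxel test uses an equivalent
radius-bounded search; all generators draw from R's RNG under explicit
seeds, and no algorithm in the evaluation chain is stochastic, so equal
inputs give byte-identical reports.

## Problem sizes and known limitations

The package's own test and acceptance runs use the default ~2×10⁵-point
scene for end-to-end properties (identity ROC at the default grid is a few
seconds; a full degradation ladder of sixty AUC evaluations runs at a
64-cell grid in about two minutes) and small random fixtures wherever a
brute-force oracle must be feasible. AUC differences between mild
degradations are small in absolute terms — omission must be severe before
positive voxels empty out — so rankings, not absolute AUC gaps, are the
meaningful output, mirroring how such scores are used in practice.

Limitations: ASCII PLY and XYZ only (binary PLY is rejected, not
mis-read); no meshes, normals or LAS; segmentation connectivity is a
documented convention, not a re-implementation of any GUI tool; rigid-grid
discretization makes the AUC invariant under translation but only
approximately invariant under arbitrary rotation (at the grid resolution);
and the degrader's artefact magnitudes are chosen for testability — the
literature describes artefact classes, not generative parameters.
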