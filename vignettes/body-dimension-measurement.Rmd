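---
title: "Measuring livestock body dimensions from point clouds: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring livestock body dimensions from point clouds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bovimetrics)
```

`bovimetrics` turns a raw 3D scene of a standing quadruped into five linear
body dimensions: withers height, chest depth, back height, waist height and
body length, all in meters. This vignette explains the models behind each
stage, the tunable parameters and their defaults, what the synthetic data
generator does and does not emulate, and the design choices made where the
method leaves room.

## The measurement model

The five dimensions are defined against the ground, not the coordinate
frame of the sensor: the withers, back and waist heights are perpendicular
distances from anatomical upper landmarks to the ground plane; chest depth
is the separation, along the ground normal, between the lowest sternum
point behind the forelegs and the back line directly above it; body length
is the straight 3D distance between a front (shoulder) and a rear (pin)
end point. Body length has no single standard operational definition in the
field; the straight-segment convention used here is the simplest one
consistent with oblique-segment illustrations of the measurement.

Six landmarks therefore have to be found automatically: the withers, back
and waist upper points, the chest lower point, and the two body-length end
points. Everything in the pipeline exists to make that landmark search
reliable on noisy, pose-free sensor data.

## Stage by stage

### Filtering fusion

Three classical filters run in a fixed order (`preprocess_cloud()`):

* `conditional_filter()` — closed per-axis interval bounds, for cropping
  background at known distances. Closed intervals make the filter exactly
  reproducible.
* `statistical_outlier_removal()` — a point survives iff its mean distance
  to its `knn_k` nearest neighbors is at most the global mean plus `alpha`
  standard deviations of those means. Defaults `knn_k = 8`, `alpha = 1.0`.
  Ties at the threshold are kept, again for determinism.
* `voxel_downsample()` — one centroid per occupied cubic cell,
  `leaf = 0.02` m by default. The voxel index is `floor(coordinate/leaf)`
  per axis, so the grid is anchored at the origin and the result does not
  depend on point order.

The defaults preserve a subject of several thousand points at roughly 2 cm
resolution, which is the scale all later neighborhood parameters assume.

### Subject isolation

`ransac_plane()` draws seeded 3-point hypotheses (200 by default), keeps
the one with most inliers at `dist_thresh = 0.02` m (ties resolve to the
earlier draw), and refits by least squares on the inliers; the unit normal
is oriented toward the cloud centroid, i.e. upward for a ground plane under
the animal. The ground is removed *before* clustering, because floor points
otherwise bridge the animal to the background and Euclidean clustering
cannot separate them. `euclidean_cluster()` (connected components of the
`tol = 0.06` m proximity graph) then yields the subject as the largest
cluster. Both the plane and the cluster tolerance live just above the voxel
resolution; they are not sensitive within a factor of two.

### Pose normalization and orientation

The canonical frame has x = body length (tail positive), y = height,
z = chest width, origin at the centroid. The frame comes from PCA of the
subject covariance (eigenvalues sorted descending; right-handedness
enforced). Two ambiguities remain and are resolved separately:

* **Up direction.** PCA only fixes the height axis up to sign, and — more
  importantly — the off-axis mass of the head and neck pitches the raw PCA
  axes by several degrees. A 5° pitch over a ~1.2 m lever arm moves
  apparent heights by ~10 cm, more than the withers-to-rump height margin,
  which would corrupt the head/tail decision below. The pipeline therefore
  aligns the height axis *exactly* to the RANSAC ground normal
  (`normalize_pose(..., up_hint, align_up = TRUE)`), re-orthogonalizing the
  length axis against it. This is consistent with the measurement model
  (heights are defined against the ground) and removes the pitch entirely.
  Plain PCA behavior is available with `align_up = FALSE`.
* **Head direction.** `orientation_correct()` splits the cloud at x = 0 and
  compares the maximum height of the two halves: the half containing the
  higher maximum holds the withers and must lie on −x; otherwise a single
  mirror `x → −x` is applied. The operation is idempotent by construction.

### Curvature and candidate regions

`principal_curvatures()` fits, per point, the quadric height field
`z = a + bu + cv + du² + euv + fv²` over the `knn_k = 16` neighborhood in a
local tangent frame whose z axis is the inward surface normal; the Monge
patch formulas then give the mean and Gaussian curvature and
`k1, k2 = H ± sqrt(H² − K)`. With the inward-z convention, regions that are
convex with respect to the outward normal get `H > 0` (peaks and ridges on
the back line), which fixes the sign semantics of the type table.

Sign bands `|H| ≤ eps_H`, `|K| ≤ eps_K` are treated as zero, with defaults
scaled to each point's neighborhood radius r: `eps_H = 0.05/r`,
`eps_K = 0.01/r²`. Because `eps_K ≥ eps_H²` and always `K ≤ H²`, the
impossible sign combination (H = 0, K > 0) can never be produced by a real
fit — it is rejected with an error if requested explicitly. Rank-deficient
neighborhoods are flagged invalid and excluded from candidate regions.

`candidate_regions()` restricts each landmark's candidates by surface type
and by optional x, y and z bands expressed as fractions of the subject's
extent. The default mapping places the upper landmarks on the convex back
line (types peak/ridge, top 10–20% height band), the chest point at the
sternum keel (low height band; note the keel is locally *convex* — a common
misconception is to look for a concave "valley" there), and the body-length
end points at the high-curvature torso ends at mid height; all six
landmarks are restricted to a sagittal mid-band in z, where they lie by
definition. The bands are anatomical priors, not fitted values: they name
where on a standing quadruped a withers or a sternum can possibly be.

### Landmark recognition

Reference FPFH descriptors (33 bins: three 11-bin histograms of the
Darboux-frame angles α, φ, θ, each block normalized to sum 100) are stored
per landmark in a feature-model database (`build_feature_db()`,
`build_reference_db()`). Recognition (`match_feature_point()`) scans the
candidates in their stored order and accepts the first one whose L1
distance to any reference descriptor of that landmark is within τ — a
first-match rule, not a global optimum.

Two choices make this rule work well:

* **Saving order.** The pipeline stores the subject cloud in descending
  curvature salience (`|k1| + |k2|`), so the scan visits bump and dip
  centers — the most distinctive and most accurately measurable points —
  before their flanks.
* **Threshold calibration.** τ is calibrated per landmark as 1.25 times the
  largest L1 distance between that landmark's own reference descriptors,
  floored at the median spread across landmarks (the max of three pairwise
  distances is a noisy estimate). Compact bumps such as the withers have
  roughly three times less descriptor spread than the extended end rims; a
  single global threshold either starves the rim landmarks or lets
  neck-junction points pass as withers.

If no candidate of a landmark passes τ — a descriptor outlier, observed on
the order of one scene in forty — the pipeline does not abort: it warns and
falls back to the candidate with the smallest descriptor distance inside
the landmark's anatomical band. The strict first-match contract (error on
no match) remains in `match_feature_point()` itself.

The FPFH radius default (0.10 m) matches the spatial scale of the back-line
bumps; at 0.05 m the descriptor mostly measures sensor noise, at 0.2 m it
blurs neighboring features together.

### Dimensions and the error report

`derive_auxiliary_points()` projects the three upper landmarks vertically
onto the ground plane and finds the chest upper point as the highest cloud
point within a small (x, z) cylinder above the sternum (default radius
0.05 m, grown adaptively if the voxelized sampling left that column empty —
at 2 cm resolution a 3 cm disc is empty too often). `compute_dimensions()`
applies the definitions above, and `error_report()` computes
`100·|automatic − manual| / manual`, rounded half-up to two decimals; the
*manual* value is the denominator, the only convention consistent with all
fifteen published reference cells bundled in `qinchuan_reference()`.

## The classifier and transfer learning

The Kd-network (`kdnet_new()`, `train_kdnet()`) canonicalizes a cloud of
`2^depth` points with a balanced Kd-tree (median splits on the widest axis;
seeded resampling and tie-breaks) and computes one representation per tree
node bottom-up: leaves carry raw coordinates, and every internal node
applies `relu(affine(concat(left, right)))` with weights shared across the
nodes of a level with the same split axis; a fully connected layer maps the
root representation to class scores. Training is plain SGD on the softmax
cross-entropy at learning rate 0.003 (larger rates degrade accuracy;
smaller ones converge slowly), with a fresh tree per cloud per epoch, which
doubles as mild augmentation. Layer widths default to doubling from 8,
capped at 128; the original-scale model corresponds to depth 11 (2048
points), while tests and desk-scale defaults use depth 5 (32 points).

Transfer to the cattle/other gate (`transfer_train()`) freezes all level
parameters — they are bit-identical afterwards — replaces the head with a
fresh 2-class affine map and retrains only the head on frozen root
representations, with TrAdaBoost instance re-weighting: misclassified
source examples shrink by the fixed factor
`beta_source = 1/(1 + sqrt(2 ln(n_source)/N))`, misclassified target
examples grow by `(e/(1−e))^{-1}` with `e` the weighted target error rate
(boosting stops if `e ≥ 0.5`), and all weights renormalize each iteration.
The head with the best held-out target accuracy across iterations is kept.
In the measurement pipeline the gate classifies the pose-normalized
subject, the same body frame the training silhouettes use.

## The synthetic data generator

`generate_scene()` emulates a single ToF-LiDAR frame of a standing animal:

* a torso lofted along x with superellipse cross-sections (exponent 2.5),
  whose analytic back line carries a withers hump (amplitude 0.15 m — the
  tallest point of the animal), a small mid-back bump and a rump rise, and
  whose belly line carries a sternum keel; end tapers close the body;
* four cylindrical legs, a neck/head ellipsoid on the head side connected
  by a neck tube;
* a ground plane sampled at a density comparable to the subject's (a pen
  sensor sees both at similar angular resolution; a much sparser ground
  would also be artificially destroyed by the statistical filter);
* optional clutter objects (a trough-like box, a post), a random rigid
  scene pose (full yaw, ±3° tilt, ±0.5 m shift) and isotropic Gaussian
  noise (σ = 3 mm, a ToF-plausible value);
* per-animal shape jitter (±3% on the main shape parameters), so reference
  animals and test animals are different individuals.

Everything downstream of the parameters is analytic: the six landmark
positions and five dimensions are evaluated from the same closed-form
profiles the sampler uses, so the ground truth is exact by construction,
and the exact landmark points are injected into the sample so they are
always reachable by a nearest-neighbor snap.

What the generator does *not* emulate: self-occlusion (a single sensor sees
one side of the animal), range-dependent noise and multipath artifacts,
non-standing postures, coat texture, and multiple animals per scene.
Passing the synthetic recovery criteria therefore shows that the geometry
and recognition chain is correct and well-calibrated at realistic noise and
resolution — not that the system is field-ready for arbitrary barn scenes.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale by choice:
scenes of ~15k points, subjects of ~4.5k after preprocessing, classifier
clouds of 32 points (depth 5), 40–80 training clouds, 20 evaluation scenes
with 3 held-out reference animals. Key numerical conventions: population
(1/n) covariance; eigen-decomposition of symmetric matrices for frames and
normals; QR least squares for the quadric fits; seeded, restartable RNG
everywhere (`with_seed` semantics — no global RNG pollution); RANSAC ties
to the earlier iteration; classification ties to the lower class index;
half-up rounding in the error report.

## Known limitations

* Landmark localization is anisotropic: along the back line or the end
  rims the first-match scan can settle a few centimeters away from the
  nominal landmark, while the component that enters the dimension (height,
  or position along the body axis) stays within a few sampling steps. The
  20-scene mean absolute relative dimension error is ~1%, with chest depth
  the noisiest dimension (worst single-scene errors around 5%).
* Transfer learning reaches ≥ 0.90 gate accuracy, but on these synthetic
  classes it does not systematically beat a from-scratch 2-class model:
  the cattle-vs-distractor separation is easy enough that frozen features
  carry no measurable advantage. The benefit claimed for transfer on real,
  scarce cattle data is not reproducible from synthetic geometry alone.
* The orientation rule assumes the withers is the highest point of the
  animal; heads raised above the withers (alert posture) would defeat it.
* ASCII PCD/PLY/XYZ only; binary dialects are out of scope.
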