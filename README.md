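# bovimetrics

Non-contact measurement of livestock body dimensions from 3D point clouds.

Periodic body measurement of large animals (withers height, chest depth,
back height, waist height, body length) is normally done with sticks and
tapes on a restrained animal — slow, stressful and inspector-dependent.
`bovimetrics` implements an automatic alternative for ToF-LiDAR-style point
clouds of a standing animal: the scene is filtered, the animal isolated,
its pose normalized, anatomical landmarks recognized from local surface
geometry, and the five linear dimensions computed against the fitted ground
plane.

## Method

Given a raw scene cloud `P = {p_i}` (meters), the pipeline runs:

1. **Filtering fusion** — conditional range filter, statistical outlier
   removal (keep `p` iff its mean k-NN distance ≤ μ + ασ of the per-point
   means), voxel-grid downsampling (centroid per occupied `leaf`-sized cell).
2. **Subject isolation** — RANSAC ground-plane fit (best 3-point hypothesis
   by inlier count, least-squares refit) followed by Euclidean clustering of
   the remaining points; the largest cluster is the animal.
3. **Pose normalization** — centroid `p_m = (1/n) Σ p_i`, covariance
   `C_p = (1/n) Σ (p_i − p_m)(p_i − p_m)ᵀ`, eigenvectors `C_p e_i = λ_i e_i`
   assigned as x = body length, y = height, z = width; an orientation rule
   (the half-body containing the higher maximum — the withers — belongs on
   −x) applies at most one mirror `x → −x` so the tail points to +x.
4. **Curvature typing** — per point, a quadric
   `z = a + bu + cv + du² + euv + fv²` is fitted over the k-neighborhood in
   a local tangent frame; mean and Gaussian curvature follow from the Monge
   patch formulas
   `H = ((1+I_x²)I_yy − 2 I_x I_y I_xy + (1+I_y²)I_xx) / (2 (1+I_x²+I_y²)^{3/2})`,
   `K = (I_xx I_yy − I_xy²) / (1+I_x²+I_y²)²`, and
   `k_{1,2} = H ± sqrt(H² − K)`. The signs of (H, K) classify each point
   into one of eight surface types (peak, ridge, saddle ridge, plane,
   minimal saddle, saddle valley, valley, well); (H = 0, K > 0) is
   mathematically impossible and rejected.
5. **Landmark recognition** — per landmark, candidate regions are the typed
   points inside configured anatomical bands; candidates are scanned in the
   stored order and the first whose 33-bin FPFH descriptor lies within a
   calibrated L1 threshold τ of a reference descriptor in the feature-model
   database is accepted (no global-best search).
6. **Dimensions** — withers/back/waist heights are perpendicular distances
   of the matched upper landmarks to the ground plane; chest depth is the
   vertical separation of the sternum point and the back line above it;
   body length is the 3D distance between its two end landmarks. An
   automatic-vs-manual error report uses
   `error% = 100·|auto − manual| / manual`, rounded half-up to 2 decimals.

A Kd-tree deep network (shared affine weights per tree level and split
axis, ReLU `f(x) = max(0, x)`, softmax head, plain SGD) pre-trained on
synthetic multi-class shape clouds can be transfer-retrained — frozen
levels, re-initialized 2-class head, TrAdaBoost instance re-weighting
(`β_src = 1/(1+√(2 ln n_src / N))`, misclassified target weights scaled by
`(e/(1−e))^{-1}`) — into a cattle / other gate for the pipeline.

Because no public cattle scan corpus ships with the package, a synthetic
scene generator provides the test bed: a parametric cow-sized body
(superellipse-section torso whose back line carries a withers hump, mid-back
bump and rump rise, a sternum keel, four cylindrical legs, a neck/head
lobe), a ground plane, background clutter, a random rigid scene pose and
Gaussian sensor noise — with exact landmark positions and dimensions as
ground truth.

## Worked example

```r
library(bovimetrics)

scene <- generate_scene(seed = 1)        # synthetic LiDAR scene + truth
scene$cloud
#> pointcloud: 15411 points, frame 'sensor'
#>   extent x [-2.173, 2.094] y [-0.529, 0.919] z [-1.677, 2.427] m

db  <- build_reference_db(c(101, 102, 103))   # 3 held-out reference animals
res <- measure_pipeline(scene$cloud, db, seed = 1)
res$dimensions
#> body dimensions (m):
#>   withers_height  1.231
#>   chest_depth     0.670
#>   back_height     1.131
#>   waist_height    1.166
#>   body_length     1.737

error_report(res$dimensions, unlist(scene$truth$dimensions_true))
#>        dimension automatic    manual error_percent
#> 1 withers_height 1.2309854 1.2329165          0.16
#> 2    chest_depth 0.6702464 0.6426838          4.29
#> 3    back_height 1.1311710 1.1357489          0.40
#> 4   waist_height 1.1664986 1.1785993          1.03
#> 5    body_length 1.7371909 1.7164041          1.21
```

The five values are the recovered dimensions in meters; the report compares
them with the generator's ground truth exactly as automatic measurements
would be compared with a manual tape measurement (manual value in the
denominator). Averaged over 20 scenes the mean absolute relative error is
about 1%.

The same flow is scriptable from a shell:

```sh
Rscript inst/cli/bovimetrics.R synth   --output scenes/ --seed 1
Rscript inst/cli/bovimetrics.R builddb --output db.json
Rscript inst/cli/bovimetrics.R measure --input scenes/scene_001.pcd \
        --db db.json --output report.json
```

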