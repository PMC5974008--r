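# contourreg

Global (initialisation-free) rigid registration between a preoperative
liver surface mesh and a partial, deformed, noisy intraoperative surface,
for image-guided laparoscopic liver surgery.

Manual initial alignment of a CT-derived liver model with the laparoscopic
view is slow and unintuitive; ICP-family fine alignment needs a good
starting pose. `contourreg` computes that starting pose from the surfaces
alone plus one piece of expert input available in both modalities: the
delineated **liver ridge line** (the sharp anterior-inferior edge of the
organ).

## Method

Feature points on both surfaces (farthest-point or normal-space sampling)
carry rigid-invariant TOLDI descriptors. Matching is a quadratic assignment
problem: minimise descriptor dissimilarity while preserving pairwise
geodesic distances. It is solved by spectral matching on an affinity matrix
`W` over candidate correspondences `(m, t)_i` (descriptor k-nearest
neighbours):

* `W[i,i] = sim(f(m_i), f(t_i))` — descriptor similarity;
* `W[i,j] = alpha * g(c_ij, sigma_d) + (1 - alpha) * g_b(i, j, sigma_b)`,

where `c_ij = min(d_g(m_i,m_j)/(d_g(t_i,t_j)+eps),
d_g(t_i,t_j)/(d_g(m_i,m_j)+eps))` is the geodesic-consistency ratio,
`g(c, sigma) = exp(-(c-1)^2 / (2 sigma^2))` tolerates non-rigid deviation,
and the contour term `g_b` applies the same kernel to each feature's
geodesic distance to the nearest ridge-line point, `d_g(x, b_x)`. The
principal eigenvector of `W` ranks candidates; greedy one-to-one selection
yields the pruned set `C_p`, from which RANSAC (minimal 3-point samples,
Kabsch/Umeyama estimation, RMSE threshold `d_RANSAC` and a 60-degree
normal-angle test, smallest-error fallback) produces the rigid transform.
Defaults follow the published operating point: `sigma_d = sigma_b = 0.3`,
`alpha = 0.6`, 1000 RANSAC iterations, `d_RANSAC` = 5 mm (rigid benchmark)
or 10 mm. Geodesics are computed by fast marching on the triangle mesh, and
the moving-side features, descriptors and geodesic tables are precomputed
once per CT model and cached.

## Worked example

Register a randomly posed 23% partial view of a synthetic liver against the
full model, with the ridge contour supplied on both sides:

```r
library(contourreg)

liver <- synthetic_liver(4)               # mesh + ridge polyline, mm
cfg   <- pipeline_config(d_ransac = 5, toldi_L = 8L, n_features = 150L,
                         toldi_radius = 0.06 * bbox_diagonal(liver$mesh))
cache <- precompute_moving(liver$mesh, liver$contour, cfg)

cs   <- contour_set(liver$mesh, liver$contour)
near <- which(geodesic_to_set(liver$mesh, cs$vertices) < 45)
view  <- make_partial_view(liver$mesh, 0.23, seed = 7, near = near)
posed <- apply_random_rigid(compute_normals(view), seed = 8)
vis   <- cs$vertices[cs$vertices %in% attr(view, "index_map")]
ridge_t <- apply_transform(posed$transform, liver$mesh$vertices[vis, ])

res <- register_surfaces(cache, posed$mesh, target_contour = ridge_t,
                         config = cfg, algorithm = "SM+R2")
res
imap <- attr(view, "index_map")
evaluate_registration(res$transform, liver$mesh$vertices[imap, ],
                      apply_transform(posed$transform,
                                      liver$mesh$vertices[imap, ]))$mean
```

```
pipeline_result [SM+R2]: |C| = 750, |C_p| = 20, RMSE 1.71 mm, accepted
[1] 0.4208765
```

750 candidate pairs are pruned to 20 by spectral matching; RANSAC accepts a
transform whose RMSE over those pairs is 1.7 mm (below the 5 mm threshold,
normal test passed), and the mean distance between every vertex of the
partial view and its ground-truth position is 0.42 mm — an order of
magnitude below the 5.5 mm mesh resolution. The benchmark protocol
(`run_robustness_experiment()`) repeats this over partial-view fractions
from 43% down to 7%, 18 deformation levels and three algorithm variants
(`R`, `SM+R1`, `SM+R2`).

A command-line front end is installed with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "contourreg", package = "contourreg"))')
Rscript $CLI precompute --moving liver_ct.ply --contour ridge_ct.csv --out cache.crz
Rscript $CLI register   --cache cache.crz --target recon.ply \
                        --target-contour ridge_video.csv --out tfm.json
Rscript $CLI benchmark  --config bench.yaml --out results/
```

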