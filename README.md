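# fovex — field-of-view expansion for multi-camera endoscopic imaging

Minimally invasive surgery forces the surgeon to work through a narrow
endoscopic view. One remedy is to add extra viewpoints (small cameras at the
access ports), localize every camera with visual SLAM, and fuse the video
streams into a single expanded view. The hard step is registration: the
cameras share no fixed baseline, so their maps must be linked through a
**similarity transform** estimated from corresponding 3D map points — and
SLAM map points are noisy enough that a plain closed-form fit is easily
corrupted.

`fovex` implements the offline core of such a pipeline for R:

* **Closed-form absolute orientation** (Horn's quaternion method). For
  paired clouds `p_i ↔ q_i` with centred coordinates `p'_i, q'_i`, the
  rotation is the unit quaternion `ė = (e0, e1, e2, e3)` maximizing the
  alignment criterion (largest eigenvector of the 4×4 matrix built from
  `Σ p'_i q'_iᵀ`), the scale is `s = Σ q'_i·(R p'_i) / Σ‖p'_i‖²`, and
  `t = q̄ − s R p̄`.
* **Robust estimation.** Two estimators on top of the closed form: an
  inlier-maximizing search over all three-point subsets
  (`estimate_pose_ransac`), and a quaternion-filtering estimator
  (`estimate_pose_filtered`) that computes one candidate quaternion per
  C(N,3) triple, keeps candidates within `σ_ℓ/d` of the component-wise
  median (σ_ℓ the per-component spread over all candidates), averages the
  survivors, and refits scale/translation from all N points. Automatic
  key-frame pair selection (≥ 20 correspondences, ≥ 20 inliers) and
  click-to-feature snapping cover the interactive workflow.
* **Presentation geometry and compositing.** Projection-plane sizing
  (`W' = Z·W/fx`), plane–plane intersection lines, bisecting planes,
  line–plane intersection, overlap clipping (trapezoid/pentagon taxonomy),
  and a polygonal-cylinder approximation with `r = W_T·360/(2π·θ)`. A
  deterministic software compositor renders the naive, single-plane,
  overlap-removal and cylindrical expanded views with per-pixel provenance.
* **Metrics.** ZNCC, mutual information (256-bin joint histogram, bits),
  aligned-cloud MSE/variance, and the angle
  `a = arccos(ω·ω′ / |ω||ω′|)` between axis-angle rotation vectors.
* **Synthetic benchmark.** The full evaluation protocol: 10 points uniform
  in [−5,5]³, random roll/pitch/yaw in [−π,π], scale in (0,5], translation
  in [−5,5], per-coordinate noise uniform in [−0.1s, 0.1s]; estimate, map
  the noisy cloud back through the inverse estimate, and score.

## Worked example

```r
library(fovex)

# exact recovery from noise-free correspondences
p  <- rbind(c(1,0,0), c(0,1,0), c(0,0,1), c(1,1,0), c(0,1,1))
tr <- similarity_transform(rpy_to_rotmat(0.2, -0.1, 0.9), s = 0.5, t = c(4, 5, -2))
est <- fit_similarity(correspondence_set(p, apply_transform(tr, p)))
print(est)
#> Similarity transform (x -> s R x + t)
#>   rotation angle: 53.5815 deg
#>   quaternion:     0.89265861  0.11141298 -0.00140894  0.43674450
#>   scale:         0.5
#>   translation:    4  5 -2

# one noisy synthetic trial, both robust estimators
trial <- generate_trial(seed = 42)
res_h <- run_protocol(trial, method = "algo1")         # best-triple search
res_f <- run_protocol(trial, method = "algo2", d = 2)  # quaternion filtering
cat(sprintf("best-triple:  a = %.4f deg, MSE = %.5f\n", res_h$a_deg, res_h$mse))
cat(sprintf("filtered d=2: a = %.4f deg, MSE = %.5f\n", res_f$a_deg, res_f$mse))
#> best-triple:  a = 0.1887 deg, MSE = 0.00874
#> filtered d=2: a = 0.2535 deg, MSE = 0.00784
print(res_f$report)
#>              wx    wy      wz theta_deg  a_deg      s      tx     ty      tz
#> truth    1.5896 1.237 -1.8808   157.896     NA 3.4416 -4.9605 3.3292 -4.9267
#> estimate 1.5930 1.246 -1.8732   157.945 0.2535 3.4628 -4.9244 3.3519 -4.8431
#> error    0.0034 0.009  0.0076     0.049     NA 0.0212  0.0361 0.0227  0.0836
```

`run_campaign(n_trials = 200, seed = 1)` repeats this over paired trials;
under the stated noise model the filtered estimator has lower mean
aligned-cloud MSE and about half the MSE variance of the best-triple
baseline (paired sign test; see the methods vignette).

A thin command-line wrapper is installed at
`system.file("cli", "fovex.R", package = "fovex")` with subcommands
`estimate | benchmark | generate | stitch | metrics`.

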