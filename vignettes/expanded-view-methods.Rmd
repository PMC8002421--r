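---
title: "Robust inter-camera pose estimation and expanded-view geometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust inter-camera pose estimation and expanded-view geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fovex)
```

## The problem

A multi-camera endoscopic setup runs one visual-SLAM instance per camera.
Each instance produces its own map: key frames, 2D feature points, and
triangulated 3D map points, in its own coordinate frame with its own
arbitrary scale (monocular SLAM cannot observe metric scale). To fuse the
views, the frames must be linked by a similarity transform

$$ q = s\,R\,p + t, $$

seven degrees of freedom estimated from map points seen by both cameras.
Those correspondences are few (tens, not thousands) and individually
unreliable — triangulation error, mismatches, and moving tissue all inject
outliers — so the estimator has to be robust at very small N.

## Estimators

**Closed form.** `fit_similarity()` implements the classical quaternion
solution: with centred coordinates $p'_i = p_i - \bar p$,
$q'_i = q_i - \bar q$, the rotation quaternion is the dominant eigenvector
of the symmetric 4×4 matrix assembled from $\sum_i p'_i q'^{\,T}_i$, the
scale is the asymmetric form $s = \sum_i q'_i \cdot (R\,p'_i) / \sum_i
\lVert p'_i \rVert^2$, and $t = \bar q - sR\bar p$. The asymmetric scale is
chosen (over the symmetric geometric-mean form) because it is the one that
pairs exactly with this translation formula; noise-free recovery is then
exact to machine precision, which the tests assert at $10^{-8}$.

**Inlier maximization** (`estimate_pose_ransac`). Every three-point subset
gives a candidate transform; candidates are scored by the number of
correspondences whose 3D residual $\lVert q_i - (sRp_i + t)\rVert$ falls
at or below a threshold. The subset search is exhaustive while
$\binom{N}{3} \le 4060$ (i.e. $N \le 30$, the manual-selection regime) and
switches to seeded sampling of distinct triples beyond that. Ties are
broken by smaller mean inlier residual, then enumeration order, making the
result order-invariant. The residual is *3D* map-point distance, not pixel
reprojection: map points are the estimation domain here, and key-frame
records need not carry intrinsics. The default threshold is one tenth of
the RMS radius of the centred target cloud, so it scales with the scene.

**Quaternion filtering** (`estimate_pose_filtered`). All $\binom{N}{3}$
candidate quaternions $\dot e_i$ are computed (canonicalized to $e_0 \ge 0$
— the $q/-q$ double cover must be resolved before any averaging), the
component-wise median $e_{m\ell}$ and the spread

$$ \sigma_\ell = \sqrt{\tfrac1n \sum_i (e_{i\ell} - \bar e_\ell)^2} $$

are taken over all candidates ($\bar e_\ell$ the mean — the spread is
mean-centred even though the band is median-centred), and a candidate is
kept only when **every** component satisfies
$|e_{i\ell} - e_{m\ell}| \le \sigma_\ell / d$. The representative rotation
is the renormalized mean of the kept candidates; scale and translation are
then refit from *all* N centred correspondences with that rotation. The
divisor is a half-width: larger `d` means a narrower band and fewer kept
candidates ($d=4$ stricter than $d=2$), and the kept set at $d=4$ is always
a subset of the one at $d=2$.

Two boundary choices deserve a note. First, the band is a half-width
$\sigma_\ell/d$ rather than a multiple $\sigma_\ell \cdot d$: only the
former makes "increase d, keep fewer" true, and that monotonicity is the
defining behaviour of the parameter. Second, because the component-wise
median need not itself be a candidate, a sufficiently narrow band can
exclude every candidate; in that case the filter keeps the single candidate
minimizing the $\sigma$-scaled maximum component deviation. That candidate
is the first to enter the band as it widens, so the fallback preserves the
subset-nesting property across `d` (a plain nearest-to-median fallback does
not, which is why it is not used).

**Key-frame pair selection.** `select_optimal_keyframe_pair()` scans all
pairs (first set major), matches descriptors (a mutual-nearest Hamming
matcher over binary descriptors is included), keeps pairs with at least
`min_corr = 20` map-point correspondences, and accepts the first whose
inlier count reaches `min_inliers = 20`. Both defaults reflect the typical
feature count of an endoscopic key frame and are configurable.

## Presentation geometry

Each camera image is texture-mapped onto a plane perpendicular to its
optical axis at distance $Z$ from the principal point, with size
$W' = Z\,W_{im}/f_x$, $H' = Z\,H_{im}/f_y$. $Z$ is an empirical scene-scale
parameter (default 1 scene unit; for the synthetic scene generator a value
is derived that puts the projection surface on the observed surface).
Three compositions are provided beyond naive superposition:

* **Single-plane projection** — both images are centrally projected onto
  the plane through the inter-plane intersection line at half the
  inter-plane angle $\theta_{12}/2$ to each. Of the two such bisectors the
  one whose normal aligns with $n_1 + n_2$ (facing the cameras) is used.
* **Overlap removal** — each camera keeps its own plane, but one quad
  (camera 2 by default, configurable) is clipped at the intersection line
  so the shared region is drawn once. The kept half-plane is the one away
  from the other camera's optical-axis intersection with the clipped
  plane. Clipping a convex quad with one line yields the expected shape
  classes: unchanged, trapezoid (4 vertices), pentagon (5), or triangle.
  Seam pixels belong to the uncropped camera (half-open assignment), so no
  canvas pixel is ever owned by both cameras — the defining property of
  this method, asserted on every render.
* **Cylindrical projection** — a cylinder tangent to the bisecting plane
  along the footprint midline, radius $r = W_T \cdot 360 / (2\pi\,
  \theta_{cyl})$ so the arc length matches the projected width $W_T$,
  approximated by `n_strips` planar chordal strips (defaults: $\theta_{cyl}
  = 120°$, 32 strips; the chord sagitta $r(1-\cos(\Delta\theta/2))$ shrinks
  monotonically with the strip count, so more strips trade time for
  smoothness).

Rendering replaces the original OpenGL texture pipeline with deterministic
software inverse mapping: each output pixel is back-projected from a
virtual viewpoint (default: midpoint of the camera centres along the mean
optical axis) onto the method's surfaces, mapped into each source camera
through the pinhole model, and sampled bilinearly (nearest-neighbour switch
for exact tests). Draw order is camera 1 then camera 2, and a provenance
mask records per-pixel ownership. Pixel coordinates are 0-based with
integer pixel centres; the principal point defaults to $(W-1)/2,(H-1)/2$.

## Metrics

`zncc()` is the zero-mean normalized cross-correlation with the
root-product denominator — the form required for the score to reach 1 on
identical images and to be invariant to positive affine intensity maps.
A constant image makes it undefined and raises an error rather than
returning a value. `mutual_information()` uses the full 256×256 joint
intensity histogram in log base 2 (bits), with $0\log 0 := 0$; colour
inputs are reduced to ITU-R 601 luma, and `[0,1]`-scaled images are
stretched to the 8-bit convention before binning. Pose accuracy is
reported in the nine-column format: rotation-vector components, angle
$\theta = \lVert\omega\rVert$ in degrees, the inter-vector angle
$a = \arccos(\omega\cdot\omega' / |\omega||\omega'|)$, scale and
translation, with each error defined as estimate − truth.

## The synthetic benchmark

`generate_trial()` reproduces the evaluation conditions exactly as stated:
10 points with coordinates uniform in $[-5,5]$; roll, pitch, yaw uniform in
$[-\pi,\pi]$ composed intrinsically as $R_z R_y R_x$ (the composition order
is a documented choice — any fixed convention samples the same rotation
distribution); translation uniform in $[-5,5]$; scale uniform in
$[0.05, 5]$ — the nominal lower bound of 0 is raised because $s = 0$ is not
a similarity and values below 0.05 collapse both the transform and its
noise band; and per-coordinate noise uniform on $[-0.1s, 0.1s]$ (a stated
range with no distribution is read as uniform). Everything is driven by a
single integer seed and is bit-for-bit reproducible.

`run_protocol()` estimates from the ideal cloud to the noisy transformed
cloud, maps the noisy cloud back through the exact inverse of the estimate,
and scores aligned-cloud MSE and its variance plus the error report.
`run_campaign()` runs paired trials for several methods; the "plain"
baseline in comparisons is the best-triple search (the closed form applied
to the winning minimal subset), with an all-points closed-form baseline
also available. With 200 trials at the stated noise level, the filtered
estimator at $d=2$ shows lower mean MSE, roughly halved MSE variance, and a
paired one-sided sign test far below $p = 0.01$ — the package's acceptance
suite asserts exactly these directional statements, not any single random
instance. `quaternion_spread()` exposes the mechanism: per-component
candidate statistics collapse to $\sigma < 10^{-8}$ on a noise-free cloud
and inflate under noise.

`generate_two_camera_scene()` complements the point-cloud trials with an
image-level fixture: two verged pinhole cameras viewing a plane textured by
a smooth seeded sum of sinusoids, rendered by exact inverse mapping, with
correspondences emitted in both map frames under a known ground-truth
similarity. It deliberately emulates only the geometry and photometric
smoothness of a scene — not specular highlights, occlusion, tissue
deformation, rolling shutter, or SLAM triangulation error structure — so
passing tests demonstrate correctness of the estimators and compositor,
not clinical performance.

## Numerical choices and degenerate inputs

* Quaternions are scalar-first and canonicalized to $e_0 \ge 0$ (ties:
  first nonzero component positive) immediately after every construction.
* A point triple is degenerate when the second singular value of its
  centred coordinate matrix falls below $10^{-9}$ of the largest
  (collinear or coincident points leave rotation about the common line
  unconstrained); degenerate triples are skipped in enumeration, and fully
  degenerate inputs raise explicit errors rather than returning garbage.
* Rotation-matrix → quaternion conversion uses Shepperd branch selection;
  axis-angle extraction goes through the quaternion, keeping angles near
  180° well-conditioned. Round-trips hold to $10^{-9}$ below 180°.
* Plane normals are normalized on construction; intersection outputs are
  verified against their defining equations by substitution at $10^{-9}$ in
  the property suite (1,000 random configurations).
* Parallel planes, lines parallel to planes, clicks with no feature in
  radius, constant images under ZNCC, and surfaces entirely behind the
  viewpoint all raise typed, descriptive errors.

## Problem sizes and limitations

The shipped test and acceptance runs use 200-trial campaigns, 1,000-case
geometry sweeps and 200×150-pixel renders — sizes chosen so the full suite
completes in about a minute while keeping every statistical comparison
well-powered. Known limitations: no bundle adjustment or iterative
refinement beyond the closed form (by design); the compositor is an offline
single-frame renderer, not a real-time video loop; exhaustive triple
enumeration is $O(N^3)$ and intentionally capped by seeded sampling at
large N; and the published estimates from real endoscopic SLAM clouds
cannot be regenerated because the underlying random instances and
recordings are not published — the package reproduces their arithmetic
identities and their qualitative method ordering instead.
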