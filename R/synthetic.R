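#' Synthetic evaluation protocol
#'
#' Seeded generators reproducing the study conditions used to evaluate the
#' pose estimators: an ideal cloud of 10 points with coordinates uniform
#' in [-5, 5], a ground-truth similarity built from roll/pitch/yaw uniform
#' in [-pi, pi], scale uniform in [0.05, 5] and translation components
#' uniform in [-5, 5], and per-coordinate observation noise uniform in
#' [-0.1 s, 0.1 s] added to the transformed cloud. (The nominal scale range
#' starts at 0, but a similarity needs s > 0, so sampling starts at 0.05.)
#'
#' @name synthetic_benchmark
NULL

#' Generate one synthetic pose-estimation trial
#'
#' @param seed integer RNG seed; identical seeds give identical trials.
#' @param n number of points (default 10).
#' @param coord_range range of ideal-cloud coordinates.
#' @param angle_range range of roll/pitch/yaw (radians).
#' @param scale_range range of the scale factor (lower bound > 0).
#' @param trans_range range of translation components.
#' @param noise relative noise half-width: each coordinate of the
#'   transformed cloud is perturbed by Uniform(-noise * s, noise * s).
#'   Set to 0 for the noise-free variant.
#' @return object of class `synthetic_trial`: `ideal_cloud`,
#'   `gt_transform`, `transformed_cloud` (exact), `noisy_cloud`, `seed`
#'   and the sampled `roll`, `pitch`, `yaw`.
#' @export
generate_trial <- function(seed, n = 10, coord_range = c(-5, 5),
                           angle_range = c(-pi, pi),
                           scale_range = c(0.05, 5),
                           trans_range = c(-5, 5), noise = 0.1) {
  stopifnot(n >= 3, scale_range[1] > 0, noise >= 0)
  set.seed(seed)
  ideal <- matrix(stats::runif(3 * n, coord_range[1], coord_range[2]),
                  ncol = 3)
  ang <- stats::runif(3, angle_range[1], angle_range[2])
  s <- stats::runif(1, scale_range[1], scale_range[2])
  t <- stats::runif(3, trans_range[1], trans_range[2])
  R <- rpy_to_rotmat(ang[1], ang[2], ang[3])
  gt <- similarity_transform(R, s, t)
  transformed <- apply_transform(gt, ideal)
  noisy <- transformed +
    matrix(stats::runif(3 * n, -noise * s, noise * s), ncol = 3)
  structure(list(ideal_cloud = ideal, gt_transform = gt,
                 transformed_cloud = transformed, noisy_cloud = noisy,
                 seed = seed, roll = ang[1], pitch = ang[2], yaw = ang[3],
                 noise = noise),
            class = "synthetic_trial")
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat("Synthetic trial (seed ", x$seed, "): ", nrow(x$ideal_cloud),
      " points, s = ", format(x$gt_transform$s, digits = 4),
      ", noise = ", x$noise, "\n", sep = "")
  invisible(x)
}

.estimate_by_method <- function(corr, method, d = 2, threshold = NULL,
                                seed = NULL) {
  switch(method,
         horn = {
           tr <- fit_similarity(corr)
           res <- transform_residuals(tr, corr)
           th <- if (is.null(threshold)) default_inlier_threshold(corr) else threshold
           structure(list(transform = tr, inlier_count = sum(res <= th),
                          inlier_mask = res <= th, residuals = res,
                          method = "horn_all_points", threshold = th),
                     class = "pose_estimate")
         },
         algo1 = estimate_pose_ransac(corr, threshold = threshold, seed = seed),
         algo2 = estimate_pose_filtered(corr, d = d, threshold = threshold,
                                        seed = seed),
         stop("unknown method: ", method))
}

#' Run the evaluation protocol on one trial
#'
#' Estimates the similarity from the ideal cloud (camera 1) to the noisy
#' transformed cloud (camera 2) with the chosen method, maps the noisy
#' cloud back through the exact inverse of the estimate, and scores the
#' result: mean squared error and its variance against the ideal cloud,
#' plus the nine-column transform error report.
#'
#' @param trial a [generate_trial()] result.
#' @param method `"horn"` (closed form on all points), `"algo1"`
#'   (inlier-maximizing triple search) or `"algo2"` (quaternion
#'   filtering).
#' @param d removal-range divisor for `"algo2"`.
#' @param threshold inlier threshold (default scene-scaled).
#' @return list with `estimate`, `report` ([transform_error_report()]),
#'   `mse`, `sd`, `a_deg`, `method`, `d`.
#' @export
run_protocol <- function(trial, method = c("algo2", "algo1", "horn"), d = 2,
                         threshold = NULL) {
  stopifnot(inherits(trial, "synthetic_trial"))
  method <- match.arg(method)
  corr <- correspondence_set(trial$ideal_cloud, trial$noisy_cloud)
  est <- .estimate_by_method(corr, method, d = d, threshold = threshold)
  back <- apply_transform(invert_transform(est$transform), trial$noisy_cloud)
  rep <- transform_error_report(est$transform, trial$gt_transform)
  list(estimate = est, report = rep,
       mse = cloud_mse(trial$ideal_cloud, back),
       sd = cloud_sd(trial$ideal_cloud, back),
       a_deg = rep["estimate", "a_deg"],
       method = method, d = d)
}

#' Run a seeded multi-trial benchmark campaign
#'
#' Generates `n_trials` independent trials and scores every requested
#' method on each, enabling paired comparisons (the same trials are used
#' for all methods).
#'
#' @param n_trials number of trials.
#' @param seed master seed; per-trial seeds are drawn from it.
#' @param methods character vector from `"horn"`, `"algo1"`, `"algo2"`.
#' @param d_values removal-range divisors evaluated for `"algo2"`.
#' @param noise relative noise half-width (see [generate_trial()]).
#' @param n points per trial.
#' @return object of class `benchmark_report`: `results` (one row per
#'   trial x method: mse, sd, a_deg, theta error, scale error),
#'   `aggregate` (mean/variance of MSE and mean angular error per method),
#'   `seed`, `n_trials`.
#' @export
run_campaign <- function(n_trials = 200, seed = 1,
                         methods = c("algo1", "algo2"), d_values = 2,
                         noise = 0.1, n = 10) {
  stopifnot(n_trials >= 1)
  set.seed(seed)
  trial_seeds <- sample.int(2^31 - 2, n_trials)
  rows <- list()
  for (i in seq_len(n_trials)) {
    trial <- generate_trial(trial_seeds[i], n = n, noise = noise)
    for (m in methods) {
      dv <- if (m == "algo2") d_values else NA_real_
      for (d in dv) {
        r <- run_protocol(trial, method = m, d = if (is.na(d)) 2 else d)
        lab <- if (m == "algo2") paste0(m, "_d", d) else m
        rows[[length(rows) + 1]] <- data.frame(
          trial = i, seed = trial_seeds[i], method = lab,
          mse = r$mse, sd = r$sd, a_deg = r$a_deg,
          theta_err = r$report["error", "theta_deg"],
          s_err = r$report["error", "s"])
      }
    }
  }
  results <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(results, results$method), function(g) {
    data.frame(method = g$method[1], mean_mse = mean(g$mse),
               var_mse = stats::var(g$mse), median_a = stats::median(g$a_deg),
               mean_a = mean(g$a_deg))
  }))
  rownames(agg) <- NULL
  structure(list(results = results, aggregate = agg, seed = seed,
                 n_trials = n_trials, noise = noise),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("Benchmark campaign: ", x$n_trials, " trials (seed ", x$seed,
      ", noise ", x$noise, ")\n", sep = "")
  print(x$aggregate, row.names = FALSE)
  invisible(x)
}

#' Paired sign-test comparison of two methods' per-trial MSE
#'
#' One-sided test that `method_a` beats `method_b` (smaller aligned-cloud
#' MSE) on more than half of the paired trials.
#'
#' @param report a [run_campaign()] result.
#' @param method_a,method_b method labels in `report$results$method`.
#' @return `htest` from [stats::binom.test()].
#' @export
campaign_sign_test <- function(report, method_a = "algo2_d2",
                               method_b = "algo1") {
  res <- report$results
  a <- res$mse[res$method == method_a][order(res$trial[res$method == method_a])]
  b <- res$mse[res$method == method_b][order(res$trial[res$method == method_b])]
  stopifnot(length(a) == length(b), length(a) > 0)
  wins <- sum(a < b)
  ties <- sum(a == b)
  stats::binom.test(wins, length(a) - ties, p = 0.5, alternative = "greater")
}

#' Component-wise spread statistics of candidate quaternions
#'
#' Computes all three-point candidate quaternions for a correspondence set
#' and summarizes each component with mean, median, standard deviation,
#' maximum and minimum — the diagnostic used to contrast clean and noisy
#' point clouds (noise inflates the spread; an ideal cloud collapses it).
#'
#' @param corr a [correspondence_set()] (or a `synthetic_trial`, whose
#'   ideal/noisy clouds are used).
#' @param reference optional reference quaternion prepended as a
#'   `gold_standard` row.
#' @return matrix with rows `mean`, `median`, `std_dev`, `maximum`,
#'   `minimum` (plus optional `gold_standard`) and columns `e0..e3`;
#'   attribute `"n_candidates"`.
#' @export
quaternion_spread <- function(corr, reference = NULL) {
  if (inherits(corr, "synthetic_trial")) {
    corr <- correspondence_set(corr$ideal_cloud, corr$noisy_cloud)
  }
  stopifnot(inherits(corr, "correspondence_set"))
  cands <- triple_quaternions(corr)
  stats <- rbind(mean = colMeans(cands),
                 median = apply(cands, 2, stats::median),
                 std_dev = apply(cands, 2, stats::sd),
                 maximum = apply(cands, 2, max),
                 minimum = apply(cands, 2, min))
  colnames(stats) <- c("e0", "e1", "e2", "e3")
  if (!is.null(reference)) {
    stats <- rbind(gold_standard = quat_canonicalize(quat_normalize(reference)),
                   stats)
  }
  structure(stats, n_candidates = nrow(cands))
}

#' Procedural texture for synthetic scenes
#'
#' Smooth, seeded sum of sinusoids over plane coordinates, rescaled to
#' `[0, 1]`; continuous so that warped resamplings stay highly correlated.
#'
#' @param seed RNG seed.
#' @param n_waves number of sinusoidal components.
#' @return function `(x, y) -> intensity`.
#' @export
make_texture <- function(seed = 1, n_waves = 6) {
  set.seed(seed)
  fr <- matrix(stats::runif(2 * n_waves, 0.5, 3), ncol = 2)
  ph <- stats::runif(n_waves, 0, 2 * pi)
  am <- stats::runif(n_waves, 0.5, 1)
  function(x, y) {
    v <- 0
    for (k in seq_len(n_waves)) {
      v <- v + am[k] * sin(fr[k, 1] * x + fr[k, 2] * y + ph[k])
    }
    (v / sum(am) + 1) / 2
  }
}

#' Generate a synthetic two-camera scene with exact ground truth
#'
#' Two verged pinhole cameras observe a textured fronto-parallel plane.
#' The world frame is camera 1's map frame; camera 2's map frame is
#' related to it by a seeded ground-truth similarity transform. Images are
#' rendered by exact inverse mapping (ray / scene-plane intersection), and
#' the emitted correspondences are scene points expressed in both map
#' frames, optionally with pixel noise-free projections into both images.
#'
#' The recommended projection distance `Z` (also returned) places the
#' bisecting projection plane exactly on the scene plane, so that
#' compositing with ground-truth poses reproduces the scene consistently
#' from both cameras.
#'
#' @param seed RNG seed.
#' @param n_points number of correspondences to emit.
#' @param vergence_deg full vergence angle between the optical axes.
#' @param baseline distance between the camera centres.
#' @param depth scene-plane depth (world z).
#' @param K shared [camera_intrinsics()]; default 160 x 120 at fx = 120.
#' @param img_size deprecated alias, ignored when `K` is given.
#' @return list: `img1`, `img2` (grayscale matrices), `pose1`, `pose2`,
#'   `K`, `correspondences` (a [correspondence_set()]), `pixels1`,
#'   `pixels2` (exact projections), `gt_transform`, `scene_plane`,
#'   `Z_recommended`, `texture`.
#' @export
generate_two_camera_scene <- function(seed = 1, n_points = 30,
                                      vergence_deg = 30, baseline = 1,
                                      depth = 3, K = NULL,
                                      img_size = c(160, 120)) {
  if (is.null(K)) {
    K <- camera_intrinsics(fx = img_size[1] * 0.75, width = img_size[1],
                           height = img_size[2])
  }
  beta <- vergence_deg / 2 * pi / 180
  c1 <- c(-baseline / 2, 0, 0)
  c2 <- c(baseline / 2, 0, 0)
  # verged inward: left camera tilted toward +x, right toward -x
  pose1 <- camera_pose(c1, rpy_to_rotmat(0, beta, 0))
  pose2 <- camera_pose(c2, rpy_to_rotmat(0, -beta, 0))
  tex <- make_texture(seed)
  scene_plane <- plane3d(c(0, 0, 1), depth)
  render_cam <- function(pose) {
    W <- K$width; H <- K$height
    uu <- rep(0:(W - 1), each = H)
    vv <- rep(0:(H - 1), times = W)
    D <- pose$rotation %*% rbind((uu - K$cx) / K$fx, (vv - K$cy) / K$fy, 1)
    tpar <- (depth - pose$center[3]) / D[3, ]
    X <- pose$center + D * rep(tpar, each = 3)
    matrix(tex(X[1, ], X[2, ]), nrow = H, ncol = W)
  }
  img1 <- render_cam(pose1)
  img2 <- render_cam(pose2)
  set.seed(seed + 1)
  # scene points in the central region seen by both cameras
  half_x <- 0.3 * depth * tan(K$theta_x / 2)
  half_y <- 0.6 * depth * tan(K$theta_y / 2)
  pts <- cbind(stats::runif(n_points, -half_x, half_x),
               stats::runif(n_points, -half_y, half_y),
               depth)
  # ground-truth similarity linking camera 2's map frame to the world
  ang <- stats::runif(3, -pi / 4, pi / 4)
  gt <- similarity_transform(rpy_to_rotmat(ang[1], ang[2], ang[3]),
                             stats::runif(1, 0.5, 2),
                             stats::runif(3, -2, 2))
  qpts <- apply_transform(gt, pts)
  project <- function(pose, X) {
    Xc <- t(pose$rotation) %*% (t(X) - pose$center)
    cbind(K$fx * Xc[1, ] / Xc[3, ] + K$cx, K$fy * Xc[2, ] / Xc[3, ] + K$cy)
  }
  list(img1 = img1, img2 = img2, pose1 = pose1, pose2 = pose2, K = K,
       correspondences = correspondence_set(pts, qpts),
       pixels1 = project(pose1, pts), pixels2 = project(pose2, pts),
       gt_transform = gt, scene_plane = scene_plane,
       Z_recommended = depth * cos(beta) + (baseline / 2) * sin(beta),
       texture = tex)
}
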