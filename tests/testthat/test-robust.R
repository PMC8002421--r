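test_that("noise-free clouds make every correspondence an inlier", {
  set.seed(31)
  tr <- random_transform()
  p <- random_cloud(10)
  corr <- correspondence_set(p, apply_transform(tr, p))
  est <- estimate_pose_ransac(corr)
  expect_equal(est$inlier_count, 10)
  expect_lt(quat_angle(est$transform$quaternion, tr$quaternion), 1e-8)
  expect_equal(est$transform$s, tr$s, tolerance = 1e-9)
})

test_that("a gross outlier is excluded by the inlier-maximizing search", {
  set.seed(32)
  tr <- random_transform()
  p <- random_cloud(10)
  q <- apply_transform(tr, p)
  q[10, ] <- q[10, ] + c(80, -90, 70)  # 10x the scene scale
  est <- estimate_pose_ransac(correspondence_set(p, q))
  expect_equal(est$inlier_count, 9)
  expect_false(est$inlier_mask[10])
  expect_lt(quat_angle(est$transform$quaternion, tr$quaternion), 1e-8)
  expect_equal(est$transform$s, tr$s, tolerance = 1e-8)
  expect_equal(est$transform$t, tr$t, tolerance = 1e-6)
})

test_that("the search is invariant to correspondence order", {
  set.seed(33)
  tr <- random_transform()
  p <- random_cloud(8)
  q <- apply_transform(tr, p) + matrix(stats::rnorm(24, sd = 0.05), ncol = 3)
  th <- default_inlier_threshold(correspondence_set(p, q))
  est1 <- estimate_pose_ransac(correspondence_set(p, q), threshold = th)
  perm <- sample(8)
  est2 <- estimate_pose_ransac(correspondence_set(p[perm, ], q[perm, ]),
                               threshold = th)
  expect_equal(est1$inlier_count, est2$inlier_count)
  expect_lt(quat_angle(est1$transform$quaternion,
                       est2$transform$quaternion), 1e-6)
})

test_that("identical filter candidates are all kept and averaged", {
  q <- quat_normalize(c(0.8, 0.1, -0.3, 0.2))
  cands <- matrix(rep(q, 10), ncol = 4, byrow = TRUE)
  f <- quaternion_filter(cands, d = 2)
  expect_true(all(f$kept))
  expect_equal(f$representative, quat_canonicalize(q), tolerance = 1e-12)
})

test_that("larger d keeps a subset of the candidates kept at smaller d", {
  set.seed(34)
  for (k in 1:25) {
    n <- sample(5:150, 1)
    base <- quat_normalize(stats::rnorm(4))
    cands <- t(vapply(seq_len(n), function(i) {
      quat_canonicalize(quat_normalize(base + stats::rnorm(4, sd = 0.1)))
    }, numeric(4)))
    k2 <- quaternion_filter(cands, d = 2)$kept
    k4 <- quaternion_filter(cands, d = 4)$kept
    expect_true(all(which(k4) %in% which(k2)))
  }
})

test_that("a planted far outlier is removed and the mean improves", {
  set.seed(35)
  target <- quat_canonicalize(quat_normalize(c(0.7, 0.3, -0.5, 0.4)))
  cluster <- t(vapply(1:119, function(i) {
    quat_canonicalize(quat_normalize(target + stats::rnorm(4, sd = 0.02)))
  }, numeric(4)))
  outlier <- quat_canonicalize(quat_normalize(c(0.1, -0.9, 0.4, 0.1)))
  cands <- rbind(cluster, outlier)
  f <- quaternion_filter(cands, d = 2)
  expect_false(f$kept[120])
  naive_mean <- quat_canonicalize(quat_normalize(colMeans(cands)))
  expect_lt(quat_angle(f$representative, target),
            quat_angle(naive_mean, target))
})

test_that("the filtered estimator reduces to the closed form at zero noise", {
  set.seed(36)
  tr <- random_transform()
  p <- random_cloud(10)
  corr <- correspondence_set(p, apply_transform(tr, p))
  est <- estimate_pose_filtered(corr, d = 2)
  expect_equal(nrow(est$filter$candidates), 120)  # C(10, 3)
  plain <- fit_similarity(corr)
  expect_lt(quat_angle(est$transform$quaternion, plain$quaternion), 1e-8)
  expect_equal(est$transform$s, plain$s, tolerance = 1e-8)
  expect_equal(est$transform$t, plain$t, tolerance = 1e-6)
  expect_lt(quat_angle(est$transform$quaternion, tr$quaternion), 1e-8)
})

test_that("filtering beats the best triple over repeated noisy trials", {
  rep <- run_campaign(n_trials = 40, seed = 99, methods = c("algo1", "algo2"),
                      d_values = 2)
  a <- subset(rep$results, method == "algo2_d2")
  b <- subset(rep$results, method == "algo1")
  expect_lt(mean(a$mse), mean(b$mse))
})

test_that("the planted key-frame pair is selected with its inliers", {
  tr <- similarity_transform(rpy_to_rotmat(0.3, -0.2, 0.5), 1.4, c(1, -2, 3))
  kf <- make_keyframe_pair(tr, n_shared = 25, n_outliers = 3, seed = 41)
  sel <- select_optimal_keyframe_pair(list(kf$f1), list(kf$f2),
                                      min_corr = 20, min_inliers = 20)
  expect_equal(sel$pair, c(1, 1))
  expect_equal(sel$estimate$inlier_count, 22)
  expect_lt(quat_angle(sel$estimate$transform$quaternion, tr$quaternion), 1e-6)
})

test_that("pairs below the correspondence threshold give no pair", {
  tr <- similarity_transform(diag(3), 1, c(0, 0, 0))
  kf <- make_keyframe_pair(tr, n_shared = 10, seed = 42)
  expect_null(select_optimal_keyframe_pair(list(kf$f1), list(kf$f2),
                                           min_corr = 20, min_inliers = 20))
  # matcher finding nothing anywhere is also a no-pair signal
  null_matcher <- function(a, b) data.frame(i1 = integer(), i2 = integer())
  expect_null(select_optimal_keyframe_pair(list(kf$f1), list(kf$f2),
                                           matcher = null_matcher))
  expect_error(select_optimal_keyframe_pair(list(), list(kf$f2)), "empty")
})

test_that("clicks snap to the nearest feature holding a map point", {
  fp <- rbind(c(100, 100), c(200, 100), c(150, 300))
  mp <- rbind(c(1, 2, 3), c(4, 5, 6), NA)
  f <- keyframe("f", fp, mp)
  hit <- snap_clicks_to_features(rbind(c(100, 100)), f, radius = 20)
  expect_equal(hit$feature, 1L)
  expect_equal(unlist(hit[1, c("x", "y", "z")], use.names = FALSE), c(1, 2, 3))
  # equidistant between features 1 and 2: lower index wins
  tie <- snap_clicks_to_features(rbind(c(150, 100)), f, radius = 60)
  expect_equal(tie$feature, 1L)
  # feature 3 is nearest to this click but has no map point
  far <- snap_clicks_to_features(rbind(c(150, 260)), f, radius = 200)
  expect_true(far$feature %in% c(1L, 2L))
  expect_error(snap_clicks_to_features(rbind(c(500, 500)), f, radius = 20),
               "click")
})
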