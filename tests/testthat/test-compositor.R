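scene <- generate_two_camera_scene(seed = 71)

test_that("coincident cameras make camera 2 cover camera 1 exactly", {
  set.seed(72)
  img1 <- matrix(stats::runif(120 * 160), 120)
  img2 <- matrix(stats::runif(120 * 160), 120)
  K <- camera_intrinsics(fx = 120, width = 160, height = 120)
  pose <- camera_pose(c(0, 0, 0), diag(3))
  v <- render_expanded_view(img1, img2, pose, pose, K, K, method = "naive",
                            Z = 1, out_size = c(160, 120),
                            interpolation = "nearest")
  covered <- v$provenance > 0
  expect_true(all(v$provenance[covered] == 3))  # identical footprints
  # painter's order: camera 2 drawn last owns every covered pixel
  expect_equal(v$canvas[covered], v$layers$cam2$canvas[covered])
  expect_identical(v$layers$cam1$mask, v$layers$cam2$mask)
})

test_that("planar footprint corners match an analytic per-corner mapping", {
  s <- scene
  Z <- s$Z_recommended
  view <- render_expanded_view(s$img1, s$img2, s$pose1, s$pose2, s$K, s$K,
                               method = "planar", Z = Z,
                               out_size = c(200, 150))
  # oracle computed inline from first principles, per corner:
  # camera-1 image corner -> point on the camera-1 projection plane ->
  # central projection from C1 onto the bisecting plane -> pinhole
  # projection into the virtual viewpoint
  K <- s$K
  corners_px <- rbind(c(-0.5, -0.5), c(K$width - 0.5, -0.5),
                      c(K$width - 0.5, K$height - 0.5),
                      c(-0.5, K$height - 0.5))
  a1 <- s$pose1$rotation[, 3]; a2 <- s$pose2$rotation[, 3]
  h1 <- sum(a1 * (s$pose1$center + Z * a1))
  h2 <- sum(a2 * (s$pose2$center + Z * a2))
  # bisecting plane through the plane-plane intersection line
  k12 <- sum(a1 * a2)
  c1 <- (h1 - h2 * k12) / (1 - k12^2)
  c2 <- (h2 - h1 * k12) / (1 - k12^2)
  X0 <- c1 * a1 + c2 * a2
  nb <- (a1 + a2) / sqrt(sum((a1 + a2)^2))
  hb <- sum(nb * X0)
  vp <- view$viewpoint; oK <- view$out_K
  expected <- t(apply(corners_px, 1, function(px) {
    dir_cam <- c((px[1] - K$cx) / K$fx, (px[2] - K$cy) / K$fy, 1)
    m <- s$pose1$rotation %*% dir_cam
    X <- s$pose1$center + as.numeric((hb - sum(nb * s$pose1$center)) /
                                       sum(nb * m)) * m
    Xc <- t(vp$rotation) %*% (X - vp$center)
    c(oK$fx * Xc[1] / Xc[3] + oK$cx, oK$fy * Xc[2] / Xc[3] + oK$cy)
  }))
  got <- footprint_polygon(view$surfaces[[1]]$poly, vp, oK)
  expect_equal(got, expected, tolerance = 1e-6)  # sub-pixel agreement
})

test_that("overlap removal leaves no doubly-owned pixel", {
  s <- scene
  for (side in c(1, 2)) {
    v <- render_expanded_view(s$img1, s$img2, s$pose1, s$pose2, s$K, s$K,
                              method = "overlap", Z = s$Z_recommended,
                              out_size = c(200, 150), crop_side = side)
    expect_false(any(v$provenance == 3))
    expect_gt(sum(v$provenance == 1), 0)
    expect_gt(sum(v$provenance == 2), 0)
  }
})

test_that("ground-truth warps of the two cameras agree where they overlap", {
  s <- scene
  v <- render_expanded_view(s$img1, s$img2, s$pose1, s$pose2, s$K, s$K,
                            method = "planar", Z = s$Z_recommended,
                            out_size = c(200, 150))
  both <- v$layers$cam1$mask & v$layers$cam2$mask
  expect_gt(sum(both), 500)
  expect_gt(zncc(matrix(v$layers$cam1$canvas[both], ncol = 1),
                 matrix(v$layers$cam2$canvas[both], ncol = 1)), 0.99)
})

test_that("planar and cylindrical renderings converge as the vergence vanishes", {
  s2 <- generate_two_camera_scene(seed = 73, vergence_deg = 2)
  args <- list(s2$img1, s2$img2, s2$pose1, s2$pose2, s2$K, s2$K,
               Z = s2$Z_recommended, out_size = c(160, 120),
               theta_cylinder = 20, n_strips = 64)
  vp <- do.call(render_expanded_view, c(args, method = "planar"))
  vc <- do.call(render_expanded_view, c(args, method = "cylinder"))
  both <- vp$provenance > 0 & vc$provenance > 0
  expect_gt(sum(both), 2000)
  expect_lt(mean(abs(vp$canvas[both] - vc$canvas[both])), 0.02)
})

test_that("footprints project as expected", {
  K <- camera_intrinsics(fx = 100, width = 100, height = 80)
  pose <- camera_pose()
  quad <- image_plane_quad(K, pose, Z = 2)
  fp <- footprint_polygon(quad[1:4, ], pose, K)
  # fronto-parallel: axis-aligned rectangle covering the full image
  expect_equal(fp[, 1], c(-0.5, 99.5, 99.5, -0.5), tolerance = 1e-9)
  expect_equal(fp[, 2], c(-0.5, -0.5, 79.5, 79.5), tolerance = 1e-9)
  # a clipped pentagon keeps its five vertices under projection
  pent <- clip_quad_by_line(quad[1:4, ], line3d(quad[1, ] + c(0.3, 0, 0),
                                                c(1, 0.5, 0)),
                            keep_point = colMeans(quad[1:4, ]))
  expect_equal(nrow(pent), 5)
  expect_equal(nrow(footprint_polygon(pent, pose, K)), 5)
  # projected area shrinks monotonically as the quad tilts away
  areas <- sapply(c(0, 20, 40, 60), function(tilt) {
    R <- rpy_to_rotmat(0, tilt * pi / 180, 0)
    q <- t(R %*% t(sweep(quad[1:4, ], 2, c(0, 0, 2))))
    polygon_area(footprint_polygon(sweep(q, 2, c(0, 0, 2), "+"), pose, K))
  })
  expect_true(all(diff(areas) < 0))
  # vertex behind the viewpoint is a degenerate mapping
  expect_error(footprint_polygon(rbind(c(0, 0, -1), c(1, 0, -1), c(0, 1, -1)),
                                 pose, K), "degenerate")
})

test_that("a surface fully behind the viewpoint raises a degenerate view", {
  img <- matrix(0.5, 60, 80)
  K <- camera_intrinsics(fx = 80, width = 80, height = 60)
  fwd <- camera_pose()
  back <- camera_pose(c(0, 0, 5), diag(3))  # planes at z=1 behind this viewpoint
  expect_error(render_expanded_view(img, img, fwd, fwd, K, K,
                                    method = "naive", Z = 1, viewpoint = back,
                                    out_size = c(80, 60)),
               "degenerate view")
})
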