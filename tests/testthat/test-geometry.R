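random_plane <- function() plane3d(stats::rnorm(3), stats::runif(1, -3, 3))

test_that("projected image size follows the pinhole model", {
  K <- camera_intrinsics(fx = 500, fy = 400, width = 640, height = 480)
  pose <- camera_pose()
  q1 <- image_plane_quad(K, pose, Z = 500)
  expect_equal(attr(q1, "width"), 640)   # Z equal to fx
  q2 <- image_plane_quad(K, pose, Z = 1000)
  expect_equal(attr(q2, "width"), 1280)  # Z * Wim / fx
  expect_equal(attr(q2, "width") / attr(q1, "width"), 2)
  expect_equal(attr(q2, "height") / attr(q1, "height"), 2)
  # quad is perpendicular to the optical axis at distance Z
  pl <- attr(q2, "plane")
  expect_equal(pl$n, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(pl$h, 1000, tolerance = 1e-12)
  expect_error(image_plane_quad(K, pose, Z = -1))
})

test_that("plane intersection lines satisfy both plane equations", {
  lx <- plane_intersection_line(plane3d(c(0, 0, 1), 0), plane3d(c(0, 1, 0), 0))
  expect_equal(abs(lx$direction), c(1, 0, 0))
  expect_equal(lx$point, c(0, 0, 0), tolerance = 1e-12)
  expect_error(plane_intersection_line(plane3d(c(0, 0, 1), 0),
                                       plane3d(c(0, 0, 1), 1)), "parallel")
  set.seed(51)
  for (k in 1:100) {
    P1 <- random_plane(); P2 <- random_plane()
    if (abs(sum(P1$n * P2$n)) >= 1 - 1e-6) next
    l <- plane_intersection_line(P1, P2)
    for (tau in c(-2, 0, 3)) {
      X <- l$point + tau * l$direction
      expect_equal(sum(P1$n * X), P1$h, tolerance = 1e-9)
      expect_equal(sum(P2$n * X), P2$h, tolerance = 1e-9)
    }
  }
})

test_that("plane angles come from the normals", {
  expect_equal(angle_between_planes(plane3d(c(0, 0, 1), 0),
                                    plane3d(c(0, 1, 0), 2)), 90)
  expect_equal(angle_between_planes(plane3d(c(0, 0, 1), 1),
                                    plane3d(c(0, 0, 1), 5)), 0)
  n2 <- c(sin(pi / 3), 0, cos(pi / 3))  # 60 degrees from +z by construction
  expect_equal(angle_between_planes(plane3d(c(0, 0, 1), 0), plane3d(n2, 0)),
               60, tolerance = 1e-12)
})

test_that("the bisecting plane halves the inter-plane angle", {
  b <- bisecting_plane(plane3d(c(0, 0, 1), 0), plane3d(c(1, 0, 0), 0))
  expect_equal(b$n, c(1, 0, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(b$h, 0, tolerance = 1e-12)
  # coincident planes are their own bisector
  same <- plane3d(c(0, 1, 0), 2)
  expect_equal(bisecting_plane(same, same)$n, same$n)
  set.seed(52)
  for (k in 1:200) {
    P1 <- random_plane(); P2 <- random_plane()
    k12 <- sum(P1$n * P2$n)
    if (abs(k12) >= 1 - 1e-6) next
    B <- bisecting_plane(P1, P2)
    th <- angle_between_planes(P1, P2)
    expect_equal(angle_between_planes(B, P1), th / 2, tolerance = 1e-9)
    expect_equal(angle_between_planes(B, P2), th / 2, tolerance = 1e-9)
    # contains the intersection line
    l <- plane_intersection_line(P1, P2)
    expect_equal(sum(B$n * l$point), B$h, tolerance = 1e-9)
    expect_lt(abs(sum(B$n * l$direction)), 1e-9)
    # sign convention: normal aligned with n1 + n2
    expect_gt(sum(B$n * (P1$n + P2$n)), 0)
  }
})

test_that("line-plane intersections satisfy the plane equation", {
  X <- line_plane_intersection(line3d(c(0, 0, 0), c(0, 0, 1)),
                               plane3d(c(0, 0, 1), 5))
  expect_equal(X, c(0, 0, 5))
  expect_error(line_plane_intersection(line3d(c(0, 0, 0), c(1, 0, 0)),
                                       plane3d(c(0, 0, 1), 5)), "parallel")
  set.seed(53)
  for (k in 1:100) {
    l <- line3d(stats::rnorm(3), stats::rnorm(3))
    P <- random_plane()
    if (abs(sum(P$n * l$direction)) < 1e-6) next
    X <- line_plane_intersection(l, P)
    expect_equal(sum(P$n * X), P$h, tolerance = 1e-9)
    # point lies on the line
    d <- X - l$point
    expect_lt(sqrt(sum(cross3(d, l$direction)^2)), 1e-8 * (1 + sqrt(sum(d^2))))
  }
})

unit_quad <- rbind(c(0, 0, 0), c(4, 0, 0), c(4, 3, 0), c(0, 3, 0))

test_that("clipping a quad yields the expected shape classes", {
  # line missing the quad: unchanged
  miss <- clip_quad_by_line(unit_quad, line3d(c(10, 0, 0), c(0, 1, 0)),
                            keep_point = c(0, 0, 0))
  expect_equal(nrow(miss), 4)
  expect_equal(miss, unit_quad)
  # line parallel to a side crossing the quad: trapezoid (4 vertices)
  trap <- clip_quad_by_line(unit_quad, line3d(c(2, 0, 0), c(0, 1, 0)),
                            keep_point = c(0, 1, 0))
  expect_equal(nrow(trap), 4)
  # diagonal line crossing two adjacent sides (bottom and right): pentagon
  pent <- clip_quad_by_line(unit_quad, line3d(c(3.5, 0, 0), c(1, 1, 0)),
                            keep_point = c(0, 1, 0))
  expect_equal(nrow(pent), 5)
  # keeping only the cut-off corner instead: triangle
  tri <- clip_quad_by_line(unit_quad, line3d(c(3.5, 0, 0), c(1, 1, 0)),
                           keep_point = c(3.9, 0.05, 0))
  expect_equal(nrow(tri), 3)
})

test_that("clipping over a grid of lines never exceeds five vertices", {
  area0 <- polygon_area(unit_quad[, 1:2])
  for (x0 in seq(-1, 5, by = 0.5)) {
    for (ang in seq(0, pi * 0.9, by = pi / 7)) {
      l <- line3d(c(x0, 1.5, 0), c(cos(ang), sin(ang), 0))
      for (kp in list(c(-5, 1.5, 0), c(9, 1.5, 0))) {
        cl <- clip_quad_by_line(unit_quad, l, keep_point = kp)
        expect_true(nrow(cl) %in% c(0, 3, 4, 5))
        if (nrow(cl) >= 3) {
          expect_lte(polygon_area(cl[, 1:2]), area0 + 1e-9)
        }
      }
    }
  }
})

test_that("the cylinder radius matches its arc length", {
  pb <- plane3d(c(0, 0, 1), 2)
  ml <- line3d(c(0, 0, 2), c(0, 1, 0))
  full <- cylinder_from_planes(pb, ml, WT = 10, theta_cylinder = 360)
  expect_equal(full$radius, 10 / (2 * pi))
  half <- cylinder_from_planes(pb, ml, WT = 10, theta_cylinder = 180)
  expect_equal(half$radius, 10 / pi)
  for (th in c(60, 120, 270)) {
    cyl <- cylinder_from_planes(pb, ml, WT = 7, theta_cylinder = th)
    expect_equal(cyl$radius * th * pi / 180, 7, tolerance = 1e-9)
    # tangency: axis sits one radius away from the plane
    expect_equal(abs(sum(pb$n * cyl$axis$point) - pb$h), cyl$radius,
                 tolerance = 1e-12)
    expect_equal(cyl$axis$direction, ml$direction)
  }
})

test_that("strip decomposition partitions the arc and flattens with n", {
  pb <- plane3d(c(0, 0, 1), 2)
  ml <- line3d(c(0, 0, 2), c(0, 1, 0))
  cyl <- cylinder_from_planes(pb, ml, WT = 6, theta_cylinder = 120)
  quad <- rbind(c(0, 0, 0), c(6, 0, 0), c(6, 4, 0), c(0, 4, 0))
  one <- strip_decomposition(quad, cyl, n_strips = 1)
  expect_length(one, 1)
  sag_prev <- Inf
  for (n in c(1, 2, 4, 8, 32)) {
    strips <- strip_decomposition(quad, cyl, n_strips = n)
    expect_length(strips, n)
    br <- attr(strips, "arc_angles")
    expect_equal((max(br) - min(br)) * cyl$radius, 6, tolerance = 1e-9)
    sag <- attr(strips, "sagitta")
    expect_equal(sag, cyl$radius * (1 - cos((br[2] - br[1]) / 2)))
    expect_lte(sag, sag_prev)
    sag_prev <- sag
    # every strip vertex lies on the cylinder surface
    for (s in strips) {
      for (i in 1:4) {
        d <- s[i, ] - cyl$axis$point
        d <- d - sum(d * cyl$axis$direction) * cyl$axis$direction
        expect_equal(sqrt(sum(d^2)), cyl$radius, tolerance = 1e-9)
      }
    }
  }
})
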