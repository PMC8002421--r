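#' Projection geometry for expanded-view presentation
#'
#' Geometry for the three presentation methods: each camera image is mapped
#' onto a projection plane perpendicular to its optical axis at distance Z
#' from the principal point; expanded views are built either on the two
#' planes directly (with the overlap region clipped away on one side), on a
#' single plane bisecting the angle between them, or on a polygonal
#' approximation of a cylinder tangent to that bisecting plane.
#'
#' Conventions: right-handed world frame; a camera looks along the +z axis
#' of its own frame, image x to the right, image y down; pixel origin at
#' the top-left with integer pixel centres.
#'
#' @name view_geometry
NULL

#' Pinhole camera intrinsics
#'
#' @param fx,fy focal lengths in pixels.
#' @param width,height image size in pixels.
#' @param cx,cy principal point in pixel coordinates; defaults to the image
#'   centre under the integer-pixel-centre convention.
#' @return object of class `camera_intrinsics` with derived view angles
#'   `theta_x`, `theta_y` (radians).
#' @export
camera_intrinsics <- function(fx, fy = fx, width, height,
                              cx = (width - 1) / 2, cy = (height - 1) / 2) {
  stopifnot(fx > 0, fy > 0, width > 0, height > 0)
  structure(list(fx = fx, fy = fy, width = width, height = height,
                 cx = cx, cy = cy,
                 theta_x = 2 * atan(width / (2 * fx)),
                 theta_y = 2 * atan(height / (2 * fy))),
            class = "camera_intrinsics")
}

#' Camera pose in the world frame
#'
#' @param center length-3 camera centre (principal point position).
#' @param rotation 3x3 camera-to-world rotation; columns are the camera's
#'   x (image right), y (image down) and z (optical axis) directions
#'   expressed in world coordinates.
#' @return object of class `camera_pose`.
#' @export
camera_pose <- function(center = c(0, 0, 0), rotation = diag(3)) {
  .assert_rotation(rotation)
  structure(list(center = as.numeric(center), rotation = unname(rotation)),
            class = "camera_pose")
}

#' Camera pose looking at a target point
#'
#' @param center camera centre.
#' @param target point the optical axis passes through.
#' @param up approximate world "up"; image y (down) is its negation
#'   projected perpendicular to the axis.
#' @return a [camera_pose()].
#' @export
look_at_pose <- function(center, target, up = c(0, -1, 0)) {
  z <- target - center
  nz <- sqrt(sum(z^2))
  if (nz < 1e-12) stop("target coincides with the camera centre")
  z <- z / nz
  x <- cross3(-up, z)
  nx <- sqrt(sum(x^2))
  if (nx < 1e-12) stop("up direction is parallel to the viewing axis")
  x <- x / nx
  y <- cross3(z, x)
  camera_pose(center, cbind(x, y, z))
}

#' Planes in Hessian normal form
#'
#' A plane is the point set `n . x = h`, with `n` a unit normal and `h`
#' the signed distance from the origin. Non-unit normals are normalized on
#' construction (and `h` rescaled accordingly).
#'
#' @param n length-3 normal vector.
#' @param h signed offset such that `n . x = h`.
#' @return object of class `plane3d`.
#' @export
plane3d <- function(n, h) {
  stopifnot(is.numeric(n), length(n) == 3, is.numeric(h), length(h) == 1)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-12) stop("plane normal must be nonzero")
  structure(list(n = n / nn, h = h / nn), class = "plane3d")
}

#' @rdname plane3d
#' @param point a point on the plane (alternative construction).
#' @export
plane_from_point_normal <- function(point, n) {
  pl <- plane3d(n, 0)
  plane3d(pl$n, sum(pl$n * point))
}

#' Lines in 3D in point-direction form
#'
#' @param point length-3 point on the line.
#' @param direction length-3 direction; normalized on construction.
#' @return object of class `line3d`.
#' @export
line3d <- function(point, direction) {
  stopifnot(length(point) == 3, length(direction) == 3)
  nd <- sqrt(sum(direction^2))
  if (nd < 1e-12) stop("line direction must be nonzero")
  structure(list(point = as.numeric(point), direction = direction / nd),
            class = "line3d")
}

#' Projection-plane quad of a camera image
#'
#' The camera image projected at distance `Z` along the optical axis spans
#' `W' = Z * width / fx` by `H' = Z * height / fy` scene units, centred on
#' the axis and perpendicular to it.
#'
#' @param K a [camera_intrinsics()].
#' @param pose a [camera_pose()].
#' @param Z projection distance (> 0) in scene units.
#' @return 4 x 3 matrix of vertices in order top-left, top-right,
#'   bottom-right, bottom-left (image orientation), with attributes
#'   `width`, `height`, `plane` (the supporting [plane3d()]) and `camera`.
#' @export
image_plane_quad <- function(K, pose, Z) {
  stopifnot(inherits(K, "camera_intrinsics"), inherits(pose, "camera_pose"),
            Z > 0)
  Wp <- Z * K$width / K$fx
  Hp <- Z * K$height / K$fy
  right <- pose$rotation[, 1]
  down <- pose$rotation[, 2]
  axis <- pose$rotation[, 3]
  ctr <- pose$center + Z * axis
  v <- rbind(ctr - (Wp / 2) * right - (Hp / 2) * down,
             ctr + (Wp / 2) * right - (Hp / 2) * down,
             ctr + (Wp / 2) * right + (Hp / 2) * down,
             ctr - (Wp / 2) * right + (Hp / 2) * down)
  structure(v, width = Wp, height = Hp,
            plane = plane_from_point_normal(ctr, axis),
            camera = pose)
}

#' Intersection line of two planes
#'
#' Closed form in the two normals: `X0 = c1 n1 + c2 n2` with
#' `c1 = (h1 - h2 k) / (1 - k^2)`, `c2 = (h2 - h1 k) / (1 - k^2)`,
#' `k = n1 . n2`, and direction `n1 x n2`.
#'
#' @param P1,P2 [plane3d()] objects; must not be parallel.
#' @return a [line3d()] whose point satisfies both plane equations.
#' @export
plane_intersection_line <- function(P1, P2) {
  stopifnot(inherits(P1, "plane3d"), inherits(P2, "plane3d"))
  k <- sum(P1$n * P2$n)
  if (abs(k) >= 1 - 1e-9) stop("planes are parallel: no unique intersection line")
  c1 <- (P1$h - P2$h * k) / (1 - k^2)
  c2 <- (P2$h - P1$h * k) / (1 - k^2)
  line3d(c1 * P1$n + c2 * P2$n, cross3(P1$n, P2$n))
}

#' Angle between two planes, in degrees
#'
#' `theta = arccos(n1 . n2 / (|n1| |n2|))`, in `[0, 180]`.
#'
#' @param P1,P2 [plane3d()] objects.
#' @return angle in degrees.
#' @export
angle_between_planes <- function(P1, P2) {
  stopifnot(inherits(P1, "plane3d"), inherits(P2, "plane3d"))
  d <- sum(P1$n * P2$n)
  acos(max(-1, min(1, d))) * 180 / pi
}

#' Plane bisecting the angle between two planes
#'
#' Contains the intersection line of the two planes and makes an angle of
#' half the inter-plane angle with each. Of the two bisectors, the one
#' whose normal aligns with `n1 + n2` (facing the same side as both input
#' normals) is returned. Coincident planes are returned unchanged.
#'
#' @param P1,P2 [plane3d()] objects.
#' @return a [plane3d()].
#' @export
bisecting_plane <- function(P1, P2) {
  stopifnot(inherits(P1, "plane3d"), inherits(P2, "plane3d"))
  k <- sum(P1$n * P2$n)
  if (k >= 1 - 1e-12 && abs(P1$h - P2$h) < 1e-9) return(P1)
  l <- plane_intersection_line(P1, P2)
  nb <- P1$n + P2$n
  if (sqrt(sum(nb^2)) < 1e-9) stop("planes are anti-parallel: bisector undefined")
  plane_from_point_normal(l$point, nb)
}

#' Intersection of a line and a plane
#'
#' `Xin = X0 + ((h - n . X0) / (n . m)) m`.
#'
#' @param line a [line3d()] (point `X0`, direction `m`).
#' @param plane a [plane3d()] (normal `n`, offset `h`).
#' @return length-3 intersection point.
#' @export
line_plane_intersection <- function(line, plane) {
  stopifnot(inherits(line, "line3d"), inherits(plane, "plane3d"))
  nm <- sum(plane$n * line$direction)
  if (abs(nm) < 1e-12) stop("line is parallel to the plane")
  line$point + ((plane$h - sum(plane$n * line$point)) / nm) * line$direction
}

#' Clip a convex quad by a line
#'
#' The line is first projected into the quad's supporting plane; the quad
#' is then clipped to the half-plane on the side of `keep_point` (or, by
#' default, the negative side of the in-plane normal `n x m`). For a
#' convex quad and a single line, the generic outcomes are the original
#' quad (line misses it), a trapezoid (4 vertices, line crossing two
#' opposite sides), a pentagon (5 vertices, line crossing two adjacent
#' sides) or a triangle.
#'
#' @param quad 4 x 3 vertex matrix (a convex planar quad, e.g. from
#'   [image_plane_quad()]).
#' @param line a [line3d()].
#' @param keep_point optional 3D point marking the half-plane to keep.
#' @return m x 3 vertex matrix, `m` in 0, 3, 4 or 5.
#' @export
clip_quad_by_line <- function(quad, line, keep_point = NULL) {
  quad <- unname(as.matrix(quad))
  stopifnot(nrow(quad) >= 3, ncol(quad) == 3, inherits(line, "line3d"))
  ctr <- colMeans(quad)
  e1 <- quad[2, ] - quad[1, ]
  e2 <- quad[3, ] - quad[1, ]
  n <- cross3(e1, e2)
  n <- n / sqrt(sum(n^2))
  # project the line into the quad plane
  m <- line$direction - sum(line$direction * n) * n
  if (sqrt(sum(m^2)) < 1e-12) stop("line is perpendicular to the quad plane")
  m <- m / sqrt(sum(m^2))
  X0 <- line$point - (sum(n * line$point) - sum(n * ctr)) * n
  w <- cross3(n, m)  # in-plane normal of the clip line
  side <- if (is.null(keep_point)) -1 else sign(sum(w * (keep_point - X0)))
  if (side == 0) side <- -1
  sgn <- function(X) side * sum(w * (X - X0))
  tol <- 1e-12 * max(1, max(abs(quad)))
  out <- list()
  nv <- nrow(quad)
  for (i in seq_len(nv)) {
    a <- quad[i, ]; b <- quad[if (i == nv) 1 else i + 1, ]
    sa <- sgn(a); sb <- sgn(b)
    if (sa >= -tol) out[[length(out) + 1]] <- a
    if ((sa > tol && sb < -tol) || (sa < -tol && sb > tol)) {
      t <- sa / (sa - sb)
      out[[length(out) + 1]] <- a + t * (b - a)
    }
  }
  if (length(out) == 0) return(matrix(numeric(0), ncol = 3))
  res <- do.call(rbind, out)
  # drop duplicate consecutive vertices produced by on-line corners
  keep <- rep(TRUE, nrow(res))
  for (i in seq_len(nrow(res))) {
    j <- if (i == nrow(res)) 1 else i + 1
    if (i != j && sqrt(sum((res[i, ] - res[j, ])^2)) < 1e-9) keep[j] <- FALSE
  }
  unname(res[keep, , drop = FALSE])
}

#' Approximate cylinder for cylindrical projection
#'
#' Defines a cylinder tangent to the bisecting projection plane along a
#' midline, with radius `r = WT * 360 / (2 pi theta_cylinder)` so that an
#' image of total width `WT` matches the arc length subtended by
#' `theta_cylinder` degrees. The axis is parallel to the inter-plane
#' intersection line and offset from the tangency midline by `r` along the
#' bisecting plane's normal.
#'
#' @param p_bisect bisecting [plane3d()] the cylinder touches.
#' @param midline [line3d()] in the bisecting plane (tangency line,
#'   parallel to the plane intersection line).
#' @param WT total projected width in scene units.
#' @param theta_cylinder projection angular range in degrees, in (0, 360].
#' @return object of class `cylinder_spec` with `radius`, `axis`
#'   (a [line3d()]), `theta_deg`, `WT`, and the radial reference direction
#'   `u0` pointing from the axis to the tangency line.
#' @export
cylinder_from_planes <- function(p_bisect, midline, WT, theta_cylinder = 120) {
  stopifnot(inherits(p_bisect, "plane3d"), inherits(midline, "line3d"),
            WT > 0, theta_cylinder > 0, theta_cylinder <= 360)
  r <- WT * 360 / (2 * pi * theta_cylinder)
  axis_point <- midline$point + r * p_bisect$n
  structure(list(radius = r, theta_deg = theta_cylinder, WT = WT,
                 axis = line3d(axis_point, midline$direction),
                 u0 = -p_bisect$n),
            class = "cylinder_spec")
}

#' Decompose an image quad into planar strips on the approximate cylinder
#'
#' The source quad's width is split into `n_strips` equal strips, each
#' mapped to a chord of the cylinder cross-section circle (a polygonal
#' cylinder with rectangular sides). Arc length equals the source width,
#' strips are centred on the tangency direction, and the chord sagitta
#' `r (1 - cos(dtheta / 2))` shrinks monotonically as `n_strips` grows.
#'
#' @param quad 4 x 3 source quad (top-left, top-right, bottom-right,
#'   bottom-left); its width sets the arc span, its height the strip
#'   height.
#' @param cyl a [cylinder_spec()].
#' @param n_strips number of strips (>= 1).
#' @return list of 4 x 3 strip quads (same vertex order); attributes
#'   `arc_angles` (breaks in radians) and `sagitta`.
#' @export
strip_decomposition <- function(quad, cyl, n_strips = 32) {
  stopifnot(inherits(cyl, "cylinder_spec"), n_strips >= 1)
  quad <- unname(as.matrix(quad))
  Wq <- sqrt(sum((quad[2, ] - quad[1, ])^2))
  Hq <- sqrt(sum((quad[4, ] - quad[1, ])^2))
  r <- cyl$radius
  span <- Wq / r                       # arc span in radians
  breaks <- seq(-span / 2, span / 2, length.out = n_strips + 1)
  u0 <- cyl$u0 / sqrt(sum(cyl$u0^2))
  m <- cyl$axis$direction
  v0 <- cross3(m, u0)
  A0 <- cyl$axis$point
  circ <- function(phi) A0 + r * (cos(phi) * u0 + sin(phi) * v0)
  half_h <- (Hq / 2) * m
  strips <- vector("list", n_strips)
  for (k in seq_len(n_strips)) {
    a <- circ(breaks[k]); b <- circ(breaks[k + 1])
    strips[[k]] <- rbind(a - half_h, b - half_h, b + half_h, a + half_h)
  }
  structure(strips, arc_angles = breaks,
            sagitta = r * (1 - cos((breaks[2] - breaks[1]) / 2)))
}
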