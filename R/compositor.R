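#' Offline expanded-view compositor
#'
#' Builds the expanded 2D view from two source images, their poses and
#' intrinsics, and a presentation method. Rendering is deterministic
#' software inverse mapping: every output pixel is back-projected from a
#' virtual viewpoint onto the method's projection surface(s), the surface
#' point is mapped into each source camera through the pinhole model, and
#' the source image is sampled bilinearly (or nearest-neighbour). Pixels
#' whose ray misses every surface, or whose surface point falls outside
#' the source footprints, stay blank (value 0) and are marked in the
#' provenance mask.
#'
#' @name compositor
NULL

.polygon_plane <- function(poly) {
  e1 <- poly[2, ] - poly[1, ]
  e2 <- poly[3, ] - poly[1, ]
  n <- cross3(e1, e2)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-12) stop("degenerate polygon")
  plane_from_point_normal(poly[1, ], n / nn)
}

# Vectorized convex-polygon containment for points X (3 x n) known to lie
# in the polygon's plane.
.inside_convex <- function(poly, X, tol = 1e-9) {
  pl <- .polygon_plane(poly)
  n <- pl$n
  ctr <- colMeans(poly)
  inside <- rep(TRUE, ncol(X))
  nv <- nrow(poly)
  for (i in seq_len(nv)) {
    a <- poly[i, ]; b <- poly[if (i == nv) 1 else i + 1, ]
    w <- cross3(n, b - a)  # in-plane edge normal
    ref <- sign(sum(w * (ctr - a)))  # side the polygon interior lies on
    if (ref == 0) next
    s <- w[1] * (X[1, ] - a[1]) + w[2] * (X[2, ] - a[2]) + w[3] * (X[3, ] - a[3])
    inside <- inside & (ref * s >= -tol)
  }
  inside
}

# Bilinear / nearest sampling of a grayscale matrix at 0-based pixel
# coordinates with integer pixel centres.
.sample_channel <- function(img, u, v, interpolation = "bilinear") {
  H <- nrow(img); W <- ncol(img)
  if (interpolation == "nearest") {
    ui <- pmin(W - 1, pmax(0, round(u)))
    vi <- pmin(H - 1, pmax(0, round(v)))
    return(img[cbind(vi + 1, ui + 1)])
  }
  u <- pmin(W - 1, pmax(0, u))
  v <- pmin(H - 1, pmax(0, v))
  u0 <- floor(u); v0 <- floor(v)
  u1 <- pmin(u0 + 1, W - 1); v1 <- pmin(v0 + 1, H - 1)
  fu <- u - u0; fv <- v - v0
  img[cbind(v0 + 1, u0 + 1)] * (1 - fu) * (1 - fv) +
    img[cbind(v0 + 1, u1 + 1)] * fu * (1 - fv) +
    img[cbind(v1 + 1, u0 + 1)] * (1 - fu) * fv +
    img[cbind(v1 + 1, u1 + 1)] * fu * fv
}

.img_channels <- function(img) {
  if (is.matrix(img)) return(list(img))
  if (is.array(img) && length(dim(img)) == 3) {
    return(lapply(seq_len(dim(img)[3]), function(k) img[, , k]))
  }
  stop("images must be numeric matrices or 3-channel arrays")
}

#' Default virtual viewpoint between two cameras
#'
#' Midpoint of the camera centres, looking along the mean optical axis
#' with the mean image-right direction.
#'
#' @param pose1,pose2 [camera_pose()] objects.
#' @return a [camera_pose()].
#' @export
midpoint_viewpoint <- function(pose1, pose2) {
  ctr <- (pose1$center + pose2$center) / 2
  z <- pose1$rotation[, 3] + pose2$rotation[, 3]
  nz <- sqrt(sum(z^2))
  if (nz < 1e-9) stop("cameras face opposite directions: no mean axis")
  z <- z / nz
  x <- pose1$rotation[, 1] + pose2$rotation[, 1]
  x <- x - sum(x * z) * z
  nx <- sqrt(sum(x^2))
  if (nx < 1e-9) stop("degenerate mean right direction")
  x <- x / nx
  camera_pose(ctr, cbind(x, cross3(z, x), z))
}

#' Projection surfaces of a presentation method
#'
#' Returns the textured surfaces (3D polygons, each sampled from one
#' source camera) that a presentation method projects the images onto, in
#' painter's draw order (camera 1 before camera 2).
#'
#' @param pose1,pose2 [camera_pose()] objects.
#' @param K1,K2 [camera_intrinsics()] objects.
#' @param method one of `"naive"`, `"planar"`, `"overlap"`, `"cylinder"`.
#' @param Z projection-plane distance in scene units.
#' @param crop_side which camera's quad is clipped in overlap removal
#'   (1 or 2; default 2).
#' @param theta_cylinder,n_strips cylindrical-method parameters.
#' @return list of `list(poly, cam)` entries in draw order.
#' @export
expanded_view_surfaces <- function(pose1, pose2, K1, K2,
                                   method = c("naive", "planar", "overlap",
                                              "cylinder"),
                                   Z = 1, crop_side = 2,
                                   theta_cylinder = 120, n_strips = 32) {
  method <- match.arg(method)
  quad1 <- image_plane_quad(K1, pose1, Z)
  quad2 <- image_plane_quad(K2, pose2, Z)
  P1 <- attr(quad1, "plane"); P2 <- attr(quad2, "plane")
  if (method == "naive") {
    return(list(list(poly = unclass(quad1)[1:4, ], cam = 1L),
                list(poly = unclass(quad2)[1:4, ], cam = 2L)))
  }
  if (method == "overlap") {
    L <- plane_intersection_line(P1, P2)
    crop <- if (crop_side == 1) list(q = quad1, other = pose2) else
      list(q = quad2, other = pose1)
    keepq <- if (crop_side == 1) quad2 else quad1
    Pc <- attr(crop$q, "plane")
    # point inside the overlap: the other camera's optical axis hitting
    # the cropped camera's plane
    ax <- line3d(crop$other$center, crop$other$rotation[, 3])
    X_ov <- tryCatch(line_plane_intersection(ax, Pc),
                     error = function(e) colMeans(keepq))
    # keep the half-plane NOT containing the overlap point
    keep_pt <- L$point - (X_ov - L$point)
    clipped <- clip_quad_by_line(crop$q, L, keep_point = keep_pt)
    out <- list()
    if (crop_side == 2) {
      out[[1]] <- list(poly = unclass(quad1)[1:4, ], cam = 1L)
      if (nrow(clipped) >= 3) out[[2]] <- list(poly = clipped, cam = 2L)
    } else {
      if (nrow(clipped) >= 3) out[[1]] <- list(poly = clipped, cam = 1L)
      out[[length(out) + 1]] <- list(poly = unclass(quad2)[1:4, ], cam = 2L)
    }
    return(out)
  }
  # planar and cylinder share the bisecting plane
  Pb <- bisecting_plane(P1, P2)
  proj_onto <- function(quad, pose, target_plane) {
    t(apply(quad[1:4, ], 1, function(v) {
      line_plane_intersection(line3d(pose$center, v - pose$center),
                              target_plane)
    }))
  }
  poly1 <- proj_onto(quad1, pose1, Pb)
  poly2 <- proj_onto(quad2, pose2, Pb)
  if (method == "planar") {
    return(list(list(poly = poly1, cam = 1L), list(poly = poly2, cam = 2L)))
  }
  # cylinder: tangent to Pb along the midline of the combined footprint
  L <- if (angle_between_planes(P1, P2) < 1e-7) {
    line3d(poly1[1, ], poly1[2, ] - poly1[1, ])
  } else {
    plane_intersection_line(P1, P2)
  }
  u <- cross3(Pb$n, L$direction)
  u <- u / sqrt(sum(u^2))
  corners <- rbind(poly1, poly2)
  cu <- corners %*% u
  cm <- corners %*% L$direction
  WT <- max(cu) - min(cu)
  Hq <- max(cm) - min(cm)
  base <- colMeans(corners)
  mid_pt <- base + (((max(cu) + min(cu)) / 2) - sum(base * u)) * u
  cyl <- cylinder_from_planes(Pb, line3d(mid_pt, L$direction), WT,
                              theta_cylinder)
  vq <- rbind(c(0, 0, 0), c(WT, 0, 0), c(WT, Hq, 0), c(0, Hq, 0))
  strips <- strip_decomposition(vq, cyl, n_strips)
  c(lapply(strips, function(s) list(poly = s, cam = 1L)),
    lapply(strips, function(s) list(poly = s, cam = 2L)))
}

#' Render an expanded view from two posed images
#'
#' @param img1,img2 source images: numeric matrices (grayscale, values in
#'   `[0, 1]`) or 3-channel arrays; both must have the same number of
#'   channels.
#' @param pose1,pose2 [camera_pose()] objects.
#' @param K1,K2 [camera_intrinsics()] objects.
#' @param method presentation method (`"naive"`, `"planar"`, `"overlap"`,
#'   `"cylinder"`).
#' @param Z projection distance in scene units (default 1).
#' @param viewpoint virtual-viewpoint [camera_pose()]; default
#'   [midpoint_viewpoint()].
#' @param out_size `c(width, height)` of the output canvas in pixels.
#' @param out_K output-canvas [camera_intrinsics()]; the default halves
#'   camera 1's focal length (scaled to the canvas) to widen the view.
#' @param interpolation `"bilinear"` or `"nearest"`.
#' @param crop_side,theta_cylinder,n_strips method parameters, see
#'   [expanded_view_surfaces()].
#' @return object of class `expanded_view`: `canvas`, integer `provenance`
#'   mask (0 blank, 1 camera 1, 2 camera 2, 3 both), per-camera `layers`
#'   (canvas + logical mask), `method`, `viewpoint`, `surfaces`, `out_K`.
#' @export
render_expanded_view <- function(img1, img2, pose1, pose2, K1, K2,
                                 method = c("naive", "planar", "overlap",
                                            "cylinder"),
                                 Z = 1, viewpoint = NULL,
                                 out_size = c(320, 240), out_K = NULL,
                                 interpolation = c("bilinear", "nearest"),
                                 crop_side = 2, theta_cylinder = 120,
                                 n_strips = 32) {
  method <- match.arg(method)
  interpolation <- match.arg(interpolation)
  ch1 <- .img_channels(img1); ch2 <- .img_channels(img2)
  if (length(ch1) != length(ch2)) stop("images must have the same number of channels")
  if (is.null(viewpoint)) viewpoint <- midpoint_viewpoint(pose1, pose2)
  W <- out_size[1]; H <- out_size[2]
  if (is.null(out_K)) {
    out_K <- camera_intrinsics(fx = 0.5 * K1$fx * W / K1$width,
                               fy = 0.5 * K1$fy * H / K1$height,
                               width = W, height = H)
  }
  surfaces <- expanded_view_surfaces(pose1, pose2, K1, K2, method, Z,
                                     crop_side, theta_cylinder, n_strips)
  # ray directions for every canvas pixel (world frame, 3 x npix)
  uu <- rep(0:(W - 1), each = H)
  vv <- rep(0:(H - 1), times = W)
  Dcam <- rbind((uu - out_K$cx) / out_K$fx, (vv - out_K$cy) / out_K$fy,
                rep(1, W * H))
  D <- viewpoint$rotation %*% Dcam
  Cv <- viewpoint$center
  n_ch <- length(ch1)
  canvas <- lapply(seq_len(n_ch), function(k) matrix(0, H, W))
  prov <- matrix(0L, H, W)
  layers <- list(list(canvas = lapply(seq_len(n_ch), function(k) matrix(0, H, W)),
                      mask = matrix(FALSE, H, W)),
                 list(canvas = lapply(seq_len(n_ch), function(k) matrix(0, H, W)),
                      mask = matrix(FALSE, H, W)))
  cams <- list(list(pose = pose1, K = K1, ch = ch1),
               list(pose = pose2, K = K2, ch = ch2))
  any_front <- FALSE
  pix_idx <- cbind(vv + 1, uu + 1)
  for (srf in surfaces) {
    pl <- .polygon_plane(srf$poly)
    denom <- as.numeric(pl$n %*% D)
    tpar <- (pl$h - sum(pl$n * Cv)) / denom
    valid <- is.finite(tpar) & tpar > 1e-9
    if (!any(valid)) next
    any_front <- TRUE
    X <- matrix(NA_real_, 3, length(tpar))
    X[, valid] <- Cv + D[, valid, drop = FALSE] *
      rep(tpar[valid], each = 3)
    inside <- valid
    inside[valid] <- .inside_convex(srf$poly, X[, valid, drop = FALSE])
    if (!any(inside)) next
    cam <- cams[[srf$cam]]
    Xc <- t(cam$pose$rotation) %*% (X[, inside, drop = FALSE] - cam$pose$center)
    zf <- Xc[3, ] > 1e-9
    us <- cam$K$fx * Xc[1, ] / Xc[3, ] + cam$K$cx
    vs <- cam$K$fy * Xc[2, ] / Xc[3, ] + cam$K$cy
    inb <- zf & us >= -0.5 & us <= cam$K$width - 0.5 &
      vs >= -0.5 & vs <= cam$K$height - 0.5
    if (!any(inb)) next
    sel <- which(inside)[inb]
    if (method == "overlap") {
      open_pix <- prov[pix_idx[sel, , drop = FALSE]] == 0 |
        prov[pix_idx[sel, , drop = FALSE]] == srf$cam
      sel <- sel[open_pix]
      inb2 <- which(inb)[open_pix]
    } else {
      inb2 <- which(inb)
    }
    if (length(sel) == 0) next
    idx <- pix_idx[sel, , drop = FALSE]
    for (k in seq_len(n_ch)) {
      vals <- .sample_channel(cam$ch[[k]], us[inb2], vs[inb2], interpolation)
      canvas[[k]][idx] <- vals
      layers[[srf$cam]]$canvas[[k]][idx] <- vals
    }
    layers[[srf$cam]]$mask[idx] <- TRUE
    prov[idx] <- bitwOr(prov[idx], srf$cam)
  }
  if (!any_front) stop("degenerate view: all projection surfaces lie behind the viewpoint")
  simplify <- function(chl) {
    if (n_ch == 1) chl[[1]] else {
      a <- array(0, dim = c(H, W, n_ch))
      for (k in seq_len(n_ch)) a[, , k] <- chl[[k]]
      a
    }
  }
  structure(list(canvas = simplify(canvas), provenance = prov,
                 layers = list(cam1 = list(canvas = simplify(layers[[1]]$canvas),
                                           mask = layers[[1]]$mask),
                               cam2 = list(canvas = simplify(layers[[2]]$canvas),
                                           mask = layers[[2]]$mask)),
                 method = method, viewpoint = viewpoint,
                 surfaces = surfaces, out_K = out_K),
            class = "expanded_view")
}

#' @export
print.expanded_view <- function(x, ...) {
  tab <- table(factor(x$provenance, levels = 0:3,
                      labels = c("blank", "cam1", "cam2", "both")))
  cat("Expanded view (", x$method, "), ", ncol(x$provenance), "x",
      nrow(x$provenance), " px\n", sep = "")
  print(tab)
  invisible(x)
}

#' Footprint of a 3D polygon on the output canvas
#'
#' Projects a surface polygon through the virtual viewpoint's pinhole
#' model onto the canvas.
#'
#' @param poly m x 3 polygon vertices in the world frame.
#' @param viewpoint a [camera_pose()].
#' @param out_K the canvas [camera_intrinsics()].
#' @return m x 2 matrix of 0-based pixel coordinates `(u, v)`.
#' @export
footprint_polygon <- function(poly, viewpoint, out_K) {
  poly <- unname(as.matrix(poly))
  Xc <- t(viewpoint$rotation) %*% (t(poly) - viewpoint$center)
  if (any(Xc[3, ] <= 1e-12)) stop("degenerate mapping: vertex behind the viewpoint")
  cbind(out_K$fx * Xc[1, ] / Xc[3, ] + out_K$cx,
        out_K$fy * Xc[2, ] / Xc[3, ] + out_K$cy)
}

#' Area of a planar polygon given 2D vertices
#'
#' @param poly m x 2 vertex matrix.
#' @return absolute shoelace area.
#' @export
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}
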