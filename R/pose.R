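#' Correspondence sets of paired 3D points
#'
#' A correspondence set holds N paired 3D map points expressed in two
#' camera (map) frames: `p[i, ]` in frame 1 corresponds to `q[i, ]` in
#' frame 2. Centroids and centred coordinates, the quantities entering the
#' closed-form absolute-orientation solution, are precomputed.
#'
#' @param p,q N x 3 numeric matrices (or objects coercible to them) of
#'   corresponding 3D points.
#' @return an object of class `correspondence_set` with elements `p`, `q`,
#'   `n`, `p_bar`, `q_bar` (centroids) and `p_c`, `q_c` (centred
#'   coordinates).
#' @export
correspondence_set <- function(p, q) {
  p <- .as_points(p)
  q <- .as_points(q)
  if (nrow(p) != nrow(q)) stop("p and q must contain the same number of points")
  if (nrow(p) < 3) stop("insufficient points: at least 3 correspondences are required")
  p_bar <- colMeans(p)
  q_bar <- colMeans(q)
  structure(list(
    p = p, q = q, n = nrow(p),
    p_bar = p_bar, q_bar = q_bar,
    p_c = sweep(p, 2, p_bar),
    q_c = sweep(q, 2, q_bar)
  ), class = "correspondence_set")
}

.as_points <- function(x) {
  if (inherits(x, "data.frame")) x <- as.matrix(x)
  if (is.numeric(x) && is.null(dim(x)) && length(x) %% 3 == 0) {
    x <- matrix(x, ncol = 3, byrow = TRUE)
  }
  if (!is.matrix(x) || ncol(x) != 3 || !is.numeric(x)) {
    stop("points must be an N x 3 numeric matrix")
  }
  storage.mode(x) <- "double"
  unname(x)
}

#' @export
print.correspondence_set <- function(x, ...) {
  cat("Correspondence set:", x$n, "paired 3D points\n")
  invisible(x)
}

# Collinearity / coincidence check on a centred point matrix. Any set of
# 3D points has centred rank <= min(N - 1, 3); a triple is degenerate when
# its centred rank falls below 2 (collinear or coincident points), which
# leaves the rotation about the common line unconstrained.
.is_degenerate_cloud <- function(p_c, rtol = 1e-9) {
  sv <- svd(p_c, nu = 0, nv = 0)$d
  sv[1] < .Machine$double.eps || sv[2] < rtol * sv[1]
}

#' Closed-form rotation between corresponding point clouds
#'
#' Computes the unit quaternion maximizing the least-squares alignment
#' criterion between the centred clouds (Horn's closed form): the largest
#' eigenvector of the 4x4 matrix assembled from the 3x3 cross-covariance
#' of centred coordinates.
#'
#' @param corr a [correspondence_set()] (N >= 3, not collinear).
#' @return canonical unit quaternion rotating frame-1 centred coordinates
#'   onto frame-2 centred coordinates.
#' @export
horn_quaternion <- function(corr) {
  stopifnot(inherits(corr, "correspondence_set"))
  if (.is_degenerate_cloud(corr$p_c) || .is_degenerate_cloud(corr$q_c)) {
    stop("degenerate geometry: points are collinear or coincident")
  }
  M <- crossprod(corr$p_c, corr$q_c)  # sum over i of p'_i q'_i^T
  .horn_quat_from_M(M)
}

.horn_quat_from_M <- function(M) {
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N4 <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,        Szx - Sxz,        Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz,  Sxy + Syx,        Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz,  Syz + Szy,
    Sxy - Syx,       Szx + Sxz,        Syz + Szy,       -Sxx - Syy + Szz
  ), nrow = 4, byrow = TRUE)
  ev <- eigen(N4, symmetric = TRUE)
  quat_canonicalize(quat_normalize(ev$vectors[, 1]))
}

#' Scale and translation completing a similarity transform
#'
#' Given the rotation, the scale is the asymmetric closed form
#' `s = sum(q'_i . (R p'_i)) / sum(|p'_i|^2)` and the translation is
#' `t = q_bar - s R p_bar`.
#'
#' @param R 3x3 rotation matrix.
#' @param corr a [correspondence_set()].
#' @return list with elements `s` (scalar) and `t` (length-3 vector).
#' @export
horn_scale_translation <- function(R, corr) {
  stopifnot(inherits(corr, "correspondence_set"))
  .assert_rotation(R)
  denom <- sum(corr$p_c^2)
  if (denom < .Machine$double.eps) {
    stop("degenerate geometry: frame-1 points are coincident (zero spread)")
  }
  rp <- corr$p_c %*% t(R)
  s <- sum(corr$q_c * rp) / denom
  t <- as.numeric(corr$q_bar - s * (R %*% corr$p_bar))
  list(s = s, t = t)
}

#' Similarity transforms
#'
#' A similarity transform `(R, s, t)` maps a point `x` in frame 1 to
#' `s * R x + t` in frame 2: rotation, uniform scale and translation
#' (7 degrees of freedom).
#'
#' @param R 3x3 rotation matrix.
#' @param s positive scalar scale.
#' @param t length-3 translation vector.
#' @return object of class `similarity_transform` with fields `R`, `s`,
#'   `t` and the canonical `quaternion` of `R`.
#' @export
similarity_transform <- function(R = diag(3), s = 1, t = c(0, 0, 0)) {
  .assert_rotation(R)
  stopifnot(is.numeric(s), length(s) == 1, s > 0,
            is.numeric(t), length(t) == 3)
  structure(list(R = unname(R), s = as.numeric(s), t = as.numeric(t),
                 quaternion = rotmat_to_quat(R)),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, digits = 6, ...) {
  omega <- rotmat_to_rotvec(x$R)
  cat("Similarity transform (x -> s R x + t)\n")
  cat("  rotation angle:", format(rotation_angle(omega), digits = digits), "deg\n")
  cat("  quaternion:   ", paste(format(x$quaternion, digits = digits), collapse = " "), "\n")
  cat("  scale:        ", format(x$s, digits = digits), "\n")
  cat("  translation:  ", paste(format(x$t, digits = digits), collapse = " "), "\n")
  invisible(x)
}

#' Estimate a similarity transform from all correspondences
#'
#' Composition of [horn_quaternion()] and [horn_scale_translation()]:
#' the closed-form least-squares similarity between the two clouds.
#'
#' @param corr a [correspondence_set()].
#' @return a [similarity_transform()].
#' @export
fit_similarity <- function(corr) {
  q <- horn_quaternion(corr)
  R <- quat_to_rotmat(q)
  st <- horn_scale_translation(R, corr)
  similarity_transform(R = R, s = st$s, t = st$t)
}

#' Apply a similarity transform to points
#'
#' @param transform a [similarity_transform()].
#' @param points N x 3 matrix (or length-3 vector).
#' @return transformed points, same shape as the input.
#' @export
apply_transform <- function(transform, points) {
  stopifnot(inherits(transform, "similarity_transform"))
  vec <- is.null(dim(points))
  pts <- .as_points(points)
  out <- transform$s * (pts %*% t(transform$R))
  out <- sweep(out, 2, transform$t, "+")
  if (vec) as.numeric(out) else out
}

#' Invert a similarity transform
#'
#' @param transform a [similarity_transform()].
#' @return the inverse transform, mapping frame 2 back to frame 1.
#' @export
invert_transform <- function(transform) {
  stopifnot(inherits(transform, "similarity_transform"))
  Ri <- t(transform$R)
  si <- 1 / transform$s
  similarity_transform(R = Ri, s = si, t = as.numeric(-si * (Ri %*% transform$t)))
}

#' Per-point alignment residuals under a similarity transform
#'
#' @param transform a [similarity_transform()].
#' @param corr a [correspondence_set()].
#' @return numeric vector of `|q_i - (s R p_i + t)|` distances.
#' @export
transform_residuals <- function(transform, corr) {
  stopifnot(inherits(corr, "correspondence_set"))
  d <- corr$q - apply_transform(transform, corr$p)
  sqrt(rowSums(d^2))
}
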