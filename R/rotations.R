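#' Rotation representations
#'
#' Rotations are handled in three interchangeable representations: a unit
#' quaternion `(e0, e1, e2, e3)` (scalar-first, right-handed), a 3x3
#' orthonormal rotation matrix with determinant +1, and an axis-angle
#' rotation vector whose direction is the rotation axis and whose Euclidean
#' norm is the rotation angle in radians.
#'
#' Quaternions form a double cover of the rotation group: `q` and `-q`
#' encode the same rotation. All quaternions returned by the package are
#' canonicalized so that `e0 >= 0`, with ties (`e0 == 0`) broken by making
#' the first nonzero component positive. Averaging quaternions (as the
#' filtering estimator does) is only meaningful after this canonicalization.
#'
#' @name rotations
NULL

.quat_tol <- 1e-9

#' Normalize a quaternion to unit length
#'
#' @param q numeric length-4 vector `(e0, e1, e2, e3)`, scalar first.
#' @return unit-norm numeric length-4 vector.
#' @export
quat_normalize <- function(q) {
  stopifnot(is.numeric(q), length(q) == 4)
  n <- sqrt(sum(q^2))
  if (n < .quat_tol) stop("cannot normalize a near-zero quaternion")
  q / n
}

#' Canonicalize a unit quaternion to the e0 >= 0 hemisphere
#'
#' Resolves the q / -q double cover: the scalar part is made non-negative;
#' if it is zero, the first nonzero component is made positive.
#'
#' @param q numeric length-4 unit quaternion.
#' @return the canonical representative of the same rotation.
#' @export
quat_canonicalize <- function(q) {
  stopifnot(is.numeric(q), length(q) == 4)
  for (k in 1:4) {
    if (abs(q[k]) > .quat_tol) {
      if (q[k] < 0) q <- -q
      return(q)
    }
  }
  q
}

#' Convert a unit quaternion to a rotation matrix
#'
#' @param q numeric length-4 unit quaternion, scalar first.
#' @return 3x3 rotation matrix R such that rotating a vector `v` is `R %*% v`.
#' @export
quat_to_rotmat <- function(q) {
  q <- quat_normalize(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Test whether a matrix is a proper rotation
#'
#' @param R candidate 3x3 matrix.
#' @param tol orthogonality/determinant tolerance.
#' @return logical.
#' @export
is_rotation_matrix <- function(R, tol = 1e-8) {
  is.matrix(R) && all(dim(R) == c(3, 3)) &&
    max(abs(crossprod(R) - diag(3))) < tol &&
    abs(det(R) - 1) < tol
}

.assert_rotation <- function(R, tol = 1e-8) {
  if (!is_rotation_matrix(R, tol)) {
    stop("matrix is not a proper rotation (orthogonal, det +1)")
  }
}

#' Convert a rotation matrix to a canonical unit quaternion
#'
#' Uses Shepperd's branch selection for numerical stability near 180
#' degree rotations.
#'
#' @param R 3x3 rotation matrix.
#' @return canonical unit quaternion `(e0, e1, e2, e3)`.
#' @export
rotmat_to_quat <- function(R) {
  .assert_rotation(R)
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s,
           (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s,
           0.25 * s,
           (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s,
           (R[1, 2] + R[2, 1]) / s,
           0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s,
           (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s,
           0.25 * s)
  }
  quat_canonicalize(quat_normalize(q))
}

#' Convert an axis-angle rotation vector to a rotation matrix
#'
#' @param omega numeric length-3 vector; `norm(omega)` is the angle in radians.
#' @return 3x3 rotation matrix (Rodrigues' formula).
#' @export
rotvec_to_rotmat <- function(omega) {
  stopifnot(is.numeric(omega), length(omega) == 3)
  theta <- sqrt(sum(omega^2))
  if (theta < 1e-12) return(diag(3))
  k <- omega / theta
  K <- matrix(c(0, -k[3], k[2],
                k[3], 0, -k[1],
                -k[2], k[1], 0), nrow = 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Convert a rotation matrix to an axis-angle rotation vector
#'
#' Extracted through the quaternion representation, which stays
#' well-conditioned for angles approaching 180 degrees.
#'
#' @param R 3x3 rotation matrix.
#' @return numeric length-3 rotation vector (radians).
#' @export
rotmat_to_rotvec <- function(R) {
  q <- rotmat_to_quat(R)
  v <- q[2:4]
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) return(c(0, 0, 0))
  theta <- 2 * atan2(nv, q[1])
  (v / nv) * theta
}

#' @rdname rotmat_to_rotvec
#' @param q unit quaternion.
#' @export
quat_to_rotvec <- function(q) rotmat_to_rotvec(quat_to_rotmat(q))

#' Rotation angle of a rotation vector, in degrees
#'
#' @param omega rotation vector (radians).
#' @return `norm(omega)` converted to degrees.
#' @export
rotation_angle <- function(omega) {
  stopifnot(is.numeric(omega), length(omega) == 3)
  sqrt(sum(omega^2)) * 180 / pi
}

#' Angular distance between two rotations given as quaternions, in degrees
#'
#' @param q1,q2 unit quaternions.
#' @return geodesic angle in degrees, in `[0, 180]`.
#' @export
quat_angle <- function(q1, q2) {
  d <- abs(sum(quat_normalize(q1) * quat_normalize(q2)))
  2 * acos(min(1, d)) * 180 / pi
}

#' Build a rotation matrix from roll, pitch and yaw angles
#'
#' Intrinsic z-y-x composition: `R = Rz(yaw) %*% Ry(pitch) %*% Rx(roll)`.
#'
#' @param roll,pitch,yaw angles in radians about x, y and z respectively.
#' @return 3x3 rotation matrix.
#' @export
rpy_to_rotmat <- function(roll, pitch, yaw) {
  cr <- cos(roll); sr <- sin(roll)
  cp <- cos(pitch); sp <- sin(pitch)
  cy <- cos(yaw); sy <- sin(yaw)
  Rz <- matrix(c(cy, -sy, 0, sy, cy, 0, 0, 0, 1), 3, byrow = TRUE)
  Ry <- matrix(c(cp, 0, sp, 0, 1, 0, -sp, 0, cp), 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cr, -sr, 0, sr, cr), 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

# 3-vector cross product (used throughout the geometry code)
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
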