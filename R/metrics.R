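#' Image-similarity and pose-error metrics
#'
#' Quantitative measures used to evaluate the expanded views and the pose
#' estimators: zero-mean normalized cross-correlation (ZNCC), mutual
#' information from the 256-bin joint intensity histogram, mean squared
#' error between aligned point clouds, and the angle between axis-angle
#' rotation vectors.
#'
#' @name metrics
NULL

# Accept grayscale matrices or RGB(A) arrays; color is reduced to luma
# (ITU-R 601 weights). Values may be on the [0, 1] or the 0-255 scale.
.as_gray <- function(img) {
  if (is.array(img) && length(dim(img)) == 3) {
    ch <- dim(img)[3]
    if (ch >= 3) {
      img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    } else {
      img <- img[, , 1]
    }
  }
  if (!is.matrix(img) || !is.numeric(img)) stop("image must be a numeric matrix or array")
  img
}

#' Zero-mean normalized cross-correlation between two images
#'
#' Pixelwise correlation of the mean-centred images with the root-product
#' denominator, so the score is invariant to affine intensity changes and
#' equals 1 for identical images, -1 for perfectly anti-correlated ones.
#'
#' @param I,J images of equal dimensions (matrices, or RGB arrays which
#'   are converted to luma).
#' @return scalar in `[-1, 1]`.
#' @export
zncc <- function(I, J) {
  I <- .as_gray(I); J <- .as_gray(J)
  if (!all(dim(I) == dim(J))) stop("images must have equal dimensions")
  ic <- I - mean(I)
  jc <- J - mean(J)
  den <- sqrt(sum(ic^2) * sum(jc^2))
  if (den < .Machine$double.eps) {
    stop("undefined metric: at least one image has zero intensity variance")
  }
  sum(ic * jc) / den
}

# Quantize intensities to integer bins 0..(n_bins-1); [0,1]-scaled images
# are stretched to the 0-255 convention first.
.quantize <- function(img, n_bins = 256) {
  if (max(img) <= 1 + 1e-12 && min(img) >= 0) img <- img * (n_bins - 1)
  b <- as.integer(round(img))
  pmax(0L, pmin(n_bins - 1L, b))
}

#' Mutual information between two images, in bits
#'
#' Computed from the joint 256 x 256 intensity histogram: `MI(I, J) =
#' sum P(i, j) log2( P(i, j) / (P(i) P(j)) )` with `0 log 0 := 0`. It is
#' symmetric, non-negative, and `MI(I, I)` equals the entropy of I's
#' intensity histogram.
#'
#' @param I,J images of equal dimensions (8-bit convention; `[0, 1]`
#'   inputs are rescaled to 0-255 before binning).
#' @param n_bins number of intensity bins (default 256).
#' @return mutual information in bits.
#' @export
mutual_information <- function(I, J, n_bins = 256) {
  I <- .as_gray(I); J <- .as_gray(J)
  if (!all(dim(I) == dim(J))) stop("images must have equal dimensions")
  bi <- .quantize(I, n_bins)
  bj <- .quantize(J, n_bins)
  joint <- table(factor(bi, levels = 0:(n_bins - 1)),
                 factor(bj, levels = 0:(n_bins - 1)))
  pij <- joint / sum(joint)
  pi_ <- rowSums(pij)
  pj_ <- colSums(pij)
  nz <- pij > 0
  outer_p <- outer(pi_, pj_)
  sum(pij[nz] * log2(pij[nz] / outer_p[nz]))
}

#' Intensity-histogram entropy of an image, in bits
#'
#' @param I image (same conventions as [mutual_information()]).
#' @param n_bins number of intensity bins.
#' @return Shannon entropy of the marginal intensity histogram.
#' @export
image_entropy <- function(I, n_bins = 256) {
  I <- .as_gray(I)
  p <- tabulate(.quantize(I, n_bins) + 1L, nbins = n_bins)
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Angle between two axis-angle rotation vectors, in degrees
#'
#' `a = arccos( w . w' / (|w| |w'|) )`, with the cosine clamped to
#' `[-1, 1]` against rounding.
#'
#' @param omega,omega_prime nonzero length-3 rotation vectors.
#' @return angle in degrees, in `[0, 180]`.
#' @export
rotation_vector_angle <- function(omega, omega_prime) {
  stopifnot(length(omega) == 3, length(omega_prime) == 3)
  n1 <- sqrt(sum(omega^2)); n2 <- sqrt(sum(omega_prime^2))
  if (n1 < 1e-12 || n2 < 1e-12) stop("rotation vectors must be nonzero")
  acos(max(-1, min(1, sum(omega * omega_prime) / (n1 * n2)))) * 180 / pi
}

#' Mean squared error between paired point clouds
#'
#' `MSE = mean_i |A_i - B_i|^2` over index-paired points.
#'
#' @param A,B N x 3 matrices paired by row index.
#' @return scalar MSE.
#' @export
cloud_mse <- function(A, B) {
  A <- .as_points(A); B <- .as_points(B)
  if (nrow(A) != nrow(B)) stop("clouds must have equal length")
  mean(rowSums((A - B)^2))
}

#' @rdname cloud_mse
#' @return `cloud_sd`: variance of the per-point squared errors.
#' @export
cloud_sd <- function(A, B) {
  A <- .as_points(A); B <- .as_points(B)
  if (nrow(A) != nrow(B)) stop("clouds must have equal length")
  stats::var(rowSums((A - B)^2))
}

#' Error report comparing an estimated transform to ground truth
#'
#' Produces the standard nine-column comparison: rotation-vector
#' components (radians), rotation angle theta (degrees), the angle `a`
#' between the two rotation vectors (degrees), scale, and the translation
#' components, with each error computed as estimate minus truth.
#'
#' @param est,truth [similarity_transform()] objects.
#' @return object of class `error_report`: a data.frame with rows
#'   `truth`, `estimate`, `error` and columns `wx, wy, wz, theta_deg,
#'   a_deg, s, tx, ty, tz`.
#' @export
transform_error_report <- function(est, truth) {
  stopifnot(inherits(est, "similarity_transform"),
            inherits(truth, "similarity_transform"))
  w_t <- rotmat_to_rotvec(truth$R)
  w_e <- rotmat_to_rotvec(est$R)
  a <- if (sqrt(sum(w_t^2)) < 1e-12 || sqrt(sum(w_e^2)) < 1e-12) {
    0
  } else {
    rotation_vector_angle(w_t, w_e)
  }
  row_of <- function(w, tr) c(w, rotation_angle(w), NA, tr$s, tr$t)
  truth_row <- row_of(w_t, truth)
  est_row <- row_of(w_e, est)
  est_row[5] <- a
  err <- est_row - truth_row
  err[5] <- NA
  df <- as.data.frame(rbind(truth = truth_row, estimate = est_row, error = err))
  names(df) <- c("wx", "wy", "wz", "theta_deg", "a_deg", "s", "tx", "ty", "tz")
  structure(df, class = c("error_report", "data.frame"))
}

#' @export
print.error_report <- function(x, digits = 4, ...) {
  y <- as.data.frame(x)
  y$theta_deg <- round(y$theta_deg, 3)
  print(round(y, digits), ...)
  invisible(x)
}
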