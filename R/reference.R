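#' Published reference results of the synthetic pose evaluation
#'
#' Rotation vectors, angles, scales and translations reported for two
#' random instances of the synthetic evaluation protocol, comparing the
#' plain closed-form estimator against the quaternion-filtering estimator
#' at removal divisors d = 4 and d = 2. These printed values are shipped
#' as plain text and serve as desk-check inputs: the rotation angle
#' `theta` must equal the norm of the rotation vector, the `a` column must
#' equal the angle between the ground-truth and estimated rotation
#' vectors, and each error row is estimate minus truth.
#'
#' @return data.frame with columns `instance`, `method`, `wx, wy, wz`
#'   (radians), `theta_deg`, `a_deg`, `s`, `tx, ty, tz`.
#' @export
reference_pose_estimates <- function() {
  path <- system.file("extdata", "reference_pose_estimates.csv",
                      package = "fovex", mustWork = TRUE)
  utils::read.csv(path)
}
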