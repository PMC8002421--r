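#' Robust pose estimation from noisy correspondences
#'
#' Two robust estimators are built on top of the closed-form solution:
#' an inlier-maximizing search over minimal three-point subsets, and a
#' quaternion-filtering estimator that computes one candidate rotation per
#' three-point combination, rejects outlying candidates around the
#' component-wise median, and averages the survivors.
#'
#' @name robust_estimation
NULL

# Enumerate three-point subsets. Exhaustive (combn order) when the number
# of combinations is small; otherwise seeded sampling of distinct triples.
.enumerate_triples <- function(n, max_triples = 4060, seed = NULL) {
  n_comb <- choose(n, 3)
  if (n_comb <= max_triples) {
    return(utils::combn(n, 3))
  }
  rng <- if (is.null(seed)) sample.int(.Machine$integer.max, 1) else seed
  picked <- new.env(hash = TRUE)
  out <- matrix(0L, nrow = 3, ncol = max_triples)
  got <- 0L
  set.seed(rng)
  while (got < max_triples) {
    tr <- sort(sample.int(n, 3))
    key <- paste(tr, collapse = ",")
    if (is.null(picked[[key]])) {
      picked[[key]] <- TRUE
      got <- got + 1L
      out[, got] <- tr
    }
  }
  out
}

# Closed-form similarity from one triple; NULL when the triple is
# degenerate (collinear/coincident in either cloud).
.triple_fit <- function(corr, idx) {
  p3 <- corr$p[idx, , drop = FALSE]
  q3 <- corr$q[idx, , drop = FALSE]
  pc <- sweep(p3, 2, colMeans(p3))
  qc <- sweep(q3, 2, colMeans(q3))
  if (.is_degenerate_cloud(pc) || .is_degenerate_cloud(qc)) return(NULL)
  quat <- .horn_quat_from_M(crossprod(pc, qc))
  R <- quat_to_rotmat(quat)
  denom <- sum(pc^2)
  s <- sum(qc * (pc %*% t(R))) / denom
  if (s <= 0) return(NULL)
  t <- colMeans(q3) - s * as.numeric(R %*% colMeans(p3))
  list(quat = quat, R = R, s = s, t = t)
}

#' Default inlier threshold for a correspondence set
#'
#' One tenth of the RMS radius of the centred frame-2 cloud, so that the
#' threshold scales with the scene.
#'
#' @param corr a [correspondence_set()].
#' @return scalar threshold in scene units.
#' @export
default_inlier_threshold <- function(corr) {
  stopifnot(inherits(corr, "correspondence_set"))
  0.1 * sqrt(mean(rowSums(corr$q_c^2)))
}

#' Inlier-maximizing pose estimation over three-point subsets
#'
#' Fits the closed-form similarity to every enumerated triple of
#' correspondences, counts inliers (3D alignment residual at or below
#' `threshold`), and returns the transform with the largest inlier count.
#' Ties are broken by smaller mean inlier residual, then by enumeration
#' order. Enumeration is exhaustive up to `max_triples` combinations and
#' seeded random sampling of distinct triples beyond that.
#'
#' @param corr a [correspondence_set()], N >= 3.
#' @param threshold inlier residual threshold in scene units; default
#'   [default_inlier_threshold()].
#' @param max_triples cap on the number of evaluated triples (default 4060,
#'   i.e. exhaustive for N <= 30).
#' @param seed RNG seed used only when sampling is needed.
#' @return object of class `pose_estimate`: `transform`, `inlier_count`,
#'   `inlier_mask`, `residuals`, `method`, `threshold`.
#' @export
estimate_pose_ransac <- function(corr, threshold = NULL, max_triples = 4060,
                                 seed = NULL) {
  stopifnot(inherits(corr, "correspondence_set"))
  if (is.null(threshold)) threshold <- default_inlier_threshold(corr)
  stopifnot(threshold > 0)
  triples <- .enumerate_triples(corr$n, max_triples, seed)
  best <- NULL
  for (k in seq_len(ncol(triples))) {
    fit <- .triple_fit(corr, triples[, k])
    if (is.null(fit)) next
    tr <- similarity_transform(fit$R, fit$s, fit$t)
    res <- transform_residuals(tr, corr)
    mask <- res <= threshold
    n_in <- sum(mask)
    mean_res <- if (n_in > 0) mean(res[mask]) else Inf
    if (is.null(best) || n_in > best$inlier_count ||
        (n_in == best$inlier_count && mean_res < best$mean_inlier_residual)) {
      best <- list(transform = tr, inlier_count = n_in, inlier_mask = mask,
                   residuals = res, mean_inlier_residual = mean_res,
                   triple = triples[, k])
    }
  }
  if (is.null(best)) stop("degenerate geometry: all candidate triples are collinear")
  structure(c(best, list(method = "inlier_max", threshold = threshold)),
            class = "pose_estimate")
}

#' @export
print.pose_estimate <- function(x, ...) {
  cat("Pose estimate (", x$method, "): ", x$inlier_count, "/",
      length(x$residuals), " inliers at threshold ",
      format(x$threshold, digits = 4), "\n", sep = "")
  print(x$transform)
  invisible(x)
}

#' Candidate quaternions from all three-point combinations
#'
#' @param corr a [correspondence_set()].
#' @param max_triples cap passed to the triple enumeration.
#' @param seed RNG seed used only when sampling is needed.
#' @return matrix with one canonical unit quaternion per row; attribute
#'   `"n_degenerate"` counts rejected triples.
#' @export
triple_quaternions <- function(corr, max_triples = 4060, seed = NULL) {
  stopifnot(inherits(corr, "correspondence_set"))
  triples <- .enumerate_triples(corr$n, max_triples, seed)
  out <- matrix(NA_real_, nrow = ncol(triples), ncol = 4)
  for (k in seq_len(ncol(triples))) {
    fit <- .triple_fit(corr, triples[, k])
    if (!is.null(fit)) out[k, ] <- fit$quat
  }
  keep <- !is.na(out[, 1])
  structure(out[keep, , drop = FALSE], n_degenerate = sum(!keep))
}

#' Median-centred quaternion filtering
#'
#' Computes the component-wise median of the candidate quaternions and the
#' per-component spread `sigma_l = sqrt(mean((e_il - mean_l)^2))` (population
#' form, centred on the mean over all candidates). A candidate is kept when
#' every component lies within `sigma_l / d` of the median; increasing `d`
#' narrows the band and keeps fewer candidates. The representative rotation
#' is the renormalized component-wise mean of the kept candidates. If the
#' band is so narrow that no candidate satisfies it in all four components
#' at once (possible because the component-wise median need not be a
#' candidate), the candidate closest to the median is kept so that the
#' result is always defined.
#'
#' @param candidates n x 4 matrix of canonical unit quaternions (rows), or
#'   a single quaternion vector.
#' @param d positive removal-range divisor (2 and 4 are typical values).
#' @return object of class `quaternion_filter`: `candidates`, `median`,
#'   `sigma`, `d`, `kept` (logical vector), `representative`.
#' @export
quaternion_filter <- function(candidates, d = 2) {
  if (is.null(dim(candidates))) candidates <- matrix(candidates, ncol = 4)
  stopifnot(is.matrix(candidates), ncol(candidates) == 4,
            nrow(candidates) >= 1, d > 0)
  med <- apply(candidates, 2, stats::median)
  mu <- colMeans(candidates)
  sigma <- sqrt(colMeans(sweep(candidates, 2, mu)^2))
  dev <- abs(sweep(candidates, 2, med))
  kept <- rowSums(dev <= rep(sigma / d, each = nrow(candidates))) == 4
  if (!any(kept)) {
    # band too narrow for every candidate: keep the one needing the least
    # band widening (max sigma-scaled deviation). This choice nests across
    # d values, so kept(d_large) stays a subset of kept(d_small).
    ratio <- apply(dev, 1, function(r) {
      max(ifelse(sigma > 0, r / sigma, ifelse(r <= 1e-12, 0, Inf)))
    })
    kept[which.min(ratio)] <- TRUE
  }
  rep_q <- quat_canonicalize(quat_normalize(colMeans(candidates[kept, , drop = FALSE])))
  structure(list(candidates = candidates, median = med, sigma = sigma,
                 d = d, kept = kept, representative = rep_q),
            class = "quaternion_filter")
}

#' @export
print.quaternion_filter <- function(x, ...) {
  cat("Quaternion filter (d = ", x$d, "): kept ", sum(x$kept), "/",
      nrow(x$candidates), " candidates\n", sep = "")
  cat("  representative:", paste(format(x$representative, digits = 6),
                                 collapse = " "), "\n")
  invisible(x)
}

#' Quaternion-filtering pose estimation
#'
#' Enumerates all three-point combinations, computes one candidate
#' quaternion per non-degenerate triple, filters the candidates around
#' their component-wise median ([quaternion_filter()]), converts the
#' representative quaternion to a rotation matrix, and finally computes
#' scale and translation from the centred coordinates of ALL N
#' correspondences with that rotation.
#'
#' @param corr a [correspondence_set()]; with N = 3 there is a single
#'   candidate and the method reduces to the plain closed form.
#' @param d removal-range divisor (default 2).
#' @param threshold inlier threshold used only to report an inlier mask;
#'   default [default_inlier_threshold()].
#' @param max_triples,seed passed to the triple enumeration.
#' @return a `pose_estimate` whose `filter` element holds the
#'   [quaternion_filter()] result.
#' @export
estimate_pose_filtered <- function(corr, d = 2, threshold = NULL,
                                   max_triples = 4060, seed = NULL) {
  stopifnot(inherits(corr, "correspondence_set"))
  if (is.null(threshold)) threshold <- default_inlier_threshold(corr)
  cands <- triple_quaternions(corr, max_triples, seed)
  if (nrow(cands) == 0) stop("degenerate geometry: all candidate triples are collinear")
  filt <- quaternion_filter(cands, d = d)
  R <- quat_to_rotmat(filt$representative)
  st <- horn_scale_translation(R, corr)
  tr <- similarity_transform(R, st$s, st$t)
  res <- transform_residuals(tr, corr)
  mask <- res <= threshold
  structure(list(transform = tr, inlier_count = sum(mask), inlier_mask = mask,
                 residuals = res, mean_inlier_residual =
                   if (any(mask)) mean(res[mask]) else Inf,
                 filter = filt, method = "quaternion_filter", d = d,
                 threshold = threshold),
            class = "pose_estimate")
}

#' Key frames with features and associated map points
#'
#' A key frame is a selected video frame whose 2D feature points anchor 3D
#' map points triangulated by the SLAM system. Features, descriptors and
#' map points are aligned by index; features without a triangulated map
#' point carry `NA` coordinates.
#'
#' @param id identifier.
#' @param feature_points F x 2 matrix of pixel coordinates.
#' @param descriptors list of F raw vectors (binary descriptors), or NULL.
#' @param map_points F x 3 matrix of 3D map-point coordinates, rows of
#'   `NA` where the feature has no map point.
#' @param map_point_ids optional integer labels, `NA` where absent.
#' @return object of class `keyframe`.
#' @export
keyframe <- function(id, feature_points, map_points,
                     descriptors = NULL, map_point_ids = NULL) {
  feature_points <- as.matrix(feature_points)
  map_points <- as.matrix(map_points)
  stopifnot(ncol(feature_points) == 2, ncol(map_points) == 3,
            nrow(feature_points) == nrow(map_points))
  if (!is.null(descriptors)) {
    stopifnot(is.list(descriptors), length(descriptors) == nrow(feature_points))
  }
  if (is.null(map_point_ids)) {
    map_point_ids <- ifelse(is.na(map_points[, 1]), NA_integer_,
                            seq_len(nrow(map_points)))
  }
  structure(list(id = id, feature_points = unname(feature_points),
                 descriptors = descriptors,
                 map_points = unname(map_points),
                 map_point_ids = as.integer(map_point_ids)),
            class = "keyframe")
}

#' Mutual-nearest Hamming matcher over binary descriptors
#'
#' @param frame1,frame2 [keyframe()] objects with raw-vector descriptors.
#' @param max_distance maximum Hamming distance (bits) for a match.
#' @return data.frame with columns `i1`, `i2`, `distance`.
#' @export
hamming_matcher <- function(frame1, frame2, max_distance = 64) {
  d1 <- frame1$descriptors
  d2 <- frame2$descriptors
  if (is.null(d1) || is.null(d2)) stop("both key frames need descriptors")
  b1 <- lapply(d1, function(r) as.integer(rawToBits(r)))
  b2 <- lapply(d2, function(r) as.integer(rawToBits(r)))
  n1 <- length(b1); n2 <- length(b2)
  if (n1 == 0 || n2 == 0) return(data.frame(i1 = integer(), i2 = integer(),
                                            distance = integer()))
  D <- matrix(0L, n1, n2)
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) D[i, j] <- sum(b1[[i]] != b2[[j]])
  }
  best12 <- apply(D, 1, which.min)
  best21 <- apply(D, 2, which.min)
  keep <- which(best21[best12] == seq_len(n1) &
                  D[cbind(seq_len(n1), best12)] <= max_distance)
  data.frame(i1 = keep, i2 = best12[keep],
             distance = D[cbind(keep, best12[keep])])
}

#' Automatic selection of the optimal key-frame pair
#'
#' Scans all pairs of key frames (first set major, second set minor). For
#' each pair, descriptor matching yields map-point correspondences; when at
#' least `min_corr` correspondences exist, the inlier-maximizing estimator
#' is run, and the first pair reaching `min_inliers` inliers is returned
#' with its transform. Both thresholds default to 20 (empirically tuned to
#' the typical number of features per frame).
#'
#' @param set1,set2 lists of [keyframe()] objects.
#' @param matcher function `(frame1, frame2) -> data.frame(i1, i2)`;
#'   default [hamming_matcher()].
#' @param min_corr minimum number of map-point correspondences.
#' @param min_inliers minimum inlier count for acceptance.
#' @param threshold inlier threshold forwarded to the estimator.
#' @param ... further arguments to [estimate_pose_ransac()].
#' @return list with `pair = c(i, j)`, `estimate`, `correspondences`; or
#'   `NULL` when no pair qualifies.
#' @export
select_optimal_keyframe_pair <- function(set1, set2, matcher = hamming_matcher,
                                         min_corr = 20, min_inliers = 20,
                                         threshold = NULL, ...) {
  if (length(set1) == 0 || length(set2) == 0) stop("empty key-frame set")
  for (i in seq_along(set1)) {
    for (j in seq_along(set2)) {
      f1 <- set1[[i]]; f2 <- set2[[j]]
      m <- matcher(f1, f2)
      if (nrow(m) == 0) next
      ok <- !is.na(f1$map_points[m$i1, 1]) & !is.na(f2$map_points[m$i2, 1])
      m <- m[ok, , drop = FALSE]
      if (nrow(m) < min_corr) next
      corr <- correspondence_set(f1$map_points[m$i1, , drop = FALSE],
                                 f2$map_points[m$i2, , drop = FALSE])
      est <- estimate_pose_ransac(corr, threshold = threshold, ...)
      if (est$inlier_count >= min_inliers) {
        return(list(pair = c(i, j), estimate = est, correspondences = corr))
      }
    }
  }
  NULL
}

#' Snap clicked pixel positions to features carrying map points
#'
#' Each click is assigned the nearest feature point (Euclidean pixel
#' distance) that has an associated 3D map point, within `radius` pixels;
#' exact ties go to the lower feature index.
#'
#' @param clicks M x 2 matrix of pixel coordinates.
#' @param frame a [keyframe()].
#' @param radius maximum snap distance in pixels.
#' @return data.frame with the click index, snapped feature index, pixel
#'   distance and map-point coordinates.
#' @export
snap_clicks_to_features <- function(clicks, frame, radius = 20) {
  clicks <- as.matrix(clicks)
  stopifnot(ncol(clicks) == 2, inherits(frame, "keyframe"), radius > 0)
  has_mp <- which(!is.na(frame$map_points[, 1]))
  if (length(has_mp) == 0) stop("key frame has no features with map points")
  fp <- frame$feature_points[has_mp, , drop = FALSE]
  out <- data.frame(click = seq_len(nrow(clicks)), feature = NA_integer_,
                    distance = NA_real_, x = NA_real_, y = NA_real_,
                    z = NA_real_)
  unresolved <- integer()
  for (k in seq_len(nrow(clicks))) {
    d <- sqrt((fp[, 1] - clicks[k, 1])^2 + (fp[, 2] - clicks[k, 2])^2)
    best <- which.min(d)  # which.min returns the first (lowest-index) tie
    if (d[best] > radius) {
      unresolved <- c(unresolved, k)
    } else {
      fi <- has_mp[best]
      out$feature[k] <- fi
      out$distance[k] <- d[best]
      out[k, c("x", "y", "z")] <- frame$map_points[fi, ]
    }
  }
  if (length(unresolved) > 0) {
    stop("no feature with a map point within radius for click(s): ",
         paste(unresolved, collapse = ", "))
  }
  out
}

#' Correspondences from clicked points in two key frames
#'
#' Snaps the same number of clicks in each frame and pairs the resulting
#' map points by click order.
#'
#' @param clicks1,clicks2 M x 2 click matrices for the two frames.
#' @param frame1,frame2 [keyframe()] objects.
#' @param radius snap radius in pixels.
#' @return a [correspondence_set()].
#' @export
correspondences_from_clicks <- function(clicks1, frame1, clicks2, frame2,
                                        radius = 20) {
  s1 <- snap_clicks_to_features(clicks1, frame1, radius)
  s2 <- snap_clicks_to_features(clicks2, frame2, radius)
  if (nrow(s1) != nrow(s2)) stop("click lists must have equal length")
  correspondence_set(as.matrix(s1[, c("x", "y", "z")]),
                     as.matrix(s2[, c("x", "y", "z")]))
}
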