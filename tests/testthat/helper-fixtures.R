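# Shared fixtures built in code.

random_rotation <- function() {
  # uniform-ish random rotation from a random quaternion
  q <- stats::rnorm(4)
  quat_to_rotmat(q / sqrt(sum(q^2)))
}

random_transform <- function() {
  similarity_transform(random_rotation(), stats::runif(1, 0.2, 3),
                       stats::runif(3, -5, 5))
}

random_cloud <- function(n = 10, range = 5) {
  matrix(stats::runif(3 * n, -range, range), ncol = 3)
}

# two key frames sharing n_shared map points under transform `tr`, with
# matching binary descriptors; n_extra unmatched features in each frame
make_keyframe_pair <- function(tr, n_shared = 25, n_extra = 5,
                               n_outliers = 0, seed = 1) {
  set.seed(seed)
  p <- random_cloud(n_shared)
  q <- apply_transform(tr, p)
  if (n_outliers > 0) {
    idx <- seq_len(n_outliers)
    q[idx, ] <- q[idx, ] + matrix(stats::runif(3 * n_outliers, 30, 60),
                                  ncol = 3)
  }
  desc_shared <- lapply(seq_len(n_shared), function(i) {
    as.raw(sample(0:255, 32, replace = TRUE))
  })
  mk_extra_desc <- function(n) lapply(seq_len(n), function(i) {
    as.raw(sample(0:255, 32, replace = TRUE))
  })
  mk_frame <- function(id, mp) {
    n_tot <- n_shared + n_extra
    keyframe(id,
             feature_points = matrix(stats::runif(2 * n_tot, 0, 640),
                                     ncol = 2),
             map_points = rbind(mp, matrix(NA_real_, n_extra, 3)),
             descriptors = c(desc_shared, mk_extra_desc(n_extra)))
  }
  list(f1 = mk_frame("f1", p), f2 = mk_frame("f2", q), p = p, q = q)
}
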