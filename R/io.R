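#' File formats
#'
#' Plain-text interchange for every object the tools produce: point
#' clouds as ASCII PLY or CSV, correspondences as CSV (`px,py,pz,qx,qy,qz`)
#' or JSON named arrays, similarity transforms as JSON (quaternion, scale,
#' translation and the 4x4 homogeneous matrix), camera intrinsics as YAML,
#' images as PNG, and reports as JSON. All coordinates are world-frame,
#' right-handed, in abstract scene units.
#'
#' @name cli_io
NULL

#' Read / write correspondences as CSV
#'
#' Columns `px, py, pz, qx, qy, qz`, one correspondence per row.
#'
#' @param path file path.
#' @return `read_correspondences_csv`: a [correspondence_set()].
#' @export
read_correspondences_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("px", "py", "pz", "qx", "qy", "qz")
  if (!all(need %in% names(df))) {
    stop("malformed correspondence CSV '", path, "': need columns ",
         paste(need, collapse = ", "))
  }
  correspondence_set(as.matrix(df[, c("px", "py", "pz")]),
                     as.matrix(df[, c("qx", "qy", "qz")]))
}

#' @rdname read_correspondences_csv
#' @param corr a [correspondence_set()].
#' @export
write_correspondences_csv <- function(corr, path) {
  stopifnot(inherits(corr, "correspondence_set"))
  df <- data.frame(px = corr$p[, 1], py = corr$p[, 2], pz = corr$p[, 3],
                   qx = corr$q[, 1], qy = corr$q[, 2], qz = corr$q[, 3])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write correspondences as JSON named arrays
#'
#' @param path file path.
#' @return a [correspondence_set()] (reader) or the path (writer).
#' @export
read_correspondences_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$p) || is.null(obj$q)) {
    stop("malformed correspondence JSON '", path, "': need fields 'p' and 'q'")
  }
  correspondence_set(obj$p, obj$q)
}

#' @rdname read_correspondences_json
#' @param corr a [correspondence_set()].
#' @export
write_correspondences_json <- function(corr, path) {
  stopifnot(inherits(corr, "correspondence_set"))
  jsonlite::write_json(list(p = corr$p, q = corr$q), path, digits = NA)
  invisible(path)
}

#' Read / write a point cloud as ASCII PLY
#'
#' Minimal `vertex` element with float properties x, y, z. (ASCII PLY is
#' simple enough that the package carries its own reader/writer.)
#'
#' @param path file path.
#' @return N x 3 matrix (reader) or the path (writer).
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || trimws(lines[1]) != "ply") {
    stop("malformed PLY '", path, "': missing 'ply' magic line")
  }
  end_hdr <- which(trimws(lines) == "end_header")[1]
  if (is.na(end_hdr)) stop("malformed PLY '", path, "': no end_header")
  hdr <- lines[seq_len(end_hdr)]
  vline <- grep("^element vertex ", trimws(hdr), value = TRUE)
  if (length(vline) != 1) stop("malformed PLY '", path, "': need one vertex element")
  n <- as.integer(strsplit(trimws(vline), "\\s+")[[1]][3])
  body <- lines[(end_hdr + 1):(end_hdr + n)]
  vals <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), function(x) {
    as.numeric(x[1:3])
  }))
  if (any(is.na(vals))) stop("malformed PLY '", path, "': non-numeric vertex data")
  vals
}

#' @rdname read_ply
#' @param points N x 3 matrix.
#' @export
write_ply <- function(points, path) {
  points <- .as_points(points)
  hdr <- c("ply", "format ascii 1.0",
           paste("element vertex", nrow(points)),
           "property float x", "property float y", "property float z",
           "end_header")
  body <- apply(points, 1, function(v) {
    paste(format(v, digits = 17, scientific = FALSE, trim = TRUE),
          collapse = " ")
  })
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read / write a similarity transform as JSON
#'
#' Serialized fields: `quaternion` (e0..e3), `scale`, `translation`, and
#' `matrix` — the 4x4 homogeneous matrix in row-major order.
#'
#' @param path file path.
#' @return a [similarity_transform()] (reader) or the path (writer).
#' @export
read_transform_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$quaternion) || is.null(obj$scale) || is.null(obj$translation)) {
    stop("malformed transform JSON '", path,
         "': need quaternion, scale, translation")
  }
  similarity_transform(quat_to_rotmat(as.numeric(obj$quaternion)),
                       as.numeric(obj$scale), as.numeric(obj$translation))
}

#' @rdname read_transform_json
#' @param transform a [similarity_transform()].
#' @param config optional list (e.g. resolved run configuration and seed)
#'   stored alongside the transform for reproducibility.
#' @export
write_transform_json <- function(transform, path, config = NULL) {
  stopifnot(inherits(transform, "similarity_transform"))
  Hm <- rbind(cbind(transform$s * transform$R, transform$t), c(0, 0, 0, 1))
  out <- list(quaternion = transform$quaternion, scale = transform$s,
              translation = transform$t,
              matrix = as.numeric(t(Hm)))
  if (!is.null(config)) out$config <- config
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read / write camera intrinsics as YAML
#'
#' Fields `fx, fy, width, height` and optional `cx, cy`.
#'
#' @param path file path.
#' @return a [camera_intrinsics()] (reader) or the path (writer).
#' @export
read_intrinsics_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  need <- c("fx", "fy", "width", "height")
  if (!all(need %in% names(obj))) {
    stop("malformed intrinsics YAML '", path, "': need fields ",
         paste(need, collapse = ", "))
  }
  args <- obj[intersect(names(obj), c(need, "cx", "cy"))]
  do.call(camera_intrinsics, args)
}

#' @rdname read_intrinsics_yaml
#' @param K a [camera_intrinsics()].
#' @export
write_intrinsics_yaml <- function(K, path) {
  stopifnot(inherits(K, "camera_intrinsics"))
  yaml::write_yaml(K[c("fx", "fy", "width", "height", "cx", "cy")], path)
  invisible(path)
}

#' Read / write images as PNG
#'
#' Grayscale matrices or RGB arrays with values in `[0, 1]`.
#'
#' @param path file path.
#' @return image matrix/array (reader) or the path (writer).
#' @export
read_image_png <- function(path) png::readPNG(path)

#' @rdname read_image_png
#' @param img image matrix or array, values clipped to `[0, 1]`.
#' @export
write_image_png <- function(img, path) {
  img[img < 0] <- 0
  img[img > 1] <- 1
  png::writePNG(img, path)
  invisible(path)
}
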