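#' Affine transform of a point cloud
#'
#' Applies `p' = M p` to every point (optionally about a fixed `center`, in
#' which case `p' = M (p - center) + center`). Rotations must be orthogonal
#' with determinant +1, mirrors with determinant -1; any other singular
#' matrix is rejected.
#'
#' @param cloud a [pointcloud()].
#' @param m 3 x 3 transform matrix.
#' @param center optional 3-vector pivot.
#' @return The transformed [pointcloud()] (point count preserved).
#' @export
affine_transform <- function(cloud, m, center = NULL) {
  stopifnot(inherits(cloud, "pointcloud"))
  m <- as.matrix(m)
  if (!all(dim(m) == c(3L, 3L))) stop("transform matrix must be 3 x 3")
  if (abs(det(m)) < 1e-12) stop("transform matrix is singular")
  pts <- coords(cloud)
  if (!is.null(center)) pts <- sweep(pts, 2, center)
  pts <- pts %*% t(m)
  if (!is.null(center)) pts <- sweep(pts, 2, center, `+`)
  pointcloud(pts, frame_id = cloud$frame_id)
}

#' Clockwise rotation about the vertical (y) axis
#'
#' Convention: viewed from above with y up, a clockwise rotation by 90
#' degrees maps (1, 0, 0) to (0, 0, -1).
#'
#' @param angle_deg rotation angle in degrees.
#' @return 3 x 3 rotation matrix (orthogonal, determinant +1).
#' @export
rotation_vertical_cw <- function(angle_deg) {
  a <- angle_deg * pi / 180
  matrix(c(cos(a), 0,  sin(a),
           0,      1,  0,
           -sin(a), 0, cos(a)), 3, 3, byrow = TRUE)
}

#' Mirror matrices
#'
#' `mirror_horizontal()` reflects across the sagittal plane (negates z);
#' `mirror_vertical()` reflects across the transverse plane (negates x).
#' Both are orthogonal with determinant -1.
#'
#' @return 3 x 3 reflection matrix.
#' @export
mirror_horizontal <- function() diag(c(1, 1, -1))

#' @rdname mirror_horizontal
#' @export
mirror_vertical <- function() diag(c(-1, 1, 1))

#' Ten-fold rigid augmentation of silhouette clouds
#'
#' Expands each input cloud into itself plus its seven clockwise rotations
#' (45, 90, ..., 315 degrees about the vertical axis through the cloud
#' centroid) and its horizontal and vertical mirrors (across planes through
#' the centroid), in that deterministic order. All nine derived variants are
#' rigid or reflecting, so pairwise distances - and hence all true body
#' dimensions - are preserved.
#'
#' @param clouds list of [pointcloud()]s (a single cloud is accepted).
#' @return List of `10 * length(clouds)` clouds, named with suffixes
#'   `_orig`, `_r045` ... `_r315`, `_mh`, `_mv`.
#' @export
augment_dataset <- function(clouds) {
  if (inherits(clouds, "pointcloud")) clouds <- list(clouds)
  if (length(clouds) == 0L) stop("augment_dataset: empty input")
  angles <- seq(45, 315, by = 45)
  out <- list()
  for (i in seq_along(clouds)) {
    cl <- clouds[[i]]
    ctr <- colMeans(coords(cl))
    base <- names(clouds)[i] %||% sprintf("cloud%03d", i)
    out[[paste0(base, "_orig")]] <- cl
    for (a in angles) {
      out[[sprintf("%s_r%03d", base, a)]] <-
        affine_transform(cl, rotation_vertical_cw(a), center = ctr)
    }
    out[[paste0(base, "_mh")]] <- affine_transform(cl, mirror_horizontal(), center = ctr)
    out[[paste0(base, "_mv")]] <- affine_transform(cl, mirror_vertical(), center = ctr)
  }
  out
}
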