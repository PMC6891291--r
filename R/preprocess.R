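#' Conditional range filter
#'
#' Keeps exactly the points whose coordinates fall inside the given closed
#' per-axis intervals, preserving stored order. Used to crop background at
#' different distances before any statistics are computed.
#'
#' @param cloud a [pointcloud()].
#' @param ranges named list with any of `x`, `y`, `z`, each `c(min, max)` in
#'   meters; omitted axes are unbounded.
#' @return The filtered [pointcloud()]. Warns (and errors on construction)
#'   if no point survives.
#' @export
conditional_filter <- function(cloud, ranges) {
  stopifnot(inherits(cloud, "pointcloud"))
  ranges <- ranges[!vapply(ranges, is.null, logical(1))]
  if (length(ranges) == 0L) stop("conditional_filter: bound at least one axis")
  pts <- coords(cloud)
  keep <- rep(TRUE, nrow(pts))
  for (ax in names(ranges)) {
    r <- ranges[[ax]]
    if (length(r) != 2L || r[1] >= r[2]) {
      stop("conditional_filter: range for axis '", ax, "' must be c(min, max) with min < max")
    }
    v <- pts[, ax]
    keep <- keep & v >= r[1] & v <= r[2]
  }
  if (!any(keep)) {
    warning("conditional_filter: no points survive the range bounds")
    return(structure(list(points = pts[0, , drop = FALSE],
                          frame_id = cloud$frame_id),
                     class = "pointcloud"))
  }
  subset_cloud(cloud, keep)
}

#' Statistical outlier removal
#'
#' For every point, the mean distance to its `knn_k` nearest neighbors is
#' computed; a point is kept iff that mean is at most the global mean plus
#' `alpha` standard deviations of the per-point means. Ties at the threshold
#' are kept, so the filter is deterministic.
#'
#' @param cloud a [pointcloud()].
#' @param knn_k neighbor count (default 8).
#' @param alpha standard-deviation multiplier (default 1.0).
#' @return The filtered [pointcloud()].
#' @export
statistical_outlier_removal <- function(cloud, knn_k = 8L, alpha = 1.0) {
  stopifnot(inherits(cloud, "pointcloud"))
  n <- npoints(cloud)
  if (knn_k < 1L) stop("knn_k must be at least 1")
  if (knn_k >= n) stop("statistical_outlier_removal: knn_k must be smaller than the cloud size")
  nn <- cpp_knn(coords(cloud), as.integer(knn_k))
  md <- rowMeans(nn$dist)
  sd_md <- stats::sd(md)
  if (!is.finite(sd_md)) sd_md <- 0
  keep <- md <= mean(md) + alpha * sd_md
  if (!any(keep)) stop("statistical_outlier_removal: all points removed")
  subset_cloud(cloud, keep)
}

#' Voxel-grid downsampling
#'
#' Partitions space into cubic cells of edge `leaf` (cell index =
#' `floor(coordinate / leaf)` per axis) and replaces the points of each
#' occupied cell by their centroid, compressing the cloud while preserving
#' its surface.
#'
#' @param cloud a [pointcloud()].
#' @param leaf voxel edge length in meters (default 0.02).
#' @return The downsampled [pointcloud()]; one point per occupied voxel, in
#'   first-occurrence order of the voxels.
#' @export
voxel_downsample <- function(cloud, leaf = 0.02) {
  stopifnot(inherits(cloud, "pointcloud"))
  if (!is.finite(leaf) || leaf <= 0) stop("leaf must be positive")
  pts <- coords(cloud)
  key <- paste(floor(pts[, 1] / leaf), floor(pts[, 2] / leaf),
               floor(pts[, 3] / leaf))
  f <- factor(key, levels = unique(key))
  out <- rowsum(pts, f, reorder = FALSE) / as.vector(table(f)[levels(f)])
  pointcloud(out, frame_id = cloud$frame_id)
}

#' Filtering fusion: conditional, statistical, then voxel
#'
#' Applies the three filters in their canonical order and reports per-stage
#' survivor counts via `message()`.
#'
#' @param cloud a [pointcloud()].
#' @param ranges per-axis bounds for [conditional_filter()]; `NULL` skips
#'   the stage.
#' @param knn_k,alpha parameters of [statistical_outlier_removal()].
#' @param leaf voxel edge for [voxel_downsample()].
#' @param verbose report per-stage survivor counts.
#' @return The preprocessed [pointcloud()].
#' @export
preprocess_cloud <- function(cloud, ranges = NULL, knn_k = 8L, alpha = 1.0,
                             leaf = 0.02, verbose = FALSE) {
  n0 <- npoints(cloud)
  if (!is.null(ranges)) cloud <- conditional_filter(cloud, ranges)
  n1 <- npoints(cloud)
  cloud <- statistical_outlier_removal(cloud, knn_k, alpha)
  n2 <- npoints(cloud)
  cloud <- voxel_downsample(cloud, leaf)
  if (verbose) {
    message(sprintf("preprocess: %d -> conditional %d -> statistical %d -> voxel %d",
                    n0, n1, n2, npoints(cloud)))
  }
  cloud
}
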