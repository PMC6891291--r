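#' Construct a point cloud
#'
#' A `pointcloud` is the universal currency between pipeline stages: an
#' n x 3 numeric matrix of metric (meter) coordinates with a `frame_id`
#' attribute recording the coordinate convention, either `"sensor"` (raw
#' device frame) or `"normalized"` (body-aligned frame with x = body length,
#' y = height, z = width).
#'
#' @param points numeric matrix or data frame with 3 columns (x, y, z) in
#'   meters; rows are points.
#' @param frame_id coordinate convention label, `"sensor"` or `"normalized"`.
#' @return An object of class `pointcloud`.
#' @examples
#' pc <- pointcloud(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
#' npoints(pc)
#' @export
pointcloud <- function(points, frame_id = "sensor") {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L) stop("points must have exactly 3 columns (x, y, z)")
  if (nrow(points) < 1L) stop("a pointcloud needs at least one point")
  if (!all(is.finite(points))) stop("pointcloud coordinates must all be finite")
  if (!frame_id %in% c("sensor", "normalized")) {
    stop("frame_id must be 'sensor' or 'normalized'")
  }
  dimnames(points) <- list(NULL, c("x", "y", "z"))
  structure(list(points = points, frame_id = frame_id), class = "pointcloud")
}

#' Number of points in a cloud
#' @param cloud a `pointcloud`.
#' @return Integer point count.
#' @export
npoints <- function(cloud) nrow(cloud$points)

#' Coordinate matrix of a cloud
#' @param cloud a `pointcloud`.
#' @return The n x 3 coordinate matrix (meters).
#' @export
coords <- function(cloud) cloud$points

#' Subset a cloud by point indices, preserving stored order
#' @param cloud a `pointcloud`.
#' @param idx integer indices (or logical mask) of points to keep.
#' @return A `pointcloud` with the selected points.
#' @export
subset_cloud <- function(cloud, idx) {
  pts <- cloud$points[idx, , drop = FALSE]
  if (nrow(pts) < 1L) stop("subset would leave an empty pointcloud")
  pointcloud(pts, frame_id = cloud$frame_id)
}

#' @export
print.pointcloud <- function(x, ...) {
  rng <- apply(x$points, 2, range)
  cat(sprintf("pointcloud: %d points, frame '%s'\n", npoints(x), x$frame_id))
  cat(sprintf("  extent x [%.3f, %.3f] y [%.3f, %.3f] z [%.3f, %.3f] m\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  invisible(x)
}
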