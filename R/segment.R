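#' Euclidean cluster extraction
#'
#' Computes the connected components of the graph linking points closer than
#' `tol`, discards components outside `[min_size, max_size]`, and returns
#' the surviving clusters largest-first as index sets into the cloud.
#'
#' @param cloud a [pointcloud()].
#' @param tol connection distance in meters.
#' @param min_size,max_size cluster size bounds.
#' @return List of integer index vectors, largest cluster first. Warns if no
#'   cluster falls in the size range.
#' @export
euclidean_cluster <- function(cloud, tol, min_size = 1L, max_size = Inf) {
  stopifnot(inherits(cloud, "pointcloud"))
  if (!is.finite(tol) || tol <= 0) stop("tol must be positive")
  lab <- cpp_cluster_labels(coords(cloud), tol)
  groups <- split(seq_along(lab), lab)
  sizes <- lengths(groups)
  groups <- groups[sizes >= min_size & sizes <= max_size]
  if (length(groups) == 0L) {
    warning("euclidean_cluster: no cluster within the size range")
    return(list())
  }
  unname(groups[order(lengths(groups), decreasing = TRUE)])
}

#' RANSAC plane fit
#'
#' Draws `max_iter` seeded 3-point hypotheses, keeps the one with the most
#' inliers (ties resolved toward the earlier iteration), then refits by
#' least squares (plane through the inlier centroid, normal = smallest
#' eigenvector of the inlier covariance). The plane is
#' `normal . p + offset = 0` with the unit normal oriented toward the cloud
#' centroid, so for a ground plane it points up toward the subject.
#'
#' @param cloud a [pointcloud()] with at least 3 points.
#' @param dist_thresh inlier distance threshold in meters.
#' @param max_iter number of random hypotheses.
#' @param seed integer seed; identical seeds give identical models.
#' @return A `plane_model`: list with `normal`, `offset`, `inlier_indices`.
#' @export
ransac_plane <- function(cloud, dist_thresh = 0.02, max_iter = 200L, seed = 1L) {
  stopifnot(inherits(cloud, "pointcloud"))
  pts <- coords(cloud)
  n <- nrow(pts)
  if (n < 3L) stop("ransac_plane: need at least 3 points")
  best <- NULL
  with_seed(seed, {
    for (it in seq_len(max_iter)) {
      tri <- pts[sample.int(n, 3L), , drop = FALSE]
      nv <- cross3(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
      nn <- sqrt(sum(nv^2))
      if (nn < 1e-12) next  # collinear draw
      nv <- nv / nn
      d <- abs(pts %*% nv - sum(nv * tri[1, ]))
      count <- sum(d <= dist_thresh)
      if (is.null(best) || count > best$count) {
        best <- list(normal = nv, point = tri[1, ], count = count)
      }
    }
  })
  if (is.null(best)) stop("ransac_plane: degenerate input (all sampled triples collinear)")
  # least-squares refit on the hypothesis inliers
  d <- abs(pts %*% best$normal - sum(best$normal * best$point))
  inl <- which(d <= dist_thresh)
  ctr <- colMeans(pts[inl, , drop = FALSE])
  cv <- crossprod(sweep(pts[inl, , drop = FALSE], 2, ctr)) / length(inl)
  ev <- eigen(cv, symmetric = TRUE)
  normal <- ev$vectors[, 3]
  normal <- normal / sqrt(sum(normal^2))
  if (sum(normal * (colMeans(pts) - ctr)) < 0) normal <- -normal
  offset <- -sum(normal * ctr)
  inlier <- which(abs(pts %*% normal + offset) <= dist_thresh)
  structure(list(normal = normal, offset = offset, inlier_indices = inlier),
            class = "plane_model")
}

#' Signed distance of points to a plane
#' @param pts n x 3 matrix or 3-vector.
#' @param plane a `plane_model` (or list with `normal`, `offset`).
#' @return Signed distances (positive on the normal side).
#' @export
plane_distance <- function(pts, plane) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  drop(pts %*% plane$normal + plane$offset)
}

#' Isolate the subject from a preprocessed scene
#'
#' Fits the ground with [ransac_plane()], removes its inliers, clusters the
#' remainder with [euclidean_cluster()] and returns the largest cluster as
#' the subject. The ground model is retained as the later height reference.
#'
#' @param cloud preprocessed scene [pointcloud()].
#' @param tol cluster connection distance.
#' @param min_size minimum cluster size.
#' @param dist_thresh,max_iter,seed RANSAC parameters.
#' @return List with `subject` ([pointcloud()]), `ground` (`plane_model`),
#'   and `subject_indices` into `cloud`.
#' @export
extract_subject <- function(cloud, tol = 0.06, min_size = 50L,
                            dist_thresh = 0.02, max_iter = 200L, seed = 1L) {
  ground <- ransac_plane(cloud, dist_thresh, max_iter, seed)
  keep <- setdiff(seq_len(npoints(cloud)), ground$inlier_indices)
  if (length(keep) == 0L) stop("extract_subject: ground removal left no points")
  rest <- subset_cloud(cloud, keep)
  clusters <- euclidean_cluster(rest, tol, min_size = min_size)
  if (length(clusters) == 0L) {
    stop("extract_subject: segmentation failed, no cluster of at least ",
         min_size, " points")
  }
  idx <- keep[clusters[[1]]]
  list(subject = subset_cloud(cloud, idx), ground = ground,
       subject_indices = idx)
}
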