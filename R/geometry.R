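#' Centroid of a point cloud
#' @param cloud a [pointcloud()].
#' @return 3-vector, the arithmetic mean of the coordinates.
#' @export
compute_centroid <- function(cloud) {
  stopifnot(inherits(cloud, "pointcloud"))
  colMeans(coords(cloud))
}

#' Covariance matrix of a point cloud
#'
#' Population covariance (1/n normalization) of the coordinates about the
#' given centroid; symmetric positive semidefinite.
#'
#' @param cloud a [pointcloud()] with at least 2 points.
#' @param centroid 3-vector; defaults to [compute_centroid()].
#' @return 3 x 3 covariance matrix.
#' @export
compute_covariance <- function(cloud, centroid = compute_centroid(cloud)) {
  stopifnot(inherits(cloud, "pointcloud"))
  pts <- coords(cloud)
  if (nrow(pts) < 2L) stop("compute_covariance: need at least 2 points")
  d <- sweep(pts, 2, centroid)
  crossprod(d) / nrow(d)
}

#' Body-aligned canonical frame from a covariance matrix
#'
#' Eigen-decomposes the covariance and assigns the axes by descending
#' eigenvalue: x = body length (largest spread), y = body height,
#' z = chest width. The frame is made right-handed by flipping the third
#' axis if necessary. Near-degenerate spectra (length and height spreads
#' almost equal) trigger an ambiguity warning.
#'
#' @param cov 3 x 3 symmetric PSD matrix.
#' @param centroid 3-vector frame origin.
#' @return A `canonical_frame`: list with `origin`, `axes` (3 x 3, rows
#'   e0/e1/e2), `eigenvalues` (descending).
#' @export
pca_frame <- function(cov, centroid = c(0, 0, 0)) {
  cov <- as.matrix(cov)
  if (!all(dim(cov) == c(3L, 3L)) || max(abs(cov - t(cov))) > 1e-8) {
    stop("pca_frame: cov must be a symmetric 3 x 3 matrix")
  }
  ev <- eigen(cov, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  axes <- t(ev$vectors)  # rows are eigenvectors, descending eigenvalue
  if (det(axes) < 0) axes[3, ] <- -axes[3, ]
  if (lam[1] <= .Machine$double.eps || (lam[1] - lam[2]) / lam[1] < 1e-3) {
    warning("pca_frame: leading eigenvalues nearly equal; axis assignment is ambiguous")
  }
  structure(list(origin = as.numeric(centroid), axes = axes,
                 eigenvalues = lam),
            class = "canonical_frame")
}

#' Map points between sensor and canonical coordinates
#' @param pts n x 3 matrix or 3-vector in the source frame.
#' @param frame a `canonical_frame`.
#' @param inverse if `TRUE`, map canonical coordinates back to the sensor
#'   frame.
#' @return Transformed coordinates, same shape as `pts`.
#' @export
frame_transform <- function(pts, frame, inverse = FALSE) {
  vec <- is.null(dim(pts))
  if (vec) pts <- matrix(pts, ncol = 3)
  out <- if (inverse) {
    sweep(pts %*% frame$axes, 2, frame$origin, `+`)
  } else {
    sweep(pts, 2, frame$origin) %*% t(frame$axes)
  }
  if (vec) drop(out) else out
}

#' Normalize the pose of a subject cloud
#'
#' Translates the cloud to its centroid and rotates it into the PCA frame
#' so that x spans body length, y body height and z chest width. The
#' returned cloud has `frame_id = "normalized"`. Axis senses (head
#' direction, up direction) remain ambiguous at this stage; see
#' [orientation_correct()] and the `up_hint` argument.
#'
#' @param cloud subject-only [pointcloud()].
#' @param up_hint optional 3-vector in sensor coordinates (e.g. the ground
#'   normal pointing toward the subject). With `align_up = FALSE` it only
#'   fixes the sign of the height axis (y and z are flipped together so the
#'   frame stays right-handed); with `align_up = TRUE` (the default when a
#'   hint is given) the height axis is set exactly to the hint and the
#'   length axis is re-orthogonalized against it. Exact alignment removes
#'   the pitch that off-axis body mass (the head and neck) induces in the
#'   raw PCA frame, which would otherwise corrupt the head/tail height
#'   comparison of [orientation_correct()].
#' @param align_up set the height axis exactly to `up_hint`.
#' @return List with `cloud` (normalized) and `frame` (`canonical_frame`).
#' @export
normalize_pose <- function(cloud, up_hint = NULL,
                           align_up = !is.null(up_hint)) {
  ctr <- compute_centroid(cloud)
  frame <- pca_frame(compute_covariance(cloud, ctr), ctr)
  if (!is.null(up_hint)) {
    up <- up_hint / sqrt(sum(up_hint^2))
    if (sum(frame$axes[2, ] * up) < 0) {
      frame$axes[2, ] <- -frame$axes[2, ]
      frame$axes[3, ] <- -frame$axes[3, ]
    }
    if (align_up) {
      e0 <- frame$axes[1, ]
      e0 <- e0 - sum(e0 * up) * up
      e0 <- e0 / sqrt(sum(e0^2))
      frame$axes <- rbind(e0, up, cross3(e0, up))
      dimnames(frame$axes) <- NULL
    }
  }
  out <- pointcloud(frame_transform(coords(cloud), frame),
                    frame_id = "normalized")
  list(cloud = out, frame = frame)
}

#' Orientation correction of a normalized cloud
#'
#' In the canonical frame the tail must point toward +x. The rule: split the
#' cloud at x = 0 into a +x half and a -x half and find each half's maximum
#' height; the half containing the higher maximum (the withers, on the head
#' side of a quadruped) must lie on -x. If it lies on +x the cloud is
#' mirrored by negating x; exactly zero or one mirror is applied, so the
#' operation is idempotent.
#'
#' @param cloud normalized [pointcloud()].
#' @return List with `cloud` (corrected) and `mirrored` (logical).
#' @export
orientation_correct <- function(cloud) {
  stopifnot(inherits(cloud, "pointcloud"))
  pts <- coords(cloud)
  q1_set <- pts[, 1] > 0
  q2_set <- pts[, 1] < 0
  if (!any(q1_set) || !any(q2_set)) {
    stop("orientation_correct: degenerate pose, one x half-space is empty")
  }
  q1 <- max(pts[q1_set, 2])
  q2 <- max(pts[q2_set, 2])
  mirrored <- q1 > q2
  if (mirrored) {
    cloud <- affine_transform(cloud, mirror_vertical())
  }
  list(cloud = cloud, mirrored = mirrored)
}

#' Normal curvature in a given direction (Euler's formula)
#' @param k1,k2 principal curvatures (1/m), `k1 >= k2`.
#' @param theta angle (radians) from the direction of `k1`.
#' @return `k1 * cos(theta)^2 + k2 * sin(theta)^2`.
#' @export
normal_curvature_euler <- function(k1, k2, theta) {
  if (any(k1 < k2)) stop("principal curvatures must satisfy k1 >= k2")
  k1 * cos(theta)^2 + k2 * sin(theta)^2
}

#' Mean and Gaussian curvature from the principal curvatures
#' @param k1,k2 principal curvatures (1/m), `k1 >= k2`.
#' @return Named vector `c(H = (k1 + k2) / 2, K = k1 * k2)`.
#' @export
mean_gaussian_curvature <- function(k1, k2) {
  if (any(k1 < k2)) stop("principal curvatures must satisfy k1 >= k2")
  c(H = (k1 + k2) / 2, K = k1 * k2)
}

#' Surface type from curvature signs
#'
#' Signs are taken as zero within the tolerances `eps_H`, `eps_K`. The eight
#' realizable combinations map to: (-,-) saddle_valley, (-,0) valley,
#' (-,+) well, (0,0) plane, (0,-) minimal_saddle, (+,-) saddle_ridge,
#' (+,0) ridge, (+,+) peak. The ninth combination (H = 0, K > 0) is
#' mathematically impossible (K <= H^2 always) and is rejected.
#'
#' @param H,K mean and Gaussian curvature (vectorized).
#' @param eps_H,eps_K positive zero-band half-widths.
#' @return Character vector of surface types.
#' @export
classify_surface_type <- function(H, K, eps_H, eps_K) {
  if (eps_H <= 0 || eps_K <= 0) stop("eps thresholds must be positive")
  sH <- sign(H) * (abs(H) > eps_H)
  sK <- sign(K) * (abs(K) > eps_K)
  if (any(sH == 0 & sK > 0)) {
    stop("impossible curvature combination: H = 0 with K > 0")
  }
  key <- paste(sH, sK)
  map <- c("-1 -1" = "saddle_valley", "-1 0" = "valley", "-1 1" = "well",
           "0 0" = "plane", "0 -1" = "minimal_saddle",
           "1 -1" = "saddle_ridge", "1 0" = "ridge", "1 1" = "peak")
  unname(map[key])
}

#' Surface type levels
#' @return Character vector of the eight realizable surface types.
#' @export
surface_types <- function() {
  c("saddle_valley", "valley", "well", "plane", "minimal_saddle",
    "saddle_ridge", "ridge", "peak")
}

#' Estimate outward surface normals
#'
#' Per point, the smallest eigenvector of the local k-neighborhood
#' covariance, oriented away from the cloud centroid so convex body regions
#' face outward.
#'
#' @param cloud a [pointcloud()].
#' @param knn_k neighborhood size (default 16).
#' @return n x 3 matrix of unit normals.
#' @export
estimate_normals <- function(cloud, knn_k = 16L) {
  pts <- coords(cloud)
  n <- nrow(pts)
  if (knn_k >= n) stop("estimate_normals: knn_k must be smaller than the cloud size")
  nn <- cpp_knn(pts, as.integer(knn_k))
  ctr <- colMeans(pts)
  normals <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    nb <- pts[c(i, nn$idx[i, ]), , drop = FALSE]
    cv <- crossprod(sweep(nb, 2, colMeans(nb)))
    v <- eigen(cv, symmetric = TRUE)$vectors[, 3]
    if (sum(v * (pts[i, ] - ctr)) < 0) v <- -v
    normals[i, ] <- v
  }
  normals
}

#' Per-point principal, mean and Gaussian curvature with surface typing
#'
#' For each point a quadric height field
#' `z = a + b u + c v + d u^2 + e u v + f v^2` is fitted by least squares
#' over its k-neighborhood in a local tangent frame whose z axis is the
#' inward normal (so convex regions get H > 0 under the outward-normal
#' convention). The first and second fundamental-form derivatives at the
#' point (`Ix = b`, `Iy = c`, `Ixx = 2d`, `Ixy = e`, `Iyy = 2f`) give the
#' mean and Gaussian curvature of the Monge patch, from which
#' `k1, k2 = H +/- sqrt(H^2 - K)`. Points with rank-deficient neighborhoods
#' are flagged invalid and excluded from candidate regions.
#'
#' The default zero-band thresholds scale with each point's neighborhood
#' radius r: `eps_H = 0.05 / r`, `eps_K = 0.01 / r^2`. Because
#' `eps_K >= eps_H^2`, the impossible combination (H = 0, K > 0) cannot be
#' produced by real fits.
#'
#' @param cloud a [pointcloud()].
#' @param knn_k neighborhood size, at least 6 (default 16).
#' @param eps_scale_H,eps_scale_K dimensionless zero-band scales.
#' @return A `curvature_field` data frame with columns `k1`, `k2`, `H`, `K`,
#'   `type`, `valid`, plus the normals in `attr(, "normals")`.
#' @export
principal_curvatures <- function(cloud, knn_k = 16L,
                                 eps_scale_H = 0.05, eps_scale_K = 0.01) {
  if (knn_k < 6L) stop("principal_curvatures: knn_k must be at least 6 (quadric has 6 coefficients)")
  pts <- coords(cloud)
  n <- nrow(pts)
  if (knn_k >= n) stop("principal_curvatures: knn_k must be smaller than the cloud size")
  nn <- cpp_knn(pts, as.integer(knn_k))
  normals <- estimate_normals(cloud, knn_k)
  H <- K <- k1 <- k2 <- rep(NA_real_, n)
  valid <- rep(FALSE, n)
  type <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    nrm <- normals[i, ]
    zax <- -nrm  # inward z so that convex-outward surfaces get H > 0
    ref <- if (abs(zax[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    u1 <- cross3(zax, ref); u1 <- u1 / sqrt(sum(u1^2))
    u2 <- cross3(zax, u1)
    nb <- sweep(pts[nn$idx[i, ], , drop = FALSE], 2, pts[i, ])
    uu <- nb %*% u1; vv <- nb %*% u2; zz <- nb %*% zax
    A <- cbind(1, uu, vv, uu^2, uu * vv, vv^2)
    qr_A <- qr(A)
    if (qr_A$rank < 6L) next
    cf <- qr.coef(qr_A, zz)
    Ix <- cf[2]; Iy <- cf[3]; Ixx <- 2 * cf[4]; Ixy <- cf[5]; Iyy <- 2 * cf[6]
    w <- 1 + Ix^2 + Iy^2
    H[i] <- ((1 + Ix^2) * Iyy - 2 * Ix * Iy * Ixy + (1 + Iy^2) * Ixx) /
      (2 * w^1.5)
    K[i] <- (Ixx * Iyy - Ixy^2) / w^2
    disc <- sqrt(max(0, H[i]^2 - K[i]))
    k1[i] <- H[i] + disc
    k2[i] <- H[i] - disc
    r <- mean(nn$dist[i, ])
    type[i] <- classify_surface_type(H[i], K[i],
                                     eps_H = eps_scale_H / r,
                                     eps_K = eps_scale_K / r^2)
    valid[i] <- TRUE
  }
  out <- data.frame(k1 = k1, k2 = k2, H = H, K = K,
                    type = type, valid = valid, stringsAsFactors = FALSE)
  attr(out, "normals") <- normals
  class(out) <- c("curvature_field", "data.frame")
  out
}

#' Candidate regions for each landmark
#'
#' Filters the typed points by each landmark's allowed surface types and an
#' optional x-band given as fractions of the cloud's x extent, returning
#' per-landmark index sets in stored point order (recognition later scans
#' them in this saving order).
#'
#' @param field a `curvature_field` from [principal_curvatures()].
#' @param cloud the matching normalized, orientation-corrected
#'   [pointcloud()].
#' @param mapping named list, one entry per landmark: `list(types =
#'   character(), xband = c(lo, hi), yband = c(lo, hi), zband = c(lo, hi))`
#'   with bands in `[0, 1]` fractions of the respective coordinate extent
#'   (`NULL` = unrestricted). See [default_landmark_mapping()].
#' @return Named list of integer index vectors. Landmarks with no candidate
#'   get an empty vector and a warning.
#' @export
candidate_regions <- function(field, cloud, mapping = default_landmark_mapping()) {
  pts <- coords(cloud)
  xr <- range(pts[, 1])
  yr <- range(pts[, 2])
  zr <- range(pts[, 3])
  xfrac <- (pts[, 1] - xr[1]) / (xr[2] - xr[1])
  yfrac <- (pts[, 2] - yr[1]) / (yr[2] - yr[1])
  zfrac <- (pts[, 3] - zr[1]) / (zr[2] - zr[1])
  out <- list()
  for (lm in names(mapping)) {
    spec <- mapping[[lm]]
    keep <- field$valid & field$type %in% spec$types
    if (!is.null(spec$xband)) {
      keep <- keep & xfrac >= spec$xband[1] & xfrac <= spec$xband[2]
    }
    if (!is.null(spec$yband)) {
      keep <- keep & yfrac >= spec$yband[1] & yfrac <= spec$yband[2]
    }
    if (!is.null(spec$zband)) {
      keep <- keep & zfrac >= spec$zband[1] & zfrac <= spec$zband[2]
    }
    idx <- which(keep)
    if (length(idx) == 0L) {
      warning("candidate_regions: no candidates for landmark '", lm, "'")
    }
    out[[lm]] <- idx
  }
  out
}

#' Default landmark-to-surface-type mapping
#'
#' Allowed surface types plus x-, y- and z-bands (fractions of the
#' subject's extent in the canonical frame; x: head at 0, tail at 1; y:
#' hooves at 0, withers at 1; z: centered on the sagittal midline, where all
#' six landmarks lie) for the six landmarks of a standing quadruped. Upper
#' landmarks sit on the convex back line (peak or ridge, top height band);
#' the chest lower point is the sternum keel behind the forelegs - also
#' locally convex, but isolated from the back line by its low height band;
#' the body length end points are the high-curvature front and rear torso
#' ends at mid height.
#'
#' @return Named list understood by [candidate_regions()].
#' @export
default_landmark_mapping <- function() {
  top <- c("peak", "ridge", "saddle_ridge")
  mid <- c(0.36, 0.64)
  list(
    withers_upper = list(types = c("peak", "ridge"), xband = c(0.30, 0.47),
                         yband = c(0.9, 1.0), zband = mid),
    chest_lower   = list(types = c(top, "minimal_saddle"),
                         xband = c(0.38, 0.58), yband = c(0.15, 0.45),
                         zband = mid),
    back_upper    = list(types = top, xband = c(0.55, 0.75),
                         yband = c(0.8, 1.0), zband = mid),
    waist_upper   = list(types = top, xband = c(0.80, 0.95),
                         yband = c(0.8, 1.0), zband = mid),
    bodylen_upper = list(types = top, xband = c(0.95, 1.0),
                         yband = c(0.45, 0.9), zband = mid),
    bodylen_lower = list(types = top, xband = c(0.18, 0.30),
                         yband = c(0.45, 0.9), zband = mid)
  )
}
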