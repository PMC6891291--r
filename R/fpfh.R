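#' Fast point feature histogram (FPFH) descriptor
#'
#' Computes the 33-bin FPFH of one point: three 11-bin histograms of the
#' Darboux-frame angular features (alpha, phi, theta) between the point's
#' normal and its radius neighborhood, where the point's simplified
#' histogram (SPFH) is blended with the distance-weighted SPFHs of its
#' neighbors. Each 11-bin block is normalized to sum to 100, which makes the
#' descriptor invariant to neighborhood size; it is invariant to rigid
#' transforms by construction.
#'
#' @param cloud a [pointcloud()].
#' @param index point index (1-based) to describe.
#' @param radius neighborhood radius in meters.
#' @param normals optional n x 3 unit normal matrix (from
#'   [estimate_normals()]); computed on demand if missing.
#' @return An `fpfh_descriptor`: list with `bins` (33 values) and `radius`.
#' @export
compute_fpfh <- function(cloud, index, radius, normals = NULL) {
  pts <- coords(cloud)
  if (is.null(normals)) normals <- estimate_normals(cloud)
  bins <- cpp_fpfh(pts, normals, as.integer(index), radius)[1, ]
  if (anyNA(bins)) {
    stop("compute_fpfh: fewer than 5 neighbors within radius; descriptor undefined")
  }
  structure(list(bins = as.numeric(bins), radius = radius),
            class = "fpfh_descriptor")
}

# Pure-R FPFH used as a cross-check of the compiled implementation.
fpfh_reference <- function(cloud, index, radius, normals = NULL) {
  pts <- coords(cloud)
  if (is.null(normals)) normals <- estimate_normals(cloud)
  nb <- cpp_radius_neighbors(pts, as.integer(index), radius)[[1]]
  if (length(nb) < 5L) {
    stop("fpfh_reference: fewer than 5 neighbors within radius")
  }
  centers <- c(index, nb)
  all_nb <- cpp_radius_neighbors(pts, as.integer(centers), radius)
  spfh <- lapply(seq_along(centers), function(j) {
    spfh_histogram(pts, normals, centers[j], all_nb[[j]])
  })
  d <- sqrt(rowSums(sweep(pts[nb, , drop = FALSE], 2, pts[index, ])^2))
  w <- 1 / pmax(d, 1e-9)
  bins <- spfh[[1]]
  acc <- Reduce(`+`, Map(function(s, wi) s * wi, spfh[-1], w))
  bins <- bins + acc / length(nb)
  for (b in 0:2) {
    blk <- b * 11 + 1:11
    s <- sum(bins[blk])
    if (s > 0) bins[blk] <- bins[blk] / s * 100
  }
  structure(list(bins = as.numeric(bins), radius = radius),
            class = "fpfh_descriptor")
}

# Simplified point feature histogram: 3 x 11 binned angular features of the
# pairs (p, q) for q in the neighborhood of p.
spfh_histogram <- function(pts, normals, i, nb) {
  bins <- numeric(33)
  if (length(nb) == 0L) return(bins)
  p <- pts[i, ]; np <- normals[i, ]
  for (j in nb) {
    dvec <- pts[j, ] - p
    dist <- sqrt(sum(dvec^2))
    if (dist < 1e-12) next
    dn <- dvec / dist
    u <- np
    v <- cross3(dn, u)
    vn <- sqrt(sum(v^2))
    if (vn < 1e-9) {
      # degenerate: displacement parallel to the normal
      v <- cross3(u, if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0))
      vn <- sqrt(sum(v^2))
    }
    v <- v / vn
    w <- cross3(u, v)
    nq <- normals[j, ]
    alpha <- sum(v * nq)                      # [-1, 1]
    phi <- sum(u * dn)                        # [-1, 1]
    theta <- atan2(sum(w * nq), sum(u * nq))  # (-pi, pi]
    bins[bin11(alpha, -1, 1)] <- bins[bin11(alpha, -1, 1)] + 1
    b2 <- 11 + bin11(phi, -1, 1)
    bins[b2] <- bins[b2] + 1
    b3 <- 22 + bin11(theta, -pi, pi)
    bins[b3] <- bins[b3] + 1
  }
  bins
}

bin11 <- function(x, lo, hi) {
  min(11L, max(1L, 1L + floor((x - lo) / (hi - lo) * 11)))
}

#' L1 distance between two FPFH descriptors
#' @param a,b `fpfh_descriptor`s.
#' @return Non-negative scalar.
#' @export
fpfh_distance <- function(a, b) sum(abs(a$bins - b$bins))

landmark_names <- function() {
  c("withers_upper", "chest_lower", "back_upper", "waist_upper",
    "bodylen_upper", "bodylen_lower")
}

#' Build a feature-model database of reference landmark descriptors
#'
#' Stores one or more reference FPFH descriptors per landmark. All six
#' landmarks (withers_upper, chest_lower, back_upper, waist_upper,
#' bodylen_upper, bodylen_lower) must be covered. If `tau` is `NULL` it is
#' calibrated from the database itself, per landmark: the largest L1
#' distance between that landmark's reference descriptors (floored at the
#' median such spread across landmarks, which stabilizes the estimate when
#' references are few) times a 1.25 margin. Calibration requires at least
#' two examples per landmark.
#'
#' @param examples list of `list(landmark = name, cloud = pointcloud,
#'   index = point index)` reference examples.
#' @param radius FPFH neighborhood radius in meters.
#' @param tau match threshold (same L1 metric): a scalar, a named
#'   per-landmark vector, or `NULL` to calibrate per landmark.
#' @return A `feature_model_db`: list with `entries` (landmark -> list of
#'   descriptors), `tau` (named per-landmark vector or scalar), `radius`.
#' @export
build_feature_db <- function(examples, radius = 0.10, tau = NULL) {
  entries <- stats::setNames(vector("list", 6), landmark_names())
  for (ex in examples) {
    if (!ex$landmark %in% landmark_names()) {
      stop("unknown landmark name: ", ex$landmark)
    }
    desc <- compute_fpfh(ex$cloud, ex$index, radius,
                         normals = ex$normals %||% NULL)
    entries[[ex$landmark]] <- c(entries[[ex$landmark]], list(desc))
  }
  missing <- names(entries)[vapply(entries, is.null, logical(1))]
  if (length(missing) > 0L) {
    stop("incomplete feature database, missing landmark(s): ",
         paste(missing, collapse = ", "))
  }
  if (is.null(tau)) {
    spread <- vapply(entries, function(ds) {
      if (length(ds) < 2L) return(NA_real_)
      cmb <- utils::combn(length(ds), 2)
      max(apply(cmb, 2, function(p) fpfh_distance(ds[[p[1]]], ds[[p[2]]])))
    }, numeric(1))
    if (anyNA(spread)) {
      stop("tau calibration needs at least two examples per landmark; pass tau explicitly")
    }
    # per-landmark thresholds: descriptor variability differs strongly
    # between compact bumps (withers) and extended rims (body ends). With
    # few references per landmark the max-spread estimate is noisy, so each
    # landmark's spread is floored at the median spread across landmarks.
    tau <- 1.25 * pmax(spread, stats::median(spread))
  }
  if (any(tau <= 0)) stop("tau must be positive")
  structure(list(entries = entries, tau = tau, radius = radius),
            class = "feature_model_db")
}

#' Save / load a feature-model database as JSON
#' @param db a `feature_model_db`.
#' @param path file path.
#' @return `path` (save) or the `feature_model_db` (load).
#' @export
save_feature_db <- function(db, path) {
  # doubles stored as %.17g strings so the round trip is bit-exact
  tau_out <- if (is.null(names(db$tau))) fmt_dbl(db$tau) else
    as.list(stats::setNames(fmt_dbl(db$tau), names(db$tau)))
  obj <- list(tau = tau_out, radius = fmt_dbl(db$radius),
              entries = lapply(db$entries, function(ds) {
                lapply(ds, function(d) fmt_dbl(d$bins))
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

fmt_dbl <- function(x) sprintf("%.17g", x)

#' @rdname save_feature_db
#' @export
read_feature_db <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  radius <- as.numeric(obj$radius)
  entries <- lapply(obj$entries, function(ds) {
    lapply(ds, function(bins) {
      structure(list(bins = as.numeric(unlist(bins)), radius = radius),
                class = "fpfh_descriptor")
    })
  })
  tau <- unlist(obj$tau)
  tau <- stats::setNames(as.numeric(tau), names(tau))
  structure(list(entries = entries, tau = tau, radius = radius),
            class = "feature_model_db")
}

#' First-match landmark recognition
#'
#' Scans the candidate indices in their stored (saving) order, computes each
#' candidate's FPFH and returns the first whose L1 distance to any reference
#' descriptor of the landmark is within the database threshold `tau`. There
#' is no global-best search: the first hit stops the scan.
#'
#' @param candidates ordered integer index vector (from
#'   [candidate_regions()]).
#' @param cloud the [pointcloud()] the indices refer to.
#' @param landmark landmark name (one of [landmark_names]).
#' @param db a `feature_model_db`.
#' @param normals optional precomputed normals.
#' @return The matched point index.
#' @export
match_feature_point <- function(candidates, cloud, landmark, db,
                                normals = NULL) {
  if (length(candidates) == 0L) {
    stop("match_feature_point: empty candidate set for '", landmark, "'")
  }
  refs <- db$entries[[landmark]]
  if (is.null(refs)) stop("feature database has no entry for '", landmark, "'")
  tau <- if (is.null(names(db$tau))) db$tau[1] else db$tau[[landmark]]
  if (is.null(tau) || is.na(tau)) {
    stop("feature database has no threshold for '", landmark, "'")
  }
  if (is.null(normals)) normals <- estimate_normals(cloud)
  for (idx in candidates) {
    desc <- tryCatch(compute_fpfh(cloud, idx, db$radius, normals = normals),
                     error = function(e) NULL)
    if (is.null(desc)) next
    for (ref in refs) {
      if (fpfh_distance(desc, ref) <= tau) return(idx)
    }
  }
  stop("match_feature_point: no candidate within tau for landmark '",
       landmark, "'")
}
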