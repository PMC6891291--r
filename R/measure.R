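#' Derive the auxiliary measurement points
#'
#' The withers/back/waist lower points are the vertical projections of the
#' matched upper landmarks onto the ground plane (same x and z, ground
#' height as y). The chest upper point is the highest cloud point within a
#' small (x, z) cylinder around the chest lower point, i.e. the back line
#' directly above the sternum.
#'
#' @param landmarks named list of six 3-vectors (the matched landmarks).
#' @param ground a `plane_model` in the same frame as `landmarks`.
#' @param cloud the subject [pointcloud()] in the same frame.
#' @param cyl_radius (x, z) search radius for the chest upper point, meters.
#' @return Named list of auxiliary 3-vectors: `withers_lower`, `back_lower`,
#'   `waist_lower`, `chest_upper`.
#' @export
derive_auxiliary_points <- function(landmarks, ground, cloud,
                                    cyl_radius = 0.05) {
  n <- ground$normal
  if (abs(n[2]) < 1e-6) {
    stop("derive_auxiliary_points: ground plane is vertical in this frame")
  }
  ground_y_at <- function(p) -(ground$offset + n[1] * p[1] + n[3] * p[3]) / n[2]
  drop_to_ground <- function(p) c(p[1], ground_y_at(p), p[3])
  pts <- coords(cloud)
  cl <- landmarks$chest_lower
  # Grow the search cylinder if sampling left no back-line point inside:
  # a valid chest upper point must sit clearly above the sternum.
  r <- cyl_radius
  chest_upper <- NULL
  while (is.null(chest_upper) && r <= 8 * cyl_radius) {
    in_cyl <- (pts[, 1] - cl[1])^2 + (pts[, 3] - cl[3])^2 <= r^2
    if (any(in_cyl)) {
      cand <- pts[which(in_cyl)[which.max(pts[in_cyl, 2])], ]
      if (cand[2] > cl[2] + 4 * cyl_radius) chest_upper <- cand
    }
    r <- r * 1.5
  }
  if (is.null(chest_upper)) {
    stop("derive_auxiliary_points: no cloud points above the chest lower point")
  }
  list(withers_lower = drop_to_ground(landmarks$withers_upper),
       back_lower = drop_to_ground(landmarks$back_upper),
       waist_lower = drop_to_ground(landmarks$waist_upper),
       chest_upper = as.numeric(chest_upper))
}

#' Compute the five body dimensions
#'
#' Withers, back and waist heights are the perpendicular distances of their
#' upper landmarks to the ground plane; chest depth is the separation of the
#' chest upper and lower points along the ground normal; body length is the
#' straight-line 3D distance between its two end landmarks.
#'
#' @param landmarks named list of six matched 3-vectors.
#' @param auxiliary output of [derive_auxiliary_points()].
#' @param ground a `plane_model`.
#' @return A `body_dimensions`: list with the five measurements (meters),
#'   the provenance `landmarks` (matched plus auxiliary) and `ground`.
#' @export
compute_dimensions <- function(landmarks, auxiliary, ground) {
  h <- function(p) abs(plane_distance(p, ground))
  dims <- list(
    withers_height = h(landmarks$withers_upper),
    chest_depth = abs(sum((auxiliary$chest_upper - landmarks$chest_lower) *
                            ground$normal)),
    back_height = h(landmarks$back_upper),
    waist_height = h(landmarks$waist_upper),
    body_length = sqrt(sum((landmarks$bodylen_upper - landmarks$bodylen_lower)^2))
  )
  if (any(unlist(dims) <= 0)) stop("compute_dimensions: non-positive dimension")
  structure(c(dims, list(landmarks = c(landmarks, auxiliary), ground = ground)),
            class = "body_dimensions")
}

#' @export
print.body_dimensions <- function(x, ...) {
  cat("body dimensions (m):\n")
  for (d in dimension_names()) cat(sprintf("  %-15s %.3f\n", d, x[[d]]))
  invisible(x)
}

dimension_names <- function() {
  c("withers_height", "chest_depth", "back_height", "waist_height",
    "body_length")
}

round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Automatic-versus-manual error report
#'
#' Per dimension, `error_percent = 100 * |automatic - manual| / manual`,
#' rounded half-up to 2 decimals. The manual (human-interaction) value is
#' the denominator.
#'
#' @param automatic a `body_dimensions` or named numeric vector of the five
#'   dimensions (meters).
#' @param manual named numeric vector of the five manual reference values
#'   (meters), all positive.
#' @return Data frame with columns `dimension`, `automatic`, `manual`,
#'   `error_percent`.
#' @export
error_report <- function(automatic, manual) {
  auto <- if (inherits(automatic, "body_dimensions")) {
    vapply(dimension_names(), function(d) automatic[[d]], numeric(1))
  } else {
    automatic[dimension_names()]
  }
  manual <- manual[dimension_names()]
  if (any(is.na(manual)) || any(manual <= 0)) {
    stop("error_report: manual reference values must be positive and complete")
  }
  if (any(is.na(auto))) stop("error_report: automatic measurements incomplete")
  data.frame(
    dimension = dimension_names(),
    automatic = as.numeric(auto),
    manual = as.numeric(manual),
    error_percent = round_half_up(100 * abs(auto - manual) / manual),
    row.names = NULL
  )
}

#' Reference body-dimension measurements of three cattle
#'
#' Published automatic and manual (human-machine interaction) measurements
#' (meters) of three adult Qinchuan cattle, with the printed error
#' percentages; used to validate the error arithmetic.
#'
#' @return Data frame with columns `animal`, `dimension`, `automatic`,
#'   `manual`, `error_percent`.
#' @export
qinchuan_reference <- function() {
  dims <- dimension_names()
  data.frame(
    animal = rep(c("Q0392", "Q0526", "Q0456"), each = 5),
    dimension = rep(dims, 3),
    automatic = c(1.213, 0.629, 1.124, 1.186, 1.387,
                  1.256, 0.610, 1.082, 1.239, 1.410,
                  1.242, 0.635, 1.133, 1.169, 1.615),
    manual = c(1.211, 0.630, 1.110, 1.175, 1.355,
               1.255, 0.619, 1.095, 1.237, 1.414,
               1.238, 0.637, 1.134, 1.166, 1.612),
    error_percent = c(0.17, 0.16, 1.26, 0.94, 2.36,
                      0.08, 1.45, 1.19, 0.16, 0.28,
                      0.32, 0.31, 0.09, 0.26, 0.19)
  )
}

# Rigid-transform a plane model into the canonical frame (and through the
# optional x mirror applied by orientation correction).
transform_plane <- function(plane, frame, mirrored = FALSE) {
  n2 <- drop(frame$axes %*% plane$normal)
  off2 <- sum(plane$normal * frame$origin) + plane$offset
  if (mirrored) n2[1] <- -n2[1]
  list(normal = n2, offset = off2)
}

#' Full measurement pipeline for one scene
#'
#' Runs preprocess, subject isolation, optional classifier gating, pose
#' normalization, orientation correction, curvature typing, candidate
#' extraction, FPFH first-match landmark recognition, auxiliary points and
#' the five dimensions. All measurements are taken against the RANSAC ground
#' plane carried through the normalization transform, so heights are
#' perpendicular distances to the fitted ground. If no candidate of a
#' landmark passes the match threshold (a descriptor outlier), the pipeline
#' degrades gracefully: it warns and takes the candidate with the smallest
#' descriptor distance inside that landmark's anatomical band.
#'
#' @param scene a sensor-frame [pointcloud()].
#' @param db a `feature_model_db`.
#' @param params pipeline parameters, see [measure_params()].
#' @param gate_model optional trained 2-class classifier; when supplied, the
#'   isolated subject must classify as `"cattle"` or the pipeline aborts.
#' @param manual optional named vector of manual reference values; when
#'   given an [error_report()] is attached.
#' @param seed seed for the RANSAC draws (and the gate's tree build).
#' @return List with `dimensions` (`body_dimensions`), `landmark_indices`,
#'   `frame`, `mirrored`, `ground` (canonical-frame plane), and `report`
#'   (or `NULL`).
#' @export
measure_pipeline <- function(scene, db, params = measure_params(),
                             gate_model = NULL, manual = NULL, seed = 1L) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("measure_pipeline failed at stage '%s': %s",
                   name, conditionMessage(e)), call. = FALSE)
    })
  }
  pre <- stage("preprocess", preprocess_cloud(
    scene, ranges = params$ranges, knn_k = params$sor_k,
    alpha = params$sor_alpha, leaf = params$leaf))
  seg <- stage("segment", extract_subject(
    pre, tol = params$cluster_tol, min_size = params$cluster_min,
    dist_thresh = params$plane_thresh, max_iter = params$ransac_iter,
    seed = seed))
  np <- stage("normalize", normalize_pose(seg$subject,
                                          up_hint = seg$ground$normal))
  oc <- stage("orient", orientation_correct(np$cloud))
  subject <- oc$cloud
  if (!is.null(gate_model)) {
    # gate on the pose-normalized subject: the classifier was trained on
    # body-frame silhouettes
    res <- stage("classify", classify_cloud(gate_model, subject, seed = seed))
    if (res$label != "cattle") {
      stop("measure_pipeline: subject rejected by the classifier gate (label '",
           res$label, "', score ", signif(res$score, 3), ")")
    }
  }
  ground_c <- transform_plane(seg$ground, np$frame, oc$mirrored)
  ground_c <- structure(ground_c, class = "plane_model")
  field <- stage("curvature", principal_curvatures(subject, params$curv_k))
  # Canonical saving order: most curvature-salient points first, so the
  # first-match scan visits bump/dip centers before their flanks.
  sal <- abs(field$k1) + abs(field$k2)
  sal[!field$valid] <- -Inf
  ord <- order(sal, decreasing = TRUE)
  subject <- subset_cloud(subject, ord)
  normals <- attr(field, "normals")[ord, , drop = FALSE]
  field <- field[ord, , drop = FALSE]
  cands <- stage("candidates",
                 candidate_regions(field, subject, params$mapping))
  lm_idx <- stage("match", {
    out <- list()
    for (lm in landmark_names()) {
      out[[lm]] <- tryCatch(
        match_feature_point(cands[[lm]], subject, lm, db, normals = normals),
        error = function(e) {
          if (!grepl("no candidate within tau", conditionMessage(e)) ||
              length(cands[[lm]]) == 0L) {
            stop(e)
          }
          # degraded mode: no candidate passed the threshold (descriptor
          # outlier); fall back to the best-scoring candidate in the region
          warning("landmark '", lm, "': no candidate within tau, ",
                  "falling back to the nearest descriptor", call. = FALSE)
          dists <- vapply(cands[[lm]], function(idx) {
            d <- tryCatch(compute_fpfh(subject, idx, db$radius,
                                       normals = normals),
                          error = function(e2) NULL)
            if (is.null(d)) return(Inf)
            min(vapply(db$entries[[lm]], fpfh_distance, numeric(1), a = d))
          }, numeric(1))
          cands[[lm]][which.min(dists)]
        })
    }
    out
  })
  pts <- coords(subject)
  landmarks <- lapply(lm_idx, function(i) pts[i, ])
  aux <- stage("auxiliary", derive_auxiliary_points(
    landmarks, ground_c, subject, cyl_radius = params$chest_cyl_radius))
  dims <- stage("dimensions", compute_dimensions(landmarks, aux, ground_c))
  report <- if (!is.null(manual)) error_report(dims, manual) else NULL
  list(dimensions = dims, landmark_indices = lm_idx, frame = np$frame,
       mirrored = oc$mirrored, ground = ground_c, report = report,
       subject = subject)
}

#' Measurement pipeline parameters
#'
#' Defaults preserve a subject of roughly ten thousand points after
#' filtering: generous range bounds, statistical filter k = 8 and alpha = 1,
#' a 0.02 m voxel leaf, 0.06 m cluster tolerance and a 0.02 m ground inlier
#' threshold.
#'
#' @param ranges conditional-filter bounds (`NULL` skips the stage).
#' @param sor_k,sor_alpha statistical outlier removal parameters.
#' @param leaf voxel leaf (m).
#' @param cluster_tol,cluster_min Euclidean clustering parameters.
#' @param plane_thresh,ransac_iter RANSAC ground-fit parameters.
#' @param curv_k curvature/normals neighborhood size.
#' @param mapping landmark mapping, see [default_landmark_mapping()].
#' @param chest_cyl_radius chest upper-point search radius (m).
#' @return Parameter list for [measure_pipeline()].
#' @export
measure_params <- function(ranges = list(x = c(-6, 6), y = c(-6, 6), z = c(-6, 6)),
                           sor_k = 8L, sor_alpha = 1.0, leaf = 0.02,
                           cluster_tol = 0.06, cluster_min = 200L,
                           plane_thresh = 0.02, ransac_iter = 200L,
                           curv_k = 16L,
                           mapping = default_landmark_mapping(),
                           chest_cyl_radius = 0.05) {
  list(ranges = ranges, sor_k = sor_k, sor_alpha = sor_alpha, leaf = leaf,
       cluster_tol = cluster_tol, cluster_min = cluster_min,
       plane_thresh = plane_thresh, ransac_iter = ransac_iter,
       curv_k = curv_k, mapping = mapping,
       chest_cyl_radius = chest_cyl_radius)
}

#' Build a reference feature database from generator animals
#'
#' Generates held-out scenes, runs them through preprocessing, subject
#' isolation and pose normalization, snaps the true landmark positions to
#' their nearest cloud points and stores those points' FPFH descriptors as
#' the reference database. This mirrors how a per-herd feature-model
#' database would be assembled from manually annotated animals.
#'
#' @param seeds integer seeds of the reference animals.
#' @param config [scene_config()] used to generate them.
#' @param params [measure_params()].
#' @param radius FPFH radius (m).
#' @param tau match threshold; `NULL` calibrates from the cross-animal
#'   descriptor spread (needs at least 2 seeds).
#' @return A `feature_model_db`.
#' @export
build_reference_db <- function(seeds, config = scene_config(),
                               params = measure_params(), radius = 0.10,
                               tau = NULL) {
  examples <- list()
  for (s in seeds) {
    sc <- generate_scene(config, seed = s)
    pre <- preprocess_cloud(sc$cloud, ranges = params$ranges,
                            knn_k = params$sor_k, alpha = params$sor_alpha,
                            leaf = params$leaf)
    seg <- extract_subject(pre, tol = params$cluster_tol,
                           min_size = params$cluster_min,
                           dist_thresh = params$plane_thresh,
                           max_iter = params$ransac_iter, seed = s)
    np <- normalize_pose(seg$subject, up_hint = seg$ground$normal)
    oc <- orientation_correct(np$cloud)
    pts <- coords(oc$cloud)
    normals <- estimate_normals(oc$cloud, params$curv_k)
    for (lm in landmark_names()) {
      p <- frame_transform(sc$truth$landmarks_true[[lm]], np$frame)
      if (oc$mirrored) p[1] <- -p[1]
      d2 <- rowSums(sweep(pts, 2, p)^2)
      # snap to the nearest point whose neighborhood supports a descriptor
      # (extreme body ends can be too thinly sampled after filtering)
      idx <- NA_integer_
      for (cand in order(d2)[seq_len(min(20L, nrow(pts)))]) {
        ok <- tryCatch({
          compute_fpfh(oc$cloud, cand, radius, normals = normals)
          TRUE
        }, error = function(e) FALSE)
        if (ok) { idx <- cand; break }
      }
      if (is.na(idx)) {
        stop("build_reference_db: no describable point near landmark '",
             lm, "' for seed ", s)
      }
      examples[[length(examples) + 1L]] <-
        list(landmark = lm, cloud = oc$cloud, index = idx,
             normals = normals)
    }
  }
  build_feature_db(examples, radius = radius, tau = tau)
}
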