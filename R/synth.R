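#' @useDynLib bovimetrics, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Run code under a seed without clobbering the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Scene-generator configuration
#'
#' Parameters of the synthetic standing-quadruped scene: an adult-cow-sized
#' body (superellipsoid-section torso whose top line carries a withers hump
#' higher than the rump, four cylindrical legs, a neck/head lobe on the head
#' side), a ground plane, background clutter, and additive sensor noise.
#' All lengths are meters. The canonical generative frame has the ground at
#' y = 0, the head on -x and the tail on +x; [generate_scene()] then moves
#' the whole scene by a random rigid pose into the sensor frame.
#'
#' @param ytop_base,ybot_base baseline heights of the back line and belly
#'   line of the torso.
#' @param withers,back,rump Gaussian bumps added to the back line, each a
#'   list with `x` (center), `amp` (amplitude) and `width` (sd), meters. The
#'   withers bump must remain the tallest point of the animal.
#' @param chest Gaussian dip subtracted from the belly line (the sternum
#'   drop behind the forelegs), same fields.
#' @param half_width torso half-width at mid-body.
#' @param torso_x x-interval spanned by the torso.
#' @param cross_exp superellipse exponent of the torso cross-section.
#' @param taper_exp sharpness of the end-cap taper.
#' @param leg list: `radius`, `x` (fore/hind positions), `z` (half track
#'   width), `top` (height where legs meet the belly).
#' @param head list: `center`, `axes` of the neck/head ellipsoid lobe, plus
#'   `neck_radius`.
#' @param n_torso,n_leg,n_head,n_ground,n_clutter surface sample counts
#'   (per leg / per clutter object).
#' @param clutter_count number of clutter objects (0 disables clutter).
#' @param noise_sigma standard deviation of isotropic Gaussian sensor noise.
#' @param shape_jitter relative spread of per-animal shape variation.
#' @param tilt_deg maximal ground tilt of the random scene pose, degrees.
#' @param shift_range maximal |translation| per axis of the scene pose.
#' @return A `scene_config` list.
#' @export
scene_config <- function(ytop_base = 1.10, ybot_base = 0.62,
                         withers = list(x = -0.55, amp = 0.15, width = 0.14),
                         back = list(x = 0.05, amp = 0.05, width = 0.18),
                         rump = list(x = 0.60, amp = 0.10, width = 0.16),
                         chest = list(x = -0.35, amp = 0.15, width = 0.12),
                         half_width = 0.28,
                         torso_x = c(-0.85, 0.85),
                         cross_exp = 2.5,
                         taper_exp = 8,
                         leg = list(radius = 0.06, x = c(-0.55, 0.55),
                                    z = 0.17, top = 0.65),
                         head = list(center = c(-1.10, 1.00, 0),
                                     axes = c(0.28, 0.15, 0.11),
                                     neck_radius = 0.07),
                         n_torso = 4200, n_leg = 300, n_head = 500,
                         n_ground = 9000, n_clutter = 200, clutter_count = 2,
                         noise_sigma = 0.003, shape_jitter = 0.03,
                         tilt_deg = 3, shift_range = 0.5) {
  cfg <- list(ytop_base = ytop_base, ybot_base = ybot_base,
              withers = withers, back = back, rump = rump, chest = chest,
              half_width = half_width, torso_x = torso_x,
              cross_exp = cross_exp, taper_exp = taper_exp,
              leg = leg, head = head,
              n_torso = n_torso, n_leg = n_leg, n_head = n_head,
              n_ground = n_ground, n_clutter = n_clutter,
              clutter_count = clutter_count,
              noise_sigma = noise_sigma, shape_jitter = shape_jitter,
              tilt_deg = tilt_deg, shift_range = shift_range)
  validate_scene_config(cfg)
  cfg
}

validate_scene_config <- function(cfg) {
  pos <- c(cfg$ytop_base, cfg$ybot_base, cfg$half_width,
           cfg$withers$amp, cfg$withers$width, cfg$back$amp, cfg$back$width,
           cfg$rump$amp, cfg$rump$width, cfg$chest$amp, cfg$chest$width,
           cfg$leg$radius, cfg$leg$top, cfg$head$axes,
           diff(cfg$torso_x))
  if (any(!is.finite(pos)) || any(pos <= 0)) {
    stop("scene_config: all body dimension parameters must be positive")
  }
  if (cfg$withers$amp <= cfg$rump$amp) {
    stop("scene_config: withers hump must be higher than the rump bump")
  }
  if (cfg$noise_sigma < 0 || cfg$clutter_count < 0) {
    stop("scene_config: noise_sigma and clutter_count must be non-negative")
  }
  invisible(cfg)
}

gaussian_bump <- function(x, b) b$amp * exp(-((x - b$x) / b$width)^2)

# Analytic body profiles: back line, belly line and end-cap tapers.
# Everything downstream (sampling, landmarks, true dimensions) evaluates
# these same closures, so ground truth is exact by construction.
body_profiles <- function(cfg) {
  xc <- mean(cfg$torso_x)
  halfspan <- diff(cfg$torso_x) / 2
  uu <- function(x) pmax(-1, pmin(1, (x - xc) / halfspan))
  sy <- function(x) (1 - abs(uu(x))^cfg$taper_exp)^(1 / 4)
  sw <- function(x) (1 - abs(uu(x))^6)^(1 / 3)
  ytop <- function(x) cfg$ytop_base + gaussian_bump(x, cfg$withers) +
    gaussian_bump(x, cfg$back) + gaussian_bump(x, cfg$rump)
  ybot <- function(x) cfg$ybot_base - gaussian_bump(x, cfg$chest)
  mid <- function(x) (ytop(x) + ybot(x)) / 2
  half <- function(x) (ytop(x) - ybot(x)) / 2
  list(ytop_eff = function(x) mid(x) + half(x) * sy(x),
       ybot_eff = function(x) mid(x) - half(x) * sy(x),
       mid = mid, half = half, sy = sy, sw = sw)
}

# Exact landmark positions and the five true dimensions in the canonical
# (ground y = 0, head on -x) frame.
body_ground_truth <- function(cfg) {
  pr <- body_profiles(cfg)
  front <- c(cfg$torso_x[1], pr$mid(cfg$torso_x[1]), 0)
  rear <- c(cfg$torso_x[2], pr$mid(cfg$torso_x[2]), 0)
  lm <- list(
    withers_upper = c(cfg$withers$x, pr$ytop_eff(cfg$withers$x), 0),
    chest_lower   = c(cfg$chest$x, pr$ybot_eff(cfg$chest$x), 0),
    back_upper    = c(cfg$back$x, pr$ytop_eff(cfg$back$x), 0),
    waist_upper   = c(cfg$rump$x, pr$ytop_eff(cfg$rump$x), 0),
    bodylen_upper = rear,
    bodylen_lower = front
  )
  dims <- list(
    withers_height = lm$withers_upper[2],
    chest_depth    = pr$ytop_eff(cfg$chest$x) - pr$ybot_eff(cfg$chest$x),
    back_height    = lm$back_upper[2],
    waist_height   = lm$waist_upper[2],
    body_length    = sqrt(sum((rear - front)^2))
  )
  list(landmarks = lm, dimensions = dims)
}

sample_torso <- function(cfg, n) {
  pr <- body_profiles(cfg)
  x <- stats::runif(n, cfg$torso_x[1], cfg$torso_x[2])
  phi <- stats::runif(n, 0, 2 * pi)
  e <- 2 / cfg$cross_exp
  g <- sign(sin(phi)) * abs(sin(phi))^e
  q <- sign(cos(phi)) * abs(cos(phi))^e
  cbind(x = x,
        y = pr$mid(x) + pr$half(x) * pr$sy(x) * g,
        z = cfg$half_width * pr$sw(x) * q)
}

sample_cylinder <- function(n, center_xz, radius, y0, y1) {
  phi <- stats::runif(n, 0, 2 * pi)
  y <- stats::runif(n, y0, y1)
  cbind(x = center_xz[1] + radius * cos(phi),
        y = y,
        z = center_xz[2] + radius * sin(phi))
}

sample_ellipsoid <- function(n, center, axes) {
  v <- matrix(stats::rnorm(3 * n), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  sweep(v %*% diag(axes), 2, center, `+`)
}

sample_body <- function(cfg) {
  torso <- sample_torso(cfg, cfg$n_torso)
  legs <- do.call(rbind, lapply(seq_len(4), function(i) {
    lx <- cfg$leg$x[(i - 1) %/% 2 + 1]
    lz <- cfg$leg$z * ifelse(i %% 2 == 0, 1, -1)
    sample_cylinder(cfg$n_leg, c(lx, lz), cfg$leg$radius, 0, cfg$leg$top)
  }))
  head <- sample_ellipsoid(cfg$n_head, cfg$head$center, cfg$head$axes)
  head <- head[head[, 1] <= cfg$torso_x[1] + 0.02, , drop = FALSE]
  # neck tube keeping the head lobe connected to the torso front
  neck_n <- max(80L, cfg$n_head %/% 4L)
  tt <- stats::runif(neck_n)
  a <- cfg$head$center
  pr <- body_profiles(cfg)
  b <- c(cfg$torso_x[1] + 0.15, pr$ytop_eff(cfg$torso_x[1] + 0.15) - 0.08, 0)
  axis <- (b - a) / sqrt(sum((b - a)^2))
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u1 <- cross3(axis, ref); u1 <- u1 / sqrt(sum(u1^2))
  u2 <- cross3(axis, u1)
  ang <- stats::runif(neck_n, 0, 2 * pi)
  neck <- t(vapply(seq_len(neck_n), function(i) {
    a + tt[i] * (b - a) +
      cfg$head$neck_radius * (cos(ang[i]) * u1 + sin(ang[i]) * u2)
  }, numeric(3)))
  gt <- body_ground_truth(cfg)
  lmpts <- do.call(rbind, gt$landmarks)
  rbind(torso, legs, head, neck, unname(lmpts))
}

jitter_config <- function(cfg, jitter) {
  if (jitter <= 0) return(cfg)
  j <- function(v) v * stats::runif(length(v), 1 - jitter, 1 + jitter)
  cfg$ytop_base <- j(cfg$ytop_base)
  cfg$ybot_base <- j(cfg$ybot_base)
  cfg$withers$amp <- j(cfg$withers$amp)
  cfg$back$amp <- j(cfg$back$amp)
  cfg$rump$amp <- pmin(j(cfg$rump$amp), 0.85 * cfg$withers$amp)
  cfg$chest$amp <- j(cfg$chest$amp)
  cfg$half_width <- j(cfg$half_width)
  span <- diff(cfg$torso_x) * stats::runif(1, 1 - jitter, 1 + jitter)
  cfg$torso_x <- mean(cfg$torso_x) + c(-0.5, 0.5) * span
  cfg
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

rotation_xyz <- function(yaw, pitch, roll) {
  cy <- cos(yaw); sy <- sin(yaw)
  cp <- cos(pitch); sp <- sin(pitch)
  cr <- cos(roll); sr <- sin(roll)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cp, sp, 0, -sp, cp), 3, 3)
  Rz <- matrix(c(cr, sr, 0, -sr, cr, 0, 0, 0, 1), 3, 3)
  Ry %*% Rx %*% Rz
}

#' Generate a synthetic LiDAR scene of a standing quadruped
#'
#' Builds a cattle-shaped subject (see [scene_config()]), a ground plane and
#' optional clutter in a canonical frame, then applies a random rigid scene
#' pose and additive Gaussian noise. The exact six landmark positions are
#' injected into the subject sample before noise, so every true landmark is
#' reachable from the cloud by a nearest-neighbor snap within the sampling
#' step. Fully deterministic given `(config, seed)`.
#'
#' @param config a [scene_config()].
#' @param seed integer seed controlling shape jitter, sampling, pose and noise.
#' @return A list with elements
#'   \describe{
#'     \item{cloud}{[pointcloud()] of the whole scene in the sensor frame.}
#'     \item{truth}{ground truth: `dimensions_true` (five named meters),
#'       `landmarks_true` (six named sensor-frame positions),
#'       `ground_plane` (`normal`, `offset` with `normal . p + offset = 0`),
#'       `component` (per-point `"subject"`/`"ground"`/`"clutter"` labels),
#'       `sampling_step`, `seed`, and the jittered `config`.}
#'   }
#' @export
generate_scene <- function(config = scene_config(), seed = 1L) {
  validate_scene_config(config)
  with_seed(seed, {
    cfg <- jitter_config(config, config$shape_jitter)
    subject <- sample_body(cfg)
    gt <- body_ground_truth(cfg)

    gx <- stats::runif(cfg$n_ground, -1.8, 1.8)
    gz <- stats::runif(cfg$n_ground, -1.2, 1.2)
    ground <- cbind(gx, 0, gz)

    clutter <- NULL
    if (cfg$clutter_count > 0) {
      spots <- list(c(0.2, 1.25), c(1.7, -1.0), c(-1.6, 1.1), c(1.3, 1.3))
      for (i in seq_len(cfg$clutter_count)) {
        s <- spots[[(i - 1) %% length(spots) + 1]]
        if (i %% 2 == 1) {
          cl <- cbind(stats::runif(cfg$n_clutter, s[1] - 0.25, s[1] + 0.25),
                      stats::runif(cfg$n_clutter, 0.05, 0.45),
                      stats::runif(cfg$n_clutter, s[2] - 0.15, s[2] + 0.15))
        } else {
          cl <- sample_cylinder(cfg$n_clutter, s, 0.08, 0.05, 1.3)
        }
        clutter <- rbind(clutter, cl)
      }
    }

    pts <- rbind(subject, ground, clutter)
    component <- c(rep("subject", nrow(subject)),
                   rep("ground", nrow(ground)),
                   rep("clutter", if (is.null(clutter)) 0 else nrow(clutter)))

    yaw <- stats::runif(1, 0, 2 * pi)
    tilt <- cfg$tilt_deg * pi / 180
    R <- rotation_xyz(yaw, stats::runif(1, -tilt, tilt),
                      stats::runif(1, -tilt, tilt))
    tr <- stats::runif(3, -cfg$shift_range, cfg$shift_range)
    pts <- sweep(pts %*% t(R), 2, tr, `+`)
    if (cfg$noise_sigma > 0) {
      pts <- pts + matrix(stats::rnorm(length(pts), 0, cfg$noise_sigma),
                          ncol = 3)
    }

    lmk <- lapply(gt$landmarks, function(p) drop(R %*% p) + tr)
    up <- drop(R %*% c(0, 1, 0))
    plane <- list(normal = up, offset = -sum(up * tr))

    torso_area <- diff(cfg$torso_x) * 2 * pi *
      sqrt((mean(c(0.25, cfg$half_width))^2 + 0.27^2) / 2)
    step <- sqrt(torso_area / cfg$n_torso)

    truth <- structure(list(
      dimensions_true = gt$dimensions,
      landmarks_true = lmk,
      ground_plane = plane,
      component = component,
      sampling_step = step,
      seed = seed,
      config = cfg
    ), class = "scene_truth")
    list(cloud = pointcloud(pts, frame_id = "sensor"), truth = truth)
  })
}

#' Labeled cloud set
#'
#' Container pairing point clouds with integer class labels (1-based) and
#' class names, used to train and transfer the classifier.
#'
#' @param clouds list of [pointcloud()]s.
#' @param labels integer class labels in `1..length(class_names)`.
#' @param class_names character vector of class names.
#' @return A `labeled_cloud_set`.
#' @export
labeled_cloud_set <- function(clouds, labels, class_names) {
  labels <- as.integer(labels)
  if (length(clouds) != length(labels)) {
    stop("clouds and labels must have equal length")
  }
  if (any(labels < 1L) || any(labels > length(class_names))) {
    stop("labels must index class_names")
  }
  structure(list(clouds = clouds, labels = labels, class_names = class_names),
            class = "labeled_cloud_set")
}

#' @export
print.labeled_cloud_set <- function(x, ...) {
  cat(sprintf("labeled_cloud_set: %d clouds, %d classes\n",
              length(x$clouds), length(x$class_names)))
  print(table(factor(x$class_names[x$labels], levels = x$class_names)))
  invisible(x)
}

shape_families <- function() {
  samp_rot <- function(pts) {
    R <- rotation_xyz(stats::runif(1, 0, 2 * pi), stats::runif(1, -0.3, 0.3),
                      stats::runif(1, -0.3, 0.3))
    s <- stats::runif(1, 0.9, 1.1)
    pts %*% t(R) * s
  }
  unit_sq <- function(n) cbind(stats::runif(n, -1, 1), stats::runif(n, -1, 1))
  list(
    plane = function(n) {
      u <- unit_sq(n); samp_rot(cbind(u[, 1], u[, 2], 0) * 0.5)
    },
    sphere = function(n) samp_rot(sample_ellipsoid(n, c(0, 0, 0), rep(0.4, 3))),
    cylinder = function(n) samp_rot(sample_cylinder(n, c(0, 0), 0.25, -0.5, 0.5)),
    box = function(n) {
      face <- sample.int(6, n, replace = TRUE)
      u <- unit_sq(n)
      pts <- matrix(0, n, 3)
      for (i in seq_len(n)) {
        ax <- (face[i] - 1) %/% 2 + 1
        sg <- ifelse(face[i] %% 2 == 0, 1, -1)
        p <- numeric(3); p[ax] <- sg
        p[setdiff(1:3, ax)] <- u[i, ]
        pts[i, ] <- p
      }
      samp_rot(pts * 0.35)
    },
    saddle = function(n) {
      u <- unit_sq(n) * 0.5
      samp_rot(cbind(u[, 1], u[, 2], u[, 1]^2 - u[, 2]^2))
    },
    torus = function(n) {
      a <- stats::runif(n, 0, 2 * pi); b <- stats::runif(n, 0, 2 * pi)
      R0 <- 0.35; r0 <- 0.12
      samp_rot(cbind((R0 + r0 * cos(b)) * cos(a),
                     (R0 + r0 * cos(b)) * sin(a), r0 * sin(b)))
    },
    two_lobe = function(n) {
      h <- n %/% 2
      samp_rot(rbind(sample_ellipsoid(h, c(-0.3, 0, 0), rep(0.2, 3)),
                     sample_ellipsoid(n - h, c(0.3, 0, 0), rep(0.2, 3))))
    },
    ellipsoid = function(n) {
      samp_rot(sample_ellipsoid(n, c(0, 0, 0), c(0.6, 0.3, 0.15)))
    },
    cone = function(n) {
      t <- sqrt(stats::runif(n)); a <- stats::runif(n, 0, 2 * pi)
      samp_rot(cbind(0.3 * t * cos(a), 0.6 * (1 - t), 0.3 * t * sin(a)))
    },
    bowl = function(n) {
      v <- sample_ellipsoid(n, c(0, 0, 0), rep(0.4, 3))
      v[, 2] <- -abs(v[, 2])
      samp_rot(v)
    },
    capsule = function(n) {
      h <- n %/% 3
      samp_rot(rbind(sample_cylinder(n - 2 * h, c(0, 0), 0.15, -0.3, 0.3),
                     sample_ellipsoid(h, c(0, 0.3, 0), rep(0.15, 3)),
                     sample_ellipsoid(h, c(0, -0.3, 0), rep(0.15, 3))))
    },
    cross = function(n) {
      h <- n %/% 2
      u1 <- unit_sq(h); u2 <- unit_sq(n - h)
      samp_rot(rbind(cbind(u1[, 1] * 0.5, u1[, 2] * 0.12, 0.1 * sign(u1[, 1])),
                     cbind(u2[, 1] * 0.12, u2[, 2] * 0.5, -0.1 * sign(u2[, 2]))))
    },
    wavy = function(n) {
      u <- unit_sq(n) * 0.5
      samp_rot(cbind(u[, 1], u[, 2], 0.08 * sin(8 * u[, 1])))
    },
    ring = function(n) {
      a <- stats::runif(n, 0, 2 * pi)
      samp_rot(cbind(0.4 * cos(a), 0.4 * sin(a),
                     stats::runif(n, -0.03, 0.03)))
    },
    pyramid = function(n) {
      t <- sqrt(stats::runif(n)); a <- floor(stats::runif(n, 0, 4))
      u <- stats::runif(n, -1, 1)
      base <- cbind(ifelse(a %% 2 == 0, u, sign(a - 1.5)),
                    0, ifelse(a %% 2 == 0, sign(a - 1.5), u)) * 0.35
      samp_rot(base * t + (1 - t) %o% c(0, 0.6, 0))
    },
    helix = function(n) {
      t <- stats::runif(n, 0, 4 * pi)
      samp_rot(cbind(0.25 * cos(t), 0.03 * t - 0.2, 0.25 * sin(t)) +
                 matrix(stats::rnorm(3 * n, 0, 0.015), ncol = 3))
    }
  )
}

#' Generate a labeled multi-class shape dataset
#'
#' Draws clouds from up to 16 distinct parametric surface families (plane,
#' sphere, cylinder, box, saddle, torus, ...) with random pose jitter, as a
#' synthetic stand-in for a multi-class shape benchmark used to pre-train
#' the classifier.
#'
#' @param n_classes number of families to use (2..16).
#' @param per_class clouds per class.
#' @param n_points points per cloud; must be a power of two so the clouds
#'   fill a balanced Kd-tree exactly.
#' @param seed integer seed.
#' @return A [labeled_cloud_set()].
#' @export
generate_shape_dataset <- function(n_classes, per_class, n_points, seed = 1L) {
  fams <- shape_families()
  if (n_classes < 2L) stop("n_classes must be at least 2")
  if (n_classes > length(fams)) {
    stop("n_classes exceeds the ", length(fams), " available shape families")
  }
  if (bitwAnd(n_points, n_points - 1L) != 0L) {
    stop("n_points must be a power of two")
  }
  with_seed(seed, {
    clouds <- list(); labels <- integer(0)
    for (cls in seq_len(n_classes)) {
      for (r in seq_len(per_class)) {
        pts <- fams[[cls]](n_points)
        clouds[[length(clouds) + 1L]] <- pointcloud(pts)
        labels <- c(labels, cls)
      }
    }
    labeled_cloud_set(clouds, labels, names(fams)[seq_len(n_classes)])
  })
}

#' Generate a cattle-vs-other silhouette set for transfer learning
#'
#' Cattle examples are subject-only bodies from the scene generator (with
#' per-animal shape jitter and sensor noise, resampled to `n_points`);
#' distractors are animal-scale clouds from the generic shape families.
#' Class 1 is `"cattle"`, class 2 is `"other"`.
#'
#' @param n_cattle,n_distractor example counts.
#' @param n_points points per cloud (power of two).
#' @param seed integer seed.
#' @param config base [scene_config()] for the cattle bodies.
#' @return A [labeled_cloud_set()] with `class_names = c("cattle", "other")`.
#' @export
generate_silhouette_set <- function(n_cattle, n_distractor, n_points = 128L,
                                    seed = 1L, config = scene_config()) {
  if (bitwAnd(n_points, n_points - 1L) != 0L) {
    stop("n_points must be a power of two")
  }
  fams <- shape_families()
  with_seed(seed, {
    clouds <- list(); labels <- integer(0)
    for (i in seq_len(n_cattle)) {
      cfg <- jitter_config(config, config$shape_jitter)
      pts <- sample_body(cfg)
      pts <- pts + matrix(stats::rnorm(length(pts), 0, cfg$noise_sigma),
                          ncol = 3)
      keep <- sample.int(nrow(pts), n_points)
      sil <- pts[keep, , drop = FALSE]
      # body-frame silhouettes, centered like a pose-normalized subject
      sil <- sweep(sil, 2, colMeans(sil))
      clouds[[length(clouds) + 1L]] <- pointcloud(sil)
      labels <- c(labels, 1L)
    }
    big <- c("box", "cylinder", "ellipsoid", "capsule", "torus", "cone")
    for (i in seq_len(n_distractor)) {
      fam <- fams[[big[(i - 1L) %% length(big) + 1L]]]
      pts <- fam(n_points) * stats::runif(1, 1.5, 2.5)
      clouds[[length(clouds) + 1L]] <- pointcloud(pts)
      labels <- c(labels, 2L)
    }
    labeled_cloud_set(clouds, labels, c("cattle", "other"))
  })
}
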