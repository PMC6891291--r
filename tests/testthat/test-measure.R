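flat_ground <- structure(list(normal = c(0, 1, 0), offset = 0,
                              inlier_indices = integer(0)),
                         class = "plane_model")

test_that("auxiliary points project onto the ground and find the back line", {
  lms <- list(withers_upper = c(-0.5, 1.21, 0),
              back_upper = c(0.1, 1.1, 0),
              waist_upper = c(0.6, 1.18, 0),
              chest_lower = c(-0.2, 0.47, 0),
              bodylen_upper = c(0.8, 0.9, 0),
              bodylen_lower = c(-0.8, 0.85, 0))
  cloud <- pointcloud(rbind(c(-0.2, 1.10, 0.01), c(-0.21, 1.05, 0),
                            c(-0.2, 0.47, 0), c(0.5, 1.2, 0.4)))
  aux <- derive_auxiliary_points(lms, flat_ground, cloud)
  expect_equal(aux$withers_lower, c(-0.5, 0, 0))
  expect_equal(aux$chest_upper, c(-0.2, 1.10, 0.01))

  # tilted ground: the lower point lies exactly on the plane
  n <- c(0.1, 0.99, -0.05); n <- n / sqrt(sum(n^2))
  tilted <- structure(list(normal = n, offset = -0.3), class = "plane_model")
  aux2 <- derive_auxiliary_points(lms, tilted, cloud)
  expect_equal(sum(aux2$waist_lower * n) - 0.3, 0, tolerance = 1e-9)
  expect_equal(aux2$waist_lower[c(1, 3)], lms$waist_upper[c(1, 3)])

  lms_far <- lms
  lms_far$chest_lower <- c(50, 0, 50)
  expect_error(derive_auxiliary_points(lms_far, flat_ground, cloud),
               "no cloud points above")
})

test_that("dimensions follow their geometric definitions", {
  lms <- list(withers_upper = c(-0.5, 1.21, 0),
              back_upper = c(0.1, 1.1, 0),
              waist_upper = c(0.6, 1.18, 0),
              chest_lower = c(-0.2, 0.47, 0),
              bodylen_upper = c(0.7, 0.9, 0),
              bodylen_lower = c(-0.8, 0.9, 0))
  aux <- list(withers_lower = c(-0.5, 0, 0), back_lower = c(0.1, 0, 0),
              waist_lower = c(0.6, 0, 0), chest_upper = c(-0.2, 1.10, 0))
  bd <- compute_dimensions(lms, aux, flat_ground)
  expect_equal(bd$withers_height, 1.21)
  expect_equal(bd$chest_depth, 0.63)
  expect_equal(bd$back_height, 1.1)
  expect_equal(bd$body_length, 1.5)
  lms$withers_upper <- c(-0.5, 0, 0)
  expect_error(compute_dimensions(lms, aux, flat_ground), "non-positive")
})

test_that("error reports use the manual denominator with half-up rounding", {
  manual <- c(withers_height = 1.211, chest_depth = 0.630, back_height = 1.110,
              waist_height = 1.175, body_length = 1.355)
  auto <- c(withers_height = 1.213, chest_depth = 0.629, back_height = 1.124,
            waist_height = 1.186, body_length = 1.387)
  rep <- error_report(auto, manual)
  expect_equal(rep$error_percent,
               c(0.17, 0.16, 1.26, 0.94, 2.36))
  expect_equal(error_report(manual, manual)$error_percent, rep(0, 5))
  expect_error(error_report(auto, manual * 0), "positive")

  q <- qinchuan_reference()
  one <- q[q$animal == "Q0526" & q$dimension == "chest_depth", ]
  expect_equal(error_report(
    stats::setNames(rep(one$automatic, 5), names(manual)),
    stats::setNames(rep(one$manual, 5), names(manual)))$error_percent[1],
    1.45)
})

test_that("the full pipeline recovers landmarks and dimensions on a scene", {
  sc <- test_scene(1)
  res <- test_measured(1)
  pts <- coords(res$subject)
  step <- sc$truth$sampling_step
  for (lm in names(res$landmark_indices)) {
    p <- truth_in_result_frame(sc, res, lm)
    d <- pts[res$landmark_indices[[lm]], ] - p
    # localization along the direction the dimension depends on: height for
    # the vertical landmarks, body axis for the length end points
    axis_err <- if (grepl("bodylen", lm)) abs(d[1]) else abs(d[2])
    expect_lt(axis_err, 3 * step)
    expect_lt(sqrt(sum(d^2)), 0.25)  # coarse bound on the full 3D offset
  }
  auto <- dims_vector(res$dimensions)
  tru <- unlist(sc$truth$dimensions_true)[dimension_names5]
  expect_lt(max(abs(auto - tru) / tru), 0.06)

  # the attached report matches error_report on the same numbers
  res2 <- measure_pipeline(sc$cloud, test_db(), manual = tru, seed = 1)
  expect_equal(res2$report$error_percent,
               error_report(res2$dimensions, tru)$error_percent)
})

test_that("measured dimensions are rigid-invariant and scale-equivariant", {
  sc <- test_scene(2)
  res <- measure_pipeline(sc$cloud, test_db(), seed = 2)
  base <- dims_vector(res$dimensions)

  R <- getFromNamespace("rotation_xyz", "bovimetrics")(2.1, 0.04, -0.03)
  moved <- pointcloud(sweep(coords(sc$cloud) %*% t(R), 2, c(3, 0.5, -2), `+`))
  res_m <- measure_pipeline(moved, test_db(), seed = 2)
  expect_lt(max(abs(dims_vector(res_m$dimensions) - base) / base), 0.03)

  s <- 1.7
  db_s <- build_reference_db(c(101L, 102L, 103L))  # same db; descriptors are scale-sensitive,
  scaled <- pointcloud(coords(sc$cloud) * s)
  params_s <- measure_params()
  params_s$leaf <- params_s$leaf * s
  params_s$cluster_tol <- params_s$cluster_tol * s
  params_s$plane_thresh <- params_s$plane_thresh * s
  params_s$chest_cyl_radius <- params_s$chest_cyl_radius * s
  db_s$radius <- db_s$radius * s
  res_s <- measure_pipeline(scaled, db_s, params = params_s, seed = 2)
  expect_lt(max(abs(dims_vector(res_s$dimensions) - s * base) / (s * base)),
            0.03)
})

test_that("a distractor scene is refused by the classifier gate", {
  pre <- make_pretrained()
  target <- generate_silhouette_set(20, 20, 32, seed = 21)
  fit <- transfer_train(pre$model, pre$source, target,
                        train_config(epochs = 30, learning_rate = 0.003,
                                     seed = 3), n_boost = 3)
  sc <- test_scene(1)
  res <- measure_pipeline(sc$cloud, test_db(), gate_model = fit$model, seed = 1)
  expect_s3_class(res$dimensions, "body_dimensions")

  # a big box on the ground instead of an animal
  set.seed(9)
  box <- getFromNamespace("shape_families", "bovimetrics")()$box(3000)
  box <- sweep(box * 2, 2, c(0, 1.0, 0), `+`)
  gx <- stats::runif(6000, -2, 2); gz <- stats::runif(6000, -1.4, 1.4)
  scene <- pointcloud(rbind(box, cbind(gx, 0, gz)) +
                        matrix(stats::rnorm(3 * (3000 + 6000), 0, 0.003), ncol = 3))
  expect_error(
    suppressWarnings(measure_pipeline(scene, test_db(), gate_model = fit$model,
                                      seed = 1)),
    "rejected by the classifier gate|failed at stage")
})
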