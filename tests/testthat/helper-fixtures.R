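# Shared lazily-built fixtures; expensive objects are computed once per run.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

test_scene <- function(seed = 1) {
  cached(paste0("scene_", seed), generate_scene(seed = seed))
}

test_db <- function() {
  cached("feature_db", build_reference_db(c(101L, 102L, 103L)))
}

test_measured <- function(seed = 1) {
  cached(paste0("measured_", seed),
         measure_pipeline(test_scene(seed)$cloud, test_db(), seed = seed))
}

# True landmark position expressed in the frame of a measure_pipeline result.
truth_in_result_frame <- function(scene, result, landmark) {
  p <- frame_transform(scene$truth$landmarks_true[[landmark]], result$frame)
  if (result$mirrored) p[1] <- -p[1]
  p
}

random_cloud <- function(n, seed = 1, scale = 1) {
  with_seed <- getFromNamespace("with_seed", "bovimetrics")
  with_seed(seed, pointcloud(matrix(stats::runif(3 * n, -scale, scale), ncol = 3)))
}

dimension_names5 <- c("withers_height", "chest_depth", "back_height",
                      "waist_height", "body_length")

dims_vector <- function(bd) vapply(dimension_names5, function(d) bd[[d]], numeric(1))

make_pretrained <- function() {
  cached("pretrained_small", {
    src <- generate_shape_dataset(4, 15, 32, seed = 11)
    fit <- train_kdnet(src, train_config(epochs = 40, learning_rate = 0.003,
                                         seed = 2), depth = 5)
    list(model = fit$model, source = src)
  })
}

# Uniform samples of analytic surfaces used as curvature oracles.
sphere_cloud <- function(n, r, seed = 1) {
  set.seed(seed)
  v <- matrix(stats::rnorm(3 * n), ncol = 3)
  pointcloud(r * v / sqrt(rowSums(v^2)))
}

cylinder_cloud <- function(n, r, h, seed = 1) {
  set.seed(seed)
  a <- stats::runif(n, 0, 2 * pi)
  pointcloud(cbind(r * cos(a), stats::runif(n, -h / 2, h / 2), r * sin(a)))
}

plane_cloud <- function(n, seed = 1) {
  set.seed(seed)
  pointcloud(cbind(stats::runif(n, -1, 1), 0, stats::runif(n, -1, 1)))
}
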