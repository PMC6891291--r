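test_that("scene generation is deterministic and ground truth is self-consistent", {
  a <- generate_scene(seed = 42)
  b <- generate_scene(seed = 42)
  expect_identical(coords(a$cloud), coords(b$cloud))

  dims <- unlist(a$truth$dimensions_true)
  expect_true(all(dims > 0))
  # landmark heights above the ground plane reproduce the stated dimensions
  pl <- a$truth$ground_plane
  h <- function(p) abs(sum(pl$normal * p) + pl$offset)
  expect_equal(h(a$truth$landmarks_true$withers_upper),
               a$truth$dimensions_true$withers_height, tolerance = 1e-9)
  expect_equal(h(a$truth$landmarks_true$back_upper),
               a$truth$dimensions_true$back_height, tolerance = 1e-9)
  expect_equal(h(a$truth$landmarks_true$waist_upper),
               a$truth$dimensions_true$waist_height, tolerance = 1e-9)
  bl <- a$truth$landmarks_true
  expect_equal(sqrt(sum((bl$bodylen_upper - bl$bodylen_lower)^2)),
               a$truth$dimensions_true$body_length, tolerance = 1e-9)
})

test_that("noise-free scenes contain the exact landmarks and the withers is the top", {
  cfg <- scene_config(noise_sigma = 0, clutter_count = 0, shape_jitter = 0,
                      tilt_deg = 0)
  sc <- generate_scene(cfg, seed = 5)
  pts <- coords(sc$cloud)
  subj <- pts[sc$truth$component == "subject", , drop = FALSE]
  # injected landmark points are present verbatim
  for (lm in sc$truth$landmarks_true) {
    expect_lt(min(sqrt(rowSums(sweep(subj, 2, lm)^2))), 1e-9)
  }
  # maximum subject height above ground equals the withers height within one
  # sampling step
  pl <- sc$truth$ground_plane
  hmax <- max(subj %*% pl$normal + pl$offset)
  expect_lt(abs(hmax - sc$truth$dimensions_true$withers_height),
            sc$truth$sampling_step)
})

test_that("landmarks are reachable by nearest-neighbor snap under default noise", {
  sc <- test_scene(3)
  subj <- coords(sc$cloud)[sc$truth$component == "subject", , drop = FALSE]
  for (lm in sc$truth$landmarks_true) {
    expect_lt(min(sqrt(rowSums(sweep(subj, 2, lm)^2))),
              sc$truth$sampling_step)
  }
})

test_that("invalid scene configurations are rejected", {
  expect_error(scene_config(half_width = -0.1), "positive")
  expect_error(scene_config(withers = list(x = -0.5, amp = 0.05, width = 0.1)),
               "withers hump")
  expect_error(scene_config(noise_sigma = -1), "non-negative")
})

test_that("shape dataset has the requested composition and is deterministic", {
  d <- generate_shape_dataset(2, 10, 128, seed = 7)
  expect_length(d$clouds, 20)
  expect_equal(as.vector(table(d$labels)), c(10, 10))
  expect_true(all(vapply(d$clouds, npoints, integer(1)) == 128))
  d2 <- generate_shape_dataset(2, 10, 128, seed = 7)
  expect_identical(lapply(d$clouds, coords), lapply(d2$clouds, coords))

  expect_error(generate_shape_dataset(40, 2, 64), "available shape families")
  expect_error(generate_shape_dataset(2, 2, 100), "power of two")
})

test_that("plane and sphere classes are separable on simple moment features", {
  d <- generate_shape_dataset(16, 5, 128, seed = 3)
  keep <- d$labels %in% c(1, 2)  # plane, sphere
  feats <- t(vapply(d$clouds[keep], function(cl) {
    ev <- eigen(compute_covariance(cl), symmetric = TRUE)$values
    ev / sum(ev)
  }, numeric(3)))
  labs <- d$labels[keep]
  centr <- rbind(colMeans(feats[labs == 1, ]), colMeans(feats[labs == 2, ]))
  pred <- apply(feats, 1, function(f) {
    which.min(rowSums(sweep(centr, 2, f)^2))
  })
  expect_gte(mean(pred == labs), 0.9)
})

test_that("silhouette sets mix cattle and distractors deterministically", {
  s <- generate_silhouette_set(5, 7, 64, seed = 2)
  expect_equal(as.vector(table(s$labels)), c(5, 7))
  expect_identical(s$class_names, c("cattle", "other"))
  s2 <- generate_silhouette_set(5, 7, 64, seed = 2)
  expect_identical(coords(s$clouds[[3]]), coords(s2$clouds[[3]]))
  expect_error(labeled_cloud_set(s$clouds, c(s$labels[-1], 9), s$class_names),
               "index class_names")
})
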