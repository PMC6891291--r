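test_that("centroid and covariance match brute-force sums", {
  pc <- pointcloud(rbind(c(0, 0, 0), c(2, 0, 0), c(1, 3, 0)))
  expect_equal(compute_centroid(pc), c(x = 1, y = 1, z = 0))
  expect_equal(compute_centroid(pointcloud(matrix(c(4, 5, 6), 1))),
               c(x = 4, y = 5, z = 6))

  two <- pointcloud(rbind(c(1, 0, 0), c(-1, 0, 0)))
  expect_equal(unname(compute_covariance(two)), diag(c(1, 0, 0)))
  same <- pointcloud(matrix(2, 5, 3) + 0)
  expect_equal(unname(compute_covariance(same)), matrix(0, 3, 3))

  pc2 <- random_cloud(500, seed = 3)
  pts <- coords(pc2)
  expect_equal(compute_centroid(pc2), colMeans(pts), tolerance = 1e-12)
  ctr <- colMeans(pts)
  oracle <- Reduce(`+`, lapply(seq_len(500), function(i) {
    d <- unname(pts[i, ] - ctr)
    d %o% d
  })) / 500
  expect_equal(unname(compute_covariance(pc2)), oracle, tolerance = 1e-12)
})

test_that("pca frames recover known axes and handle degeneracy", {
  f <- pca_frame(diag(c(4, 1, 0.25)), c(1, 2, 3))
  expect_equal(f$eigenvalues, c(4, 1, 0.25))
  expect_equal(abs(f$axes), diag(3), tolerance = 1e-9)
  expect_equal(det(f$axes), 1, tolerance = 1e-9)

  set.seed(6)
  th <- stats::runif(3, 0, 2 * pi)
  R <- getFromNamespace("rotation_xyz", "bovimetrics")(th[1], th[2] / 10, th[3] / 10)
  cov <- R %*% diag(c(4, 1, 0.25)) %*% t(R)
  f2 <- pca_frame(cov)
  for (i in 1:3) {
    expect_gt(abs(sum(f2$axes[i, ] * R[, i])), 1 - 1e-6)
  }
  expect_warning(f0 <- pca_frame(matrix(0, 3, 3)), "ambiguous")
  expect_equal(f0$eigenvalues, c(0, 0, 0))
  expect_equal(crossprod(f0$axes), diag(3), tolerance = 1e-9)
})

test_that("pose normalization orders the extents and is idempotent", {
  set.seed(7)
  v <- matrix(stats::rnorm(3000), ncol = 3)
  ell <- v / sqrt(rowSums(v^2)) * 1
  ell <- ell %*% diag(c(4, 2, 1))
  R <- getFromNamespace("rotation_xyz", "bovimetrics")(0.7, 0.4, -0.3)
  pc <- pointcloud(sweep(ell %*% t(R), 2, c(5, -2, 1), `+`))
  np <- normalize_pose(pc)
  expect_identical(np$cloud$frame_id, "normalized")
  ext <- apply(coords(np$cloud), 2, function(u) diff(range(u)))
  expect_true(ext[1] > ext[2] && ext[2] > ext[3])
  expect_equal(unname(colMeans(coords(np$cloud))), c(0, 0, 0),
               tolerance = 1e-9)

  np2 <- normalize_pose(np$cloud)
  expect_equal(abs(coords(np2$cloud)), abs(coords(np$cloud)), tolerance = 1e-6)

  # round trip through the frame
  back <- frame_transform(coords(np$cloud), np$frame, inverse = TRUE)
  expect_equal(back, unname(coords(pc)), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("orientation correction puts the higher (head) half on -x", {
  sc <- generate_scene(scene_config(clutter_count = 0, tilt_deg = 0,
                                    shape_jitter = 0),
                       seed = 8)
  solo <- pointcloud(coords(sc$cloud)[sc$truth$component == "subject", ])
  np <- normalize_pose(solo, up_hint = sc$truth$ground_plane$normal)
  oc <- orientation_correct(np$cloud)
  pts <- coords(oc$cloud)
  expect_lt(pts[which.max(pts[, 2]), 1], 0)  # withers on the head side (-x)
  # mirroring the corrected cloud and correcting again undoes the mirror
  flipped <- affine_transform(oc$cloud, mirror_vertical())
  oc2 <- orientation_correct(flipped)
  expect_true(oc2$mirrored)
  expect_equal(coords(oc2$cloud), coords(oc$cloud), tolerance = 1e-12)
  # applying it to its own output changes nothing
  oc3 <- orientation_correct(oc$cloud)
  expect_false(oc3$mirrored)
  # the mirror matrix is an involution
  m <- mirror_vertical()
  expect_equal(m %*% m, diag(3))
  expect_error(orientation_correct(pointcloud(cbind(1:3, 0, 0))), "degenerate")
})

test_that("Euler's formula and H/K follow the analytic definitions", {
  expect_equal(normal_curvature_euler(3, 1, 0), 3)
  expect_equal(normal_curvature_euler(3, 1, pi / 2), 1)
  expect_equal(normal_curvature_euler(3, 1, pi / 4), 2)
  expect_error(normal_curvature_euler(1, 3, 0), "k1 >= k2")

  expect_error(mean_gaussian_curvature(2, 4), "k1 >= k2")
  expect_equal(mean_gaussian_curvature(4, 2), c(H = 3, K = 8))
  expect_equal(mean_gaussian_curvature(1, -1), c(H = 0, K = -1))
  r <- 0.5
  expect_equal(mean_gaussian_curvature(1 / r, 1 / r), c(H = 2, K = 4))
})

test_that("surface typing implements the sign table and rejects H=0, K>0", {
  expect_identical(classify_surface_type(-1, 2, 0.1, 0.1), "well")
  expect_identical(classify_surface_type(0, 0, 0.1, 0.1), "plane")
  expect_identical(classify_surface_type(-1, -2, 0.1, 0.1), "saddle_valley")
  expect_identical(classify_surface_type(-1, 0, 0.1, 0.1), "valley")
  expect_identical(classify_surface_type(1, -2, 0.1, 0.1), "saddle_ridge")
  expect_identical(classify_surface_type(1, 0, 0.1, 0.1), "ridge")
  expect_identical(classify_surface_type(1, 2, 0.1, 0.1), "peak")
  expect_identical(classify_surface_type(0, -1, 0.1, 0.1), "minimal_saddle")
  expect_error(classify_surface_type(0, 1, 0.1, 0.1), "impossible")
  expect_error(classify_surface_type(1, 1, -0.1, 0.1), "positive")
  expect_length(surface_types(), 8)
})

test_that("quadric curvature estimates match analytic surfaces", {
  sp <- sphere_cloud(1500, 1, seed = 2)
  f <- principal_curvatures(sp, 16)
  expect_gt(mean(f$valid), 0.99)
  expect_lt(abs(median(f$H[f$valid]) - 1), 0.1)
  expect_lt(abs(median(f$K[f$valid]) - 1), 0.15)
  # H/K consistency with the stored principal curvatures
  expect_lt(max(abs((f$k1 + f$k2) / 2 - f$H), na.rm = TRUE), 1e-9)
  expect_lt(max(abs(f$k1 * f$k2 - f$K), na.rm = TRUE), 1e-9)

  cy <- cylinder_cloud(1500, 0.5, 2, seed = 3)
  fc <- principal_curvatures(cy, 16)
  inner <- abs(coords(cy)[, 2]) < 0.7
  expect_lt(abs(median(fc$k1[inner]) - 2), 0.3)
  expect_lt(abs(median(fc$K[inner])), 0.05 * 4)

  pl <- plane_cloud(1200, seed = 4)
  fp <- principal_curvatures(pl, 16)
  interior <- rowSums(abs(coords(pl)[, c(1, 3)]) > 0.9) == 0
  expect_gte(mean(fp$type[interior] == "plane"), 0.95)

  expect_error(principal_curvatures(sp, 5), "at least 6")
})

test_that("curvature is invariant to rigid motion of the cloud", {
  pc <- sphere_cloud(600, 0.8, seed = 5)
  R <- getFromNamespace("rotation_xyz", "bovimetrics")(1.1, 0.3, -0.2)
  moved <- pointcloud(sweep(coords(pc) %*% t(R), 2, c(2, -1, 3), `+`))
  f1 <- principal_curvatures(pc, 14)
  f2 <- principal_curvatures(moved, 14)
  ok <- f1$valid & f2$valid
  expect_gt(stats::cor(f1$H[ok], f2$H[ok]), 0.99)
  expect_lt(median(abs(f1$H[ok] - f2$H[ok])), 0.02)
})

test_that("candidate regions honor the mapping and warn when empty", {
  pl <- plane_cloud(800, seed = 6)
  f <- principal_curvatures(pl, 16)
  expect_warning(
    cands <- candidate_regions(f, pl, list(withers_upper = list(
      types = c("peak", "ridge"), xband = NULL))),
    "no candidates")
  expect_length(cands$withers_upper, 0)
  expect_warning(
    candidate_regions(f, pl, list(x = list(types = character(0)))),
    "no candidates")

  # the snapped true withers point appears in its candidate set
  res <- test_measured(1)
  sc <- test_scene(1)
  pts <- coords(res$subject)
  field <- principal_curvatures(res$subject, 16)
  cands <- candidate_regions(field, res$subject)
  p <- truth_in_result_frame(sc, res, "withers_upper")
  i <- which.min(rowSums(sweep(pts, 2, p)^2))
  near <- which(sqrt(rowSums(sweep(pts, 2, p)^2)) < 0.06)
  expect_true(any(near %in% cands$withers_upper))
})
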