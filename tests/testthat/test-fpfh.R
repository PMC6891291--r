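test_that("FPFH of a flat patch concentrates in the central bins", {
  pl <- plane_cloud(900, seed = 1)
  # analytic zero-angle case: consistent normals of the plane y = 0
  nrm <- matrix(rep(c(0, 1, 0), each = 900), ncol = 3)
  ctr <- which.min(rowSums(coords(pl)[, c(1, 3)]^2))
  d <- compute_fpfh(pl, ctr, 0.2, normals = nrm)
  blocks <- split(d$bins, rep(1:3, each = 11))
  for (b in blocks) {
    expect_equal(sum(b), 100, tolerance = 1e-6)
    expect_gt(sum(b[5:7]), 90)  # zero-angle features fall in the middle bins
  }
  expect_true(all(d$bins >= 0))
  expect_equal(fpfh_distance(d, d), 0)
})

test_that("FPFH is invariant under rigid transforms of the whole cloud", {
  pc <- sphere_cloud(700, 0.7, seed = 2)
  nrm <- estimate_normals(pc, 12)
  R <- getFromNamespace("rotation_xyz", "bovimetrics")(0.9, 0.2, -0.4)
  moved <- pointcloud(sweep(coords(pc) %*% t(R), 2, c(1, 2, 3), `+`))
  nrm2 <- estimate_normals(moved, 12)
  d1 <- compute_fpfh(pc, 10, 0.25, normals = nrm)
  d2 <- compute_fpfh(moved, 10, 0.25, normals = nrm2)
  expect_lt(fpfh_distance(d1, d2), 1e-6)
  expect_error(compute_fpfh(pc, 10, 1e-4), "fewer than 5")
})

test_that("compiled FPFH agrees with the plain-R reference implementation", {
  set.seed(5)
  a <- stats::runif(400, -0.5, 0.5)
  b <- stats::runif(400, -0.5, 0.5)
  pc <- pointcloud(cbind(a, a^2 - b^2 + stats::rnorm(400, 0, 0.002), b))
  nrm <- estimate_normals(pc, 12)
  ref <- getFromNamespace("fpfh_reference", "bovimetrics")
  for (i in c(3, 100, 250)) {
    d1 <- compute_fpfh(pc, i, 0.15, normals = nrm)
    d2 <- ref(pc, i, 0.15, normals = nrm)
    expect_equal(d1$bins, d2$bins, tolerance = 1e-12)
  }
})

test_that("the feature database counts, persists and self-matches", {
  db <- test_db()
  expect_setequal(names(db$entries),
                  c("withers_upper", "chest_lower", "back_upper",
                    "waist_upper", "bodylen_upper", "bodylen_lower"))
  expect_true(all(lengths(db$entries) == 3))  # 6 landmarks x 3 animals
  expect_true(all(db$tau > 0))

  f <- withr::local_tempfile(fileext = ".json")
  save_feature_db(db, f)
  back <- read_feature_db(f)
  expect_equal(back$tau, db$tau)
  for (lm in names(db$entries)) {
    for (k in seq_along(db$entries[[lm]])) {
      expect_identical(back$entries[[lm]][[k]]$bins, db$entries[[lm]][[k]]$bins)
    }
  }

  # every reference descriptor matches at least one other animal's within tau
  for (lm in names(db$entries)) {
    ds <- db$entries[[lm]]
    for (i in seq_along(ds)) {
      others <- vapply(ds[-i], fpfh_distance, numeric(1), a = ds[[i]])
      expect_lte(min(others), db$tau[[lm]])
    }
  }

  expect_error(build_feature_db(list(list(landmark = "withers_upper",
                                          cloud = sphere_cloud(300, 1),
                                          index = 1)), radius = 0.3, tau = 1),
               "incomplete feature database")
})

test_that("matching scans candidates in order and stops at the first hit", {
  pc <- sphere_cloud(600, 1, seed = 3)
  nrm <- estimate_normals(pc, 12)
  d5 <- compute_fpfh(pc, 5, 0.3, normals = nrm)
  lmn <- getFromNamespace("landmark_names", "bovimetrics")()
  db <- list(entries = stats::setNames(rep(list(list(d5)), 6), lmn),
             tau = 1e9, radius = 0.3)
  class(db) <- "feature_model_db"
  # both candidates match (huge tau): the first is returned
  expect_equal(match_feature_point(c(30, 31), pc, "withers_upper", db,
                                   normals = nrm), 30)
  # only the exact point matches at tau = 0
  db$tau <- 0
  expect_equal(match_feature_point(c(30, 5), pc, "withers_upper", db,
                                   normals = nrm), 5)
  expect_error(match_feature_point(c(30, 31), pc, "withers_upper", db,
                                   normals = nrm), "no candidate within tau")
  expect_error(match_feature_point(integer(0), pc, "withers_upper", db),
               "empty candidate set")
})
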