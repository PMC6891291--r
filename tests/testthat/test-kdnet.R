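test_that("relu is max(0, x) including the boundary", {
  expect_equal(relu(-1), 0)
  expect_equal(relu(3), 3)
  expect_equal(relu(0), 0)
  m <- matrix(c(-1, 2, 0, -3), 2)
  expect_identical(dim(relu(m)), dim(m))
})

test_that("kd-tree building splits on the widest axis with balanced halves", {
  pc <- pointcloud(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 10, 0), c(1, 10, 0)))
  tr <- build_kdtree(pc, depth = 2, seed = 1)
  expect_equal(tr$split_dims[1], 2)        # root splits on y (range 10)
  expect_equal(tr$split_dims[2:3], c(1, 1))  # both children split on x
  expect_length(tr$leaf_order, 4)
  # left subtree <= right subtree on the split axis, at every node
  leaves <- tr$points[tr$leaf_order, ]
  expect_lte(max(leaves[1:2, 2]), min(leaves[3:4, 2]))
  expect_lte(leaves[1, 1], leaves[2, 1])
  expect_lte(leaves[3, 1], leaves[4, 1])

  same <- pointcloud(matrix(1, 8, 3) + 0)
  tr2 <- build_kdtree(same, depth = 3, seed = 2)
  expect_length(tr2$leaf_order, 8)
  expect_setequal(tr2$leaf_order, 1:8)

  a <- build_kdtree(random_cloud(64, 5), 6, seed = 9)
  b <- build_kdtree(random_cloud(64, 5), 6, seed = 9)
  expect_identical(a, b)
  expect_error(build_kdtree(pc, 0), "depth")
})

test_that("forward pass matches a hand-computed depth-1 oracle", {
  pc <- pointcloud(rbind(c(0, 0, 0), c(1, 2, 3)))
  tr <- build_kdtree(pc, 1, seed = 1)
  model <- kdnet_new(1, n_classes = 2, widths = 2L, seed = 1)
  W <- matrix(seq(0.1, 1.2, by = 0.1), 2, 6)
  model$levels[[1]]$W <- array(rep(W, 3), dim = c(2, 6, 3))
  model$levels[[1]]$b <- matrix(0.5, 2, 3)
  model$fc$W <- matrix(c(1, -1, 2, 0.5), 2, 2)
  model$fc$b <- c(0.1, -0.2)
  leaves <- tr$points[tr$leaf_order, ]
  concat <- c(leaves[1, ], leaves[2, ])
  root <- pmax(W %*% concat + 0.5, 0)
  want <- drop(model$fc$W %*% root + model$fc$b)
  expect_equal(kdnet_forward(model, tr), want, tolerance = 1e-12)
})

test_that("constant networks and canonicalized order behave as expected", {
  model <- kdnet_new(5, 3, seed = 4)
  for (l in seq_along(model$levels)) {
    model$levels[[l]]$W[] <- 0
    model$levels[[l]]$b[] <- 0
  }
  model$fc$W[] <- 0
  model$fc$b <- c(0.3, -0.1, 2)
  tr <- build_kdtree(random_cloud(32, 6), 5, seed = 1)
  expect_equal(kdnet_forward(model, tr), c(0.3, -0.1, 2))

  # permutation invariance: same resampling seed, shuffled point order
  model2 <- kdnet_new(5, 2, seed = 5)
  pc <- random_cloud(32, 7)
  perm <- sample.int(32)
  s1 <- kdnet_forward(model2, build_kdtree(pc, 5, seed = 3))
  s2 <- kdnet_forward(model2, build_kdtree(subset_cloud(pc, perm), 5, seed = 3))
  expect_equal(s1, s2, tolerance = 1e-9)

  expect_error(kdnet_forward(model2, build_kdtree(pc, 4, seed = 1)), "depth")
})

test_that("zero learning rate freezes the accuracy history", {
  data <- generate_shape_dataset(2, 8, 16, seed = 9)
  fit <- train_kdnet(data, train_config(epochs = 5, learning_rate = 0,
                                        seed = 2), depth = 4)
  expect_equal(length(unique(fit$history$val_accuracy)), 1)
})

test_that("the default learning rate is no worse than a 3x larger one", {
  data <- generate_shape_dataset(2, 16, 32, seed = 5)
  acc <- vapply(c(0.003, 0.009), function(lr) {
    fit <- train_kdnet(data, train_config(epochs = 40, learning_rate = lr,
                                          seed = 1), depth = 5)
    utils::tail(fit$history$val_accuracy, 1)
  }, numeric(1))
  expect_gte(acc[1], acc[2] - 0.05)
})

test_that("training separates two easy shape classes and improves with epochs", {
  data <- generate_shape_dataset(2, 24, 32, seed = 7)
  fit <- train_kdnet(data, train_config(epochs = 60, learning_rate = 0.003,
                                        seed = 1), depth = 5)
  h <- fit$history
  expect_gte(utils::tail(h$val_accuracy, 1), 0.75)
  # later-epoch accuracy does not fall below the early level (epoch study
  # direction), with slack for the small validation set
  expect_gte(mean(h$val_accuracy[h$epoch > 50]),
             mean(h$val_accuracy[h$epoch <= 10]) - 0.05)
  expect_true(all(is.finite(h$loss)))
})
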