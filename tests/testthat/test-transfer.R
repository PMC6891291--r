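test_that("freeze-and-rewire keeps the levels bit-identical and swaps the head", {
  pre <- make_pretrained()
  m2 <- freeze_and_rewire(pre$model, 2, seed = 9)
  expect_true(m2$frozen)
  expect_identical(m2$levels, pre$model$levels)
  expect_equal(nrow(m2$fc$W), 2)
  expect_error(freeze_and_rewire(pre$model, 1), "at least 2")

  # root representation is untouched by the rewiring
  tr <- build_kdtree(random_cloud(32, 3), 5, seed = 4)
  expect_identical(kdnet_root(pre$model, tr), kdnet_root(m2, tr))
})

test_that("TrAdaBoost updates follow the stated weight rules", {
  w <- instance_weights(100, 10, 10)
  expect_equal(w$beta_source, 1 / (1 + sqrt(2 * log(100) / 10)),
               tolerance = 1e-12)
  expect_equal(round(w$beta_source, 4), 0.5103)
  expect_equal(sum(w$source_w) + sum(w$target_w), 1, tolerance = 1e-12)

  # no errors anywhere: weights unchanged after renormalization
  w0 <- tradaboost_update(w, rep(0L, 100), rep(0L, 10), 0)
  expect_equal(w0$source_w, w$source_w, tolerance = 1e-12)
  expect_equal(w0$target_w, w$target_w, tolerance = 1e-12)

  # one misclassified source example: only its weight drops relative to peers
  se <- c(1L, rep(0L, 99))
  w1 <- tradaboost_update(w, se, rep(0L, 10), 0.1)
  expect_lt(w1$source_w[1], w1$source_w[2])
  expect_equal(stats::var(w1$source_w[-1]), 0, tolerance = 1e-20)
  expect_equal(sum(w1$source_w) + sum(w1$target_w), 1, tolerance = 1e-12)
  expect_true(all(c(w1$source_w, w1$target_w) > 0))

  # misclassified target examples are up-weighted
  te <- c(1L, rep(0L, 9))
  w2 <- tradaboost_update(w, rep(0L, 100), te, 0.1)
  expect_gt(w2$target_w[1], w2$target_w[2])

  expect_error(tradaboost_update(w, rep(0L, 100), te, 0.6),
               class = "boosting_stopped")
})

test_that("weighted head loss scales exactly with an example's weight", {
  pre <- make_pretrained()
  m2 <- freeze_and_rewire(pre$model, 2, seed = 1)
  set.seed(8)
  roots <- matrix(stats::rnorm(5 * ncol(m2$fc$W)), 5)
  labels <- c(1L, 2L, 1L, 2L, 1L)
  w <- rep(0.2, 5)
  base <- head_weighted_loss(m2, roots, labels, w)
  w2 <- w; w2[3] <- 2 * w[3]
  doubled <- head_weighted_loss(m2, roots, labels, w2)
  single <- head_weighted_loss(m2, roots[3, , drop = FALSE], labels[3], w[3])
  expect_equal(doubled - base, single, tolerance = 1e-12)
})

test_that("transfer training reaches high target accuracy and stays frozen", {
  pre <- make_pretrained()
  target <- generate_silhouette_set(30, 30, 32, seed = 12)
  fit <- transfer_train(pre$model, pre$source, target,
                        train_config(epochs = 30, learning_rate = 0.003,
                                     seed = 3), n_boost = 4)
  expect_gte(max(fit$history$val_accuracy), 0.9)
  expect_identical(fit$model$levels, pre$model$levels)
  expect_true(all(c(fit$weights$source_w, fit$weights$target_w) > 0))
  expect_equal(sum(fit$weights$source_w) + sum(fit$weights$target_w), 1,
               tolerance = 1e-9)

  # classification of a generated cattle silhouette
  cl <- generate_silhouette_set(2, 2, 32, seed = 77)
  res <- classify_cloud(fit$model, cl$clouds[[1]], seed = 5)
  expect_identical(res$label, "cattle")
  expect_gt(res$score, 0.5)
  res2 <- classify_cloud(fit$model, cl$clouds[[1]], seed = 5)
  expect_identical(res, res2)
})

test_that("with one boosting round and zero learning rate the head is untouched", {
  pre <- make_pretrained()
  target <- generate_silhouette_set(6, 6, 32, seed = 13)
  cfg <- train_config(epochs = 3, learning_rate = 0, seed = 3)
  fit <- transfer_train(pre$model, pre$source, target, cfg, n_boost = 1)
  init <- freeze_and_rewire(pre$model, 2, seed = cfg$seed)
  expect_identical(fit$model$fc, init$fc)
})

test_that("classification ties break toward the lower class index", {
  m <- kdnet_new(2, 2, widths = c(4L, 4L), seed = 1)
  for (l in 1:2) { m$levels[[l]]$W[] <- 0; m$levels[[l]]$b[] <- 0 }
  m$fc$W[] <- 0
  m$fc$b <- c(0.7, 0.7)
  m$class_names <- c("cattle", "other")
  res <- classify_cloud(m, random_cloud(4, 2), seed = 1)
  expect_identical(res$label, "cattle")
  expect_equal(res$score, 0.5)
})
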