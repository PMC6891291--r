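#' Freeze a pre-trained model and rewire its head
#'
#' Marks all level parameters non-trainable (they stay bit-identical through
#' any later training) and replaces the fully connected layer by a freshly
#' initialized affine map to `n_classes_new` outputs.
#'
#' @param model a trained `kdnet_model`.
#' @param n_classes_new new output class count (>= 2).
#' @param seed seed for the new head's initialization.
#' @return The rewired, frozen `kdnet_model`.
#' @export
freeze_and_rewire <- function(model, n_classes_new, seed = 1L) {
  if (n_classes_new < 2L) stop("n_classes_new must be at least 2")
  w_root <- model$widths[model$depth]
  model$fc <- with_seed(seed, list(
    W = matrix(stats::rnorm(n_classes_new * w_root, 0, 0.01),
               n_classes_new, w_root),
    b = numeric(n_classes_new)))
  model$n_classes <- as.integer(n_classes_new)
  model$frozen <- TRUE
  model$class_names <- NULL
  model
}

#' Instance weights for boosting-based transfer
#'
#' Positive per-example weights over the source and target sets, jointly
#' normalized to sum 1. `beta_source = 1 / (1 + sqrt(2 ln(n_source) / N))`
#' is the fixed source down-weighting factor for `N` boosting iterations.
#'
#' @param n_source,n_target example counts.
#' @param n_boost total number of boosting iterations `N`.
#' @return An `instance_weights` object.
#' @export
instance_weights <- function(n_source, n_target, n_boost) {
  w <- rep(1 / (n_source + n_target), n_source + n_target)
  structure(list(source_w = w[seq_len(n_source)],
                 target_w = w[n_source + seq_len(n_target)],
                 beta_source = 1 / (1 + sqrt(2 * log(n_source) / n_boost)),
                 iteration = 0L),
            class = "instance_weights")
}

#' One TrAdaBoost weight update
#'
#' Misclassified source examples are multiplied by the fixed factor
#' `beta_source` (shrinking the influence of source instances that disagree
#' with the target concept); misclassified target examples are multiplied by
#' `beta_t^(-1)` with `beta_t = e / (1 - e)` where `e` is the weighted
#' target error rate (growing the influence of hard target instances). All
#' weights are then renormalized to sum 1.
#'
#' @param weights an [instance_weights()] object.
#' @param source_errors,target_errors 0/1 per-example error indicators.
#' @param target_error_rate weighted target error rate, must be < 0.5; at or
#'   above 0.5 a `boosting_stopped` condition is signalled.
#' @return The updated `instance_weights`.
#' @export
tradaboost_update <- function(weights, source_errors, target_errors,
                              target_error_rate) {
  if (target_error_rate < 0) stop("target_error_rate must be non-negative")
  if (target_error_rate >= 0.5) {
    cond <- structure(
      class = c("boosting_stopped", "error", "condition"),
      list(message = sprintf(
        "tradaboost_update: target error rate %.3f >= 0.5, boosting stopped",
        target_error_rate), call = sys.call(-1)))
    stop(cond)
  }
  sw <- weights$source_w * weights$beta_source^source_errors
  beta_t <- target_error_rate / (1 - target_error_rate)
  tw <- if (target_error_rate == 0) {
    weights$target_w
  } else {
    weights$target_w * beta_t^(-target_errors)
  }
  tot <- sum(sw) + sum(tw)
  weights$source_w <- sw / tot
  weights$target_w <- tw / tot
  weights$iteration <- weights$iteration + 1L
  weights
}

# Frozen root representations of a list of clouds (one fresh tree each).
frozen_roots <- function(model, clouds, seed) {
  t(vapply(seq_along(clouds), function(i) {
    tree <- build_kdtree(clouds[[i]], model$depth, seed = derive_seed(seed, i))
    kdnet_root(model, tree)
  }, numeric(model$widths[model$depth])))
}

#' Weighted cross-entropy of the head on precomputed representations
#' @param model `kdnet_model` (only its fc head is used).
#' @param roots matrix of root representations (rows = examples).
#' @param labels integer labels.
#' @param weights per-example weights.
#' @return `sum(weights * per-example cross-entropy)`.
#' @export
head_weighted_loss <- function(model, roots, labels, weights) {
  s <- roots %*% t(model$fc$W)
  s <- sweep(s, 2, model$fc$b, `+`)
  p <- t(apply(s, 1, softmax))
  -sum(weights * log(pmax(p[cbind(seq_along(labels), labels)], 1e-12)))
}

train_head <- function(model, roots, labels, weights, epochs, lr, seed) {
  n <- nrow(roots)
  for (ep in seq_len(epochs)) {
    ord <- with_seed(derive_seed(seed, ep), sample.int(n))
    for (i in ord) {
      s <- drop(model$fc$W %*% roots[i, ] + model$fc$b)
      p <- softmax(s)
      d <- p
      d[labels[i]] <- d[labels[i]] - 1
      d <- d * weights[i] * n  # weights average to 1/n, so scale keeps lr meaningful
      model$fc$W <- model$fc$W - lr * (d %o% roots[i, ])
      model$fc$b <- model$fc$b - lr * d
    }
  }
  model
}

#' Transfer-train a frozen model onto a 2-class target task
#'
#' Freezes the pre-trained levels, rewires the head to 2 classes
#' (cattle / other) and retrains the head only, with TrAdaBoost instance
#' re-weighting: per boosting iteration, the head is fitted by weighted SGD
#' on source examples (all labeled "other") plus target examples, evaluated,
#' and the weights updated by [tradaboost_update()]. The head with the best
#' held-out target accuracy across iterations is returned.
#'
#' @param model pre-trained `kdnet_model` (source task).
#' @param source a [labeled_cloud_set()] of source-domain clouds; all are
#'   treated as class "other" for the target task.
#' @param target a [labeled_cloud_set()] with classes cattle/other.
#' @param cfg a [train_config()] (epochs = head-SGD passes per boosting
#'   iteration).
#' @param n_boost number of boosting iterations.
#' @return List with `model` (best head, frozen levels), `history` (data
#'   frame: iteration, target error rate, held-out accuracy), `weights`.
#' @export
transfer_train <- function(model, source, target, cfg = train_config(),
                           n_boost = 5L) {
  if (length(target$clouds) == 0L) stop("transfer_train: empty target set")
  if (!identical(target$class_names, c("cattle", "other"))) {
    stop("transfer_train: target classes must be c('cattle', 'other')")
  }
  model <- freeze_and_rewire(model, 2L, seed = cfg$seed)
  model$class_names <- target$class_names

  n_t <- length(target$clouds)
  val_idx <- with_seed(derive_seed(cfg$seed, 11), {
    unlist(lapply(split(seq_len(n_t), target$labels), function(ix) {
      sample(ix, max(1L, round(length(ix) * cfg$val_fraction)))
    }))
  })
  tr_idx <- setdiff(seq_len(n_t), val_idx)

  src_roots <- frozen_roots(model, source$clouds, derive_seed(cfg$seed, 12))
  tgt_roots <- frozen_roots(model, target$clouds, derive_seed(cfg$seed, 13))
  src_labels <- rep(2L, length(source$clouds))  # source domain = "other"
  tgt_labels <- target$labels

  w <- instance_weights(length(src_labels), length(tr_idx), n_boost)
  best <- list(acc = -Inf, fc = model$fc)
  history <- data.frame(iteration = integer(0), target_error = numeric(0),
                        val_accuracy = numeric(0))
  roots_all <- rbind(src_roots, tgt_roots[tr_idx, , drop = FALSE])
  labels_all <- c(src_labels, tgt_labels[tr_idx])

  for (it in seq_len(n_boost)) {
    model <- train_head(model, roots_all, labels_all,
                        c(w$source_w, w$target_w),
                        epochs = cfg$epochs, lr = cfg$learning_rate,
                        seed = derive_seed(cfg$seed, 20, it))
    pred <- function(roots) {
      s <- sweep(roots %*% t(model$fc$W), 2, model$fc$b, `+`)
      max.col(s, ties.method = "first")
    }
    src_err <- as.integer(pred(src_roots) != src_labels)
    tgt_err_tr <- as.integer(pred(tgt_roots[tr_idx, , drop = FALSE]) !=
                               tgt_labels[tr_idx])
    e_t <- sum(w$target_w * tgt_err_tr) / sum(w$target_w)
    acc <- mean(pred(tgt_roots[val_idx, , drop = FALSE]) ==
                  tgt_labels[val_idx])
    history <- rbind(history, data.frame(iteration = it, target_error = e_t,
                                         val_accuracy = acc))
    if (acc > best$acc) best <- list(acc = acc, fc = model$fc)
    w <- tryCatch(tradaboost_update(w, src_err, tgt_err_tr, e_t),
                  boosting_stopped = function(c) NULL)
    if (is.null(w)) break
  }
  model$fc <- best$fc
  list(model = model, history = history, weights = w)
}

#' Classify a cloud with a trained 2-class model
#'
#' Builds a seeded Kd-tree over the cloud, runs the forward pass and takes
#' the argmax (ties break toward the lower class index). The score is the
#' softmax probability of the chosen class.
#'
#' @param model trained `kdnet_model` with class names.
#' @param cloud a [pointcloud()].
#' @param seed tree-build seed; identical inputs and seeds give identical
#'   outputs.
#' @return List with `label` (class name) and `score`.
#' @export
classify_cloud <- function(model, cloud, seed = 1L) {
  tree <- build_kdtree(cloud, model$depth, seed = seed)
  s <- kdnet_forward(model, tree)
  p <- softmax(s)
  k <- which.max(p)  # which.max already breaks ties toward the lower index
  label <- if (!is.null(model$class_names)) model$class_names[k] else as.character(k)
  list(label = label, score = unname(p[k]))
}
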