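#' Rectified linear unit
#' @param x numeric input.
#' @return `max(0, x)`, elementwise.
#' @export
relu <- function(x) pmax(x, 0)  # x first so matrix inputs keep their dim

#' Build a balanced Kd-tree index over a cloud
#'
#' Resamples the cloud to exactly `2^depth` points (without replacement when
#' possible, with replacement otherwise), then recursively median-splits:
#' at each node the split axis is the axis of largest coordinate range in
#' the node's point set, the sorted lower half goes left and the upper half
#' right, and the split value is the midpoint of the two middle coordinates.
#' `seed` drives the resampling and the coordinate tie-breaks, so the index
#' is fully deterministic.
#'
#' @param cloud a [pointcloud()].
#' @param depth tree depth (>= 1); the tree has `2^depth` leaves, one point
#'   each.
#' @param seed integer seed.
#' @return A `kdtree_index`: list with `depth`, `split_dims` and
#'   `split_values` (heap order, root = 1), `leaf_order` (point row per leaf
#'   position), and `points` (the resampled coordinate matrix).
#' @export
build_kdtree <- function(cloud, depth, seed = 1L) {
  if (depth < 1L) stop("build_kdtree: depth must be at least 1")
  m <- as.integer(2^depth)
  pts <- coords(cloud)
  with_seed(seed, {
    take <- sample.int(nrow(pts), m, replace = nrow(pts) < m)
    pts <- pts[take, , drop = FALSE]
    tie <- stats::runif(m)
    split_dims <- integer(m - 1L)
    split_values <- numeric(m - 1L)
    leaf_order <- integer(m)
    recurse <- function(node, idx) {
      if (length(idx) == 1L) {
        leaf_order[node - (m - 1L)] <<- idx
        return(invisible(NULL))
      }
      rng <- apply(pts[idx, , drop = FALSE], 2, function(v) diff(range(v)))
      d <- which.max(rng)
      ord <- idx[order(pts[idx, d], tie[idx])]
      half <- length(ord) %/% 2L
      split_dims[node] <<- d
      split_values[node] <<- (pts[ord[half], d] + pts[ord[half + 1L], d]) / 2
      recurse(2L * node, ord[seq_len(half)])
      recurse(2L * node + 1L, ord[half + seq_len(half)])
    }
    recurse(1L, seq_len(m))
    structure(list(depth = as.integer(depth), split_dims = split_dims,
                   split_values = split_values, leaf_order = leaf_order,
                   points = pts, sample_idx = take),
              class = "kdtree_index")
  })
}

default_widths <- function(depth) pmin(8L * 2L^(seq_len(depth) - 1L), 128L)

#' Initialize a Kd-network model
#'
#' A level-wise shared-weight network over a balanced Kd-tree: leaves carry
#' the raw point coordinates; every internal node at level `l` (counted from
#' the leaves) applies `relu(affine(concat(left, right)))`, where the affine
#' map is shared by all nodes of that level with the same split axis; a
#' final fully connected layer maps the root representation to class scores.
#'
#' @param depth tree depth (number of merge levels).
#' @param n_classes number of output classes.
#' @param widths representation width per level; default doubles from 8,
#'   capped at 128.
#' @param seed integer seed for the random initialization.
#' @return A `kdnet_model`.
#' @export
kdnet_new <- function(depth, n_classes, widths = default_widths(depth),
                      seed = 1L) {
  if (length(widths) != depth) stop("widths must have one entry per level")
  with_seed(seed, {
    levels <- vector("list", depth)
    w_in <- 3L
    for (l in seq_len(depth)) {
      w_out <- widths[l]
      sd <- sqrt(2 / (2 * w_in))
      W <- array(stats::rnorm(w_out * 2 * w_in * 3, 0, sd),
                 dim = c(w_out, 2L * w_in, 3L))
      levels[[l]] <- list(W = W, b = matrix(0, w_out, 3))
      w_in <- w_out
    }
    fc <- list(W = matrix(stats::rnorm(n_classes * w_in, 0, 0.01),
                          n_classes, w_in),
               b = numeric(n_classes))
    structure(list(depth = as.integer(depth), widths = widths,
                   n_classes = as.integer(n_classes), levels = levels,
                   fc = fc, frozen = FALSE, class_names = NULL),
              class = "kdnet_model")
  })
}

# Forward pass keeping the intermediate activations needed for backprop.
kdnet_forward_full <- function(model, tree) {
  if (tree$depth != model$depth) {
    stop("kdnet_forward: tree depth does not match model depth")
  }
  reps <- t(tree$points[tree$leaf_order, , drop = FALSE])  # 3 x 2^depth
  cache <- vector("list", model$depth)
  for (l in seq_len(model$depth)) {
    m <- ncol(reps) %/% 2L
    Z <- rbind(reps[, seq(1, 2 * m, by = 2), drop = FALSE],
               reps[, seq(2, 2 * m, by = 2), drop = FALSE])
    first <- 2L^(model$depth - l)
    axes <- tree$split_dims[first:(2L * first - 1L)]
    pre <- matrix(0, model$widths[l], m)
    for (d in 1:3) {
      cols <- which(axes == d)
      if (length(cols) == 0L) next
      pre[, cols] <- model$levels[[l]]$W[, , d] %*% Z[, cols, drop = FALSE] +
        model$levels[[l]]$b[, d]
    }
    cache[[l]] <- list(Z = Z, pre = pre, axes = axes)
    reps <- relu(pre)
  }
  root <- reps[, 1]
  scores <- drop(model$fc$W %*% root + model$fc$b)
  list(scores = scores, root = root, cache = cache)
}

#' Forward pass of the Kd-network
#' @param model a `kdnet_model`.
#' @param tree a `kdtree_index` of matching depth.
#' @return Numeric class-score vector of length `n_classes`.
#' @export
kdnet_forward <- function(model, tree) kdnet_forward_full(model, tree)$scores

#' Root representation of a cloud under a model
#' @inheritParams kdnet_forward
#' @return The root representation vector (input to the fully connected
#'   layer).
#' @export
kdnet_root <- function(model, tree) kdnet_forward_full(model, tree)$root

softmax <- function(s) {
  e <- exp(s - max(s))
  e / sum(e)
}

# Backward pass; returns gradients in the same shapes as the parameters.
# When the model is frozen only the fc gradient is produced.
kdnet_backward <- function(model, tree, fwd, label, weight = 1) {
  p <- softmax(fwd$scores)
  dscore <- p
  dscore[label] <- dscore[label] - 1
  dscore <- dscore * weight
  g_fc <- list(W = dscore %o% fwd$root, b = dscore)
  if (isTRUE(model$frozen)) {
    return(list(fc = g_fc, levels = NULL,
                loss = -weight * log(max(p[label], 1e-12))))
  }
  g_levels <- vector("list", model$depth)
  drep <- matrix(drop(crossprod(model$fc$W, dscore)), ncol = 1)
  for (l in rev(seq_len(model$depth))) {
    cache <- fwd$cache[[l]]
    dpre <- drep * (cache$pre > 0)
    w_in <- nrow(cache$Z) %/% 2L
    gW <- array(0, dim = dim(model$levels[[l]]$W))
    gb <- matrix(0, model$widths[l], 3)
    dZ <- matrix(0, nrow(cache$Z), ncol(cache$Z))
    for (d in 1:3) {
      cols <- which(cache$axes == d)
      if (length(cols) == 0L) next
      gW[, , d] <- dpre[, cols, drop = FALSE] %*% t(cache$Z[, cols, drop = FALSE])
      gb[, d] <- rowSums(dpre[, cols, drop = FALSE])
      dZ[, cols] <- crossprod(model$levels[[l]]$W[, , d],
                              dpre[, cols, drop = FALSE])
    }
    g_levels[[l]] <- list(W = gW, b = gb)
    m <- ncol(cache$Z)
    drep_child <- matrix(0, w_in, 2L * m)
    drep_child[, seq(1, 2 * m, by = 2)] <- dZ[seq_len(w_in), , drop = FALSE]
    drep_child[, seq(2, 2 * m, by = 2)] <- dZ[w_in + seq_len(w_in), , drop = FALSE]
    drep <- drep_child
  }
  list(fc = g_fc, levels = g_levels,
       loss = -weight * log(max(p[label], 1e-12)))
}

apply_gradients <- function(model, grads, lr) {
  model$fc$W <- model$fc$W - lr * grads$fc$W
  model$fc$b <- model$fc$b - lr * grads$fc$b
  if (!is.null(grads$levels) && !isTRUE(model$frozen)) {
    for (l in seq_along(grads$levels)) {
      model$levels[[l]]$W <- model$levels[[l]]$W - lr * grads$levels[[l]]$W
      model$levels[[l]]$b <- model$levels[[l]]$b - lr * grads$levels[[l]]$b
    }
  }
  model
}

#' Training configuration
#' @param epochs number of passes over the training set.
#' @param learning_rate SGD step size (default 0.003).
#' @param batch_size examples per gradient step.
#' @param seed master seed (initialization, splits, shuffles, per-iteration
#'   tree rebuilds).
#' @param val_fraction held-out fraction per class.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 100L, learning_rate = 0.003,
                         batch_size = 1L, seed = 1L, val_fraction = 0.25) {
  if (epochs < 1L) stop("epochs must be at least 1")
  if (learning_rate < 0) stop("learning_rate must be non-negative")
  list(epochs = as.integer(epochs), learning_rate = learning_rate,
       batch_size = as.integer(batch_size), seed = as.integer(seed),
       val_fraction = val_fraction)
}

derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  s <- 0
  for (p in parts) s <- (s * 7919 + as.numeric(p) + 1) %% 2147483647
  as.integer(s)
}

#' Train a Kd-network classifier
#'
#' Plain stochastic gradient descent on the softmax cross-entropy. A fresh
#' Kd-tree is built for every cloud in every epoch (with seeds derived from
#' `cfg$seed`), which acts as the method's input canonicalization and as a
#' mild augmentation. A stratified fraction of the data is held out and its
#' accuracy recorded per epoch.
#'
#' @param data a [labeled_cloud_set()] with at least 2 classes; clouds must
#'   all have a power-of-two compatible size (they are resampled to
#'   `2^depth` points by the tree build).
#' @param cfg a [train_config()].
#' @param depth tree/model depth; default `log2` of the first cloud's size.
#' @param widths per-level representation widths.
#' @return List with `model` (`kdnet_model`) and `history` (data frame of
#'   epoch, mean training loss, held-out accuracy).
#' @export
train_kdnet <- function(data, cfg = train_config(),
                        depth = as.integer(round(log2(npoints(data$clouds[[1]])))),
                        widths = default_widths(depth)) {
  n_classes <- length(data$class_names)
  if (n_classes < 2L) stop("train_kdnet: need at least 2 classes")
  model <- kdnet_new(depth, n_classes, widths, seed = cfg$seed)
  model$class_names <- data$class_names
  n <- length(data$clouds)
  val_idx <- with_seed(derive_seed(cfg$seed, 1), {
    unlist(lapply(split(seq_len(n), data$labels), function(ix) {
      k <- max(1L, round(length(ix) * cfg$val_fraction))
      sample(ix, k)
    }))
  })
  train_idx <- setdiff(seq_len(n), val_idx)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_accuracy = numeric(0))
  for (epoch in seq_len(cfg$epochs)) {
    ord <- with_seed(derive_seed(cfg$seed, 2, epoch),
                     sample(train_idx, length(train_idx)))
    losses <- numeric(0)
    batch <- NULL
    nb <- 0L
    for (i in ord) {
      tree <- build_kdtree(data$clouds[[i]], depth,
                           seed = derive_seed(cfg$seed, 3, epoch, i))
      fwd <- kdnet_forward_full(model, tree)
      g <- kdnet_backward(model, tree, fwd, data$labels[i])
      losses <- c(losses, g$loss)
      if (is.null(batch)) batch <- g else batch <- add_grads(batch, g)
      nb <- nb + 1L
      if (nb == cfg$batch_size || i == ord[length(ord)]) {
        model <- apply_gradients(model, scale_grads(batch, 1 / nb),
                                 cfg$learning_rate)
        batch <- NULL; nb <- 0L
      }
    }
    if (!all(is.finite(losses))) {
      stop("train_kdnet: training diverged (non-finite loss) at epoch ", epoch)
    }
    acc <- kdnet_accuracy(model, data, val_idx,
                          seed = derive_seed(cfg$seed, 4, epoch))
    history <- rbind(history, data.frame(epoch = epoch,
                                         loss = mean(losses),
                                         val_accuracy = acc))
  }
  list(model = model, history = history)
}

add_grads <- function(a, b) {
  a$fc$W <- a$fc$W + b$fc$W
  a$fc$b <- a$fc$b + b$fc$b
  if (!is.null(a$levels)) {
    for (l in seq_along(a$levels)) {
      a$levels[[l]]$W <- a$levels[[l]]$W + b$levels[[l]]$W
      a$levels[[l]]$b <- a$levels[[l]]$b + b$levels[[l]]$b
    }
  }
  a$loss <- a$loss + b$loss
  a
}

scale_grads <- function(g, s) {
  g$fc$W <- g$fc$W * s
  g$fc$b <- g$fc$b * s
  if (!is.null(g$levels)) {
    for (l in seq_along(g$levels)) {
      g$levels[[l]]$W <- g$levels[[l]]$W * s
      g$levels[[l]]$b <- g$levels[[l]]$b * s
    }
  }
  g
}

#' Accuracy of a model on a subset of a labeled set
#' @param model a `kdnet_model`.
#' @param data a [labeled_cloud_set()].
#' @param idx indices to evaluate (default all).
#' @param seed seed for the tree builds.
#' @return Fraction correct.
#' @export
kdnet_accuracy <- function(model, data, idx = seq_along(data$clouds),
                           seed = 1L) {
  correct <- 0L
  for (i in idx) {
    tree <- build_kdtree(data$clouds[[i]], model$depth,
                         seed = derive_seed(seed, i))
    s <- kdnet_forward(model, tree)
    if (which.max(s) == data$labels[i]) correct <- correct + 1L
  }
  correct / length(idx)
}
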