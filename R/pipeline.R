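#' Default pipeline configuration
#'
#' Nested configuration for the command-line pipeline: scene generation,
#' preprocessing/segmentation/measurement parameters, classifier training
#' and transfer settings, plus a master `seed` that fans out to per-stage
#' seeds via [stage_seed()]. Serializable to and from YAML.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    scene = list(n = 1L, noise_sigma = 0.003, clutter_count = 2L),
    measure = list(leaf = 0.02, sor_k = 8L, sor_alpha = 1.0,
                   cluster_tol = 0.06, cluster_min = 200L,
                   plane_thresh = 0.02, ransac_iter = 200L, curv_k = 16L,
                   chest_cyl_radius = 0.05),
    db = list(seeds = c(101L, 102L, 103L), radius = 0.10),
    train = list(n_classes = 4L, per_class = 12L, n_points = 32L,
                 epochs = 60L, learning_rate = 0.003),
    transfer = list(n_cattle = 30L, n_distractor = 30L, n_points = 32L,
                    epochs = 40L, n_boost = 5L)
  )
}

#' Read and validate a pipeline configuration from YAML
#'
#' Unknown keys (at the top level or inside a known block) are rejected so
#' that typos cannot silently fall back to defaults.
#'
#' @param path YAML file; `NULL` returns [default_config()].
#' @return Validated configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  bad <- setdiff(names(user), names(cfg))
  if (length(bad) > 0L) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  }
  for (k in names(user)) {
    if (is.list(cfg[[k]]) && is.list(user[[k]])) {
      badk <- setdiff(names(user[[k]]), names(cfg[[k]]))
      if (length(badk) > 0L) {
        stop("unknown configuration key(s) in '", k, "': ",
             paste(badk, collapse = ", "))
      }
      cfg[[k]][names(user[[k]])] <- user[[k]]
    } else {
      cfg[[k]] <- user[[k]]
    }
  }
  cfg
}

#' Per-stage seed derived from the master seed
#'
#' Hashes the stage name into the master seed so stages can be rerun in
#' isolation and still be reproducible.
#'
#' @param seed master seed.
#' @param stage stage name.
#' @return Integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  derive_seed(seed, utf8ToInt(stage))
}

measure_params_from_config <- function(cfg) {
  m <- cfg$measure
  measure_params(sor_k = m$sor_k, sor_alpha = m$sor_alpha, leaf = m$leaf,
                 cluster_tol = m$cluster_tol, cluster_min = m$cluster_min,
                 plane_thresh = m$plane_thresh, ransac_iter = m$ransac_iter,
                 curv_k = m$curv_k, chest_cyl_radius = m$chest_cyl_radius)
}

#' Run a pipeline command
#'
#' Programmatic entry point behind the command-line script
#' (`inst/cli/bovimetrics.R`). Commands: `synth` (write scenes plus ground
#' truth), `measure` (measure one scene file against a feature database),
#' `builddb` (build and save the reference feature database), `train`
#' (pre-train the classifier on the multi-class shape set), `transfer`
#' (transfer it to cattle/other), `classify` (label one cloud file). All
#' artifacts are plain text (PCD/JSON/CSV).
#'
#' @param command one of `synth`, `builddb`, `measure`, `train`, `transfer`,
#'   `classify`.
#' @param config configuration list from [read_config()].
#' @param input input file (scene or cloud), where the command needs one.
#' @param output output file or directory.
#' @param db_path feature-database JSON (for `measure`; written by
#'   `builddb`).
#' @param model_path model checkpoint JSON (`train`/`transfer`/`classify`).
#' @return Command-dependent result, invisibly.
#' @export
run_command <- function(command, config = default_config(), input = NULL,
                        output = NULL, db_path = NULL, model_path = NULL) {
  command <- match.arg(command, c("synth", "builddb", "measure", "train",
                                  "transfer", "classify"))
  seed <- config$seed
  switch(command,
    synth = {
      if (is.null(output)) stop("synth: --output directory required")
      dir.create(output, showWarnings = FALSE, recursive = TRUE)
      sc_cfg <- scene_config(noise_sigma = config$scene$noise_sigma,
                             clutter_count = config$scene$clutter_count)
      files <- character(0)
      for (i in seq_len(config$scene$n)) {
        s <- stage_seed(seed, paste0("synth", i))
        scene <- generate_scene(sc_cfg, seed = s)
        f <- file.path(output, sprintf("scene_%03d.pcd", i))
        write_pointcloud(scene$cloud, f)
        truth <- scene$truth
        jsonlite::write_json(
          list(dimensions_true = truth$dimensions_true,
               landmarks_true = truth$landmarks_true,
               ground_plane = truth$ground_plane,
               sampling_step = truth$sampling_step, seed = truth$seed),
          file.path(output, sprintf("scene_%03d_truth.json", i)),
          digits = NA, auto_unbox = TRUE)
        files <- c(files, f)
      }
      message(sprintf("synth: wrote %d scene(s) to %s", length(files), output))
      invisible(files)
    },
    builddb = {
      if (is.null(output)) stop("builddb: --output file required")
      db <- build_reference_db(config$db$seeds,
                               params = measure_params_from_config(config),
                               radius = config$db$radius)
      save_feature_db(db, output)
      message("builddb: wrote ", output, " (max tau = ", signif(max(db$tau), 4), ")")
      invisible(output)
    },
    measure = {
      if (is.null(input)) stop("measure: --input scene file required")
      if (is.null(db_path)) stop("measure: --db feature database required")
      cloud <- read_pointcloud(input)
      db <- read_feature_db(db_path)
      res <- measure_pipeline(cloud, db,
                              params = measure_params_from_config(config),
                              seed = stage_seed(seed, "measure"))
      dims <- res$dimensions
      out <- list(dimensions = stats::setNames(
        lapply(dimension_names(), function(d) dims[[d]]), dimension_names()),
        landmarks = lapply(dims$landmarks, as.numeric),
        config = config)
      if (!is.null(output)) {
        jsonlite::write_json(out, output, digits = NA, auto_unbox = TRUE)
        message("measure: wrote ", output)
      }
      invisible(out)
    },
    train = {
      tc <- config$train
      data <- generate_shape_dataset(tc$n_classes, tc$per_class, tc$n_points,
                                     seed = stage_seed(seed, "trainset"))
      fit <- train_kdnet(data, train_config(epochs = tc$epochs,
                                            learning_rate = tc$learning_rate,
                                            seed = stage_seed(seed, "train")))
      if (!is.null(model_path)) save_kdnet(fit$model, model_path)
      if (!is.null(output)) {
        utils::write.csv(fit$history, output, row.names = FALSE)
      }
      message(sprintf("train: final held-out accuracy %.3f",
                      utils::tail(fit$history$val_accuracy, 1)))
      invisible(fit)
    },
    transfer = {
      if (is.null(model_path)) stop("transfer: --model checkpoint required")
      model <- read_kdnet(model_path)
      tc <- config$transfer
      target <- generate_silhouette_set(tc$n_cattle, tc$n_distractor,
                                        tc$n_points,
                                        seed = stage_seed(seed, "target"))
      source <- generate_shape_dataset(config$train$n_classes,
                                       config$train$per_class, tc$n_points,
                                       seed = stage_seed(seed, "trainset"))
      fit <- transfer_train(model, source, target,
                            train_config(epochs = tc$epochs,
                                         seed = stage_seed(seed, "transfer")),
                            n_boost = tc$n_boost)
      save_kdnet(fit$model, model_path)
      if (!is.null(output)) {
        utils::write.csv(fit$history, output, row.names = FALSE)
      }
      message(sprintf("transfer: best held-out target accuracy %.3f",
                      max(fit$history$val_accuracy)))
      invisible(fit)
    },
    classify = {
      if (is.null(input)) stop("classify: --input cloud file required")
      if (is.null(model_path)) stop("classify: --model checkpoint required")
      model <- read_kdnet(model_path)
      cloud <- read_pointcloud(input)
      res <- classify_cloud(model, cloud, seed = stage_seed(seed, "classify"))
      message(sprintf("classify: %s (score %.3f)", res$label, res$score))
      invisible(res)
    }
  )
}

#' Save / load a Kd-network model as a JSON checkpoint
#' @param model a `kdnet_model`.
#' @param path file path.
#' @return `path` (save) or the `kdnet_model` (load).
#' @export
save_kdnet <- function(model, path) {
  fmt <- function(x) sprintf("%.17g", as.numeric(x))  # bit-exact round trip
  obj <- list(depth = model$depth, widths = model$widths,
              n_classes = model$n_classes, frozen = model$frozen,
              class_names = model$class_names,
              levels = lapply(model$levels, function(lv) {
                list(W = fmt(lv$W), dim = dim(lv$W), b = fmt(lv$b))
              }),
              fc = list(W = fmt(model$fc$W), dim = dim(model$fc$W),
                        b = fmt(model$fc$b)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_kdnet
#' @export
read_kdnet <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(x) as.numeric(unlist(x))
  levels <- lapply(o$levels, function(lv) {
    d <- as.integer(unlist(lv$dim))
    list(W = array(num(lv$W), dim = d), b = matrix(num(lv$b), nrow = d[1]))
  })
  fcd <- as.integer(unlist(o$fc$dim))
  structure(list(depth = as.integer(o$depth),
                 widths = as.integer(unlist(o$widths)),
                 n_classes = as.integer(o$n_classes), levels = levels,
                 fc = list(W = matrix(num(o$fc$W), fcd[1], fcd[2]),
                           b = num(o$fc$b)),
                 frozen = isTRUE(o$frozen),
                 class_names = if (is.null(o$class_names)) NULL
                               else as.character(unlist(o$class_names))),
            class = "kdnet_model")
}
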