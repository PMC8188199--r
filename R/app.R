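# End-to-end runs: configuration, dispatch, artifacts, model export.

#' Run configuration
#'
#' One YAML-serializable object describing a complete end-to-end run.
#' Fields depend on the task:
#' \describe{
#'   \item{synth}{`kind` (`"shapes"`, `"stained"`, `"events"`), generator
#'     parameters, `out_dir`}
#'   \item{train}{`train_path`/`valid_path` (HDF5 containers or class
#'     folders), `model` (architecture name), `training` (a
#'     [training_config()] or its field list), optional `control_file`,
#'     `out_dir`}
#'   \item{evaluate}{`checkpoint`, `data_path`, `out_dir`}
#'   \item{tilepipe}{`train_paths`/`valid_paths` (paired original +
#'     green-overlay labeled images), tiling parameters, `out_dir`}
#'   \item{export}{`checkpoint`, `format`, `out_dir`}
#' }
#'
#' @param task one of `"synth"`, `"train"`, `"evaluate"`, `"tilepipe"`,
#'   `"export"`
#' @param ... task-specific fields (see above)
#' @param out_dir output directory; a timestamped run directory is created
#'   inside it
#' @return object of class `run_config`
#' @export
run_config <- function(task = c("synth", "train", "evaluate", "tilepipe",
                                "export"),
                       ..., out_dir = ".") {
  task <- match.arg(task)
  structure(c(list(task = task, out_dir = out_dir), list(...)),
            class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file with a `task` field and task-specific fields
#' @return a `run_config`
#' @export
read_run_config <- function(path) {
  y <- yaml::yaml.load_file(path)
  if (is.null(y$task)) stop_dc("config missing required field 'task'")
  do.call(run_config, y)
}

load_any_dataset <- function(path, split = "train") {
  if (dir.exists(path)) load_folder(path, split)
  else if (grepl("\\.(h5|hdf5)$", path)) read_imageset_h5(path)
  else stop_dc("cannot load dataset from ", path,
               " (expected a class folder or .h5 container)")
}

training_config_from_fields <- function(fields) {
  if (inherits(fields, "training_config")) return(fields)
  fields <- fields %||% list()
  aug <- fields$augmentation
  if (!is.null(aug) && !inherits(aug, "augmentation_config")) {
    if (is.character(aug)) aug <- preset_config(aug)
    else aug <- do.call(augmentation_config, aug)
    fields$augmentation <- aug
  }
  do.call(training_config, fields)
}

new_run_dir <- function(out_dir, task) {
  stamp <- format(Sys.time(), "%Y%m%d_%H%M%S")
  d <- file.path(out_dir, paste0(task, "_", stamp))
  i <- 0L
  while (dir.exists(d)) { i <- i + 1L; d <- file.path(out_dir,
                          paste0(task, "_", stamp, "_", i)) }
  dir.create(d, recursive = TRUE)
  d
}

run_log <- function(run_dir, ...) {
  line <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
  cat(line, "\n", sep = "", file = file.path(run_dir, "run.log"),
      append = TRUE)
  message(line)
}

#' Execute an end-to-end run
#'
#' Dispatches on `config$task`, writes all artifacts (checkpoints,
#' meta-file, history CSV, evaluation reports, tile maps, fixtures) under
#' a timestamped run directory, and logs per-step lines to console and
#' `run.log`. Two runs with identical config and seed produce identical
#' history CSVs.
#'
#' @param config a [run_config()] or path to a YAML config
#' @param seed master seed; overrides the seed in the config when given
#' @return the run directory path, invisibly; errors propagate as R
#'   conditions (the CLI converts them to nonzero exit codes)
#' @export
run <- function(config, seed = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  run_dir <- new_run_dir(config$out_dir, config$task)
  run_log(run_dir, "task '", config$task, "' started")
  switch(config$task,
    synth = run_synth(config, run_dir, seed),
    train = run_train(config, run_dir, seed),
    evaluate = run_evaluate(config, run_dir),
    tilepipe = run_tilepipe(config, run_dir, seed),
    export = run_export(config, run_dir))
  run_log(run_dir, "task '", config$task, "' finished")
  invisible(run_dir)
}

run_synth <- function(config, run_dir, seed) {
  seed <- seed %||% config$seed %||% 1L
  kind <- config$kind %||% "shapes"
  if (kind == "shapes") {
    for (split in c("train", "valid")) {
      set <- make_shapes_dataset(config$n_classes %||% 4L,
                                 config$n_per_class %||% 100L,
                                 config$side %||% 32L,
                                 seed = derive_seed(seed,
                                   match(split, c("train", "valid"))),
                                 split = split)
      write_imageset_h5(set, file.path(run_dir, paste0(split, ".h5")))
      run_log(run_dir, "wrote ", split, ".h5 (", n_images(set), " images)")
    }
  } else if (kind == "stained") {
    ms <- make_stained_culture(config$n_images %||% 10L, seed = seed)
    for (m in ms) {
      png::writePNG(aperm(m$image, c(1L, 2L, 3L)) / 255,
                    file.path(run_dir, paste0(m$source_id, ".png")))
      lab <- m$image
      lab_r <- lab[, , 1]; lab_g <- lab[, , 2]; lab_b <- lab[, , 3]
      lab_r[m$mask] <- 0; lab_g[m$mask] <- 255; lab_b[m$mask] <- 0
      lab[, , 1] <- lab_r; lab[, , 2] <- lab_g; lab[, , 3] <- lab_b
      png::writePNG(lab / 255,
                    file.path(run_dir, paste0(m$source_id, "_labeled.png")))
    }
    run_log(run_dir, "wrote ", length(ms), " image/label pairs")
  } else if (kind == "events") {
    pops <- lapply(config$populations, function(p) do.call(population_spec, p))
    ev <- make_cell_events(pops, config$n_events %||% 500L, seed = seed)
    write_imageset_h5(ev$events, file.path(run_dir, "events.h5"))
    write_feature_table(ev$features, file.path(run_dir, "features.csv"))
    run_log(run_dir, "wrote events.h5 and features.csv")
  } else stop_dc("unknown synth kind '", kind, "'")
}

run_train <- function(config, run_dir, seed) {
  if (is.null(config$train_path) || is.null(config$valid_path))
    stop_dc("train task needs fields 'train_path' and 'valid_path'")
  train_set <- load_any_dataset(config$train_path, "train")
  valid_set <- load_any_dataset(config$valid_path, "valid")
  tc <- training_config_from_fields(config$training)
  if (!is.null(seed)) tc$seed <- as.integer(seed)
  geom <- image_geometry(train_set)
  model <- build_model(config$model %||% "lenet5",
                       config$input_side %||% geom[1], geom[3],
                       length(train_set$class_names), seed = tc$seed)
  run_log(run_dir, "training ", model$spec$name, " for ", tc$epochs,
          " epochs on ", n_images(train_set), " images")
  res <- train_model(model, train_set, valid_set, tc,
                     control_source = config$control_file,
                     run_dir = run_dir)
  write_history_csv(res, file.path(run_dir, "history.csv"))
  write_meta(res, res$model$spec, train_set, valid_set,
             file.path(run_dir, basename(run_dir) %+% "_meta.yaml"))
  run_log(run_dir, sprintf("best val_accuracy %.4f at epoch %d",
                           res$best_val_accuracy, res$best_epoch))
}

`%+%` <- function(a, b) paste0(a, b)

run_evaluate <- function(config, run_dir) {
  if (is.null(config$checkpoint) || is.null(config$data_path))
    stop_dc("evaluate task needs fields 'checkpoint' and 'data_path'")
  model <- load_checkpoint(config$checkpoint)
  data <- load_any_dataset(config$data_path, "test")
  rep <- evaluate_model(model, data)
  write_report(rep, run_dir)
  run_log(run_dir, sprintf("accuracy %.4f on %d images", rep$accuracy,
                           n_images(data)))
}

run_tilepipe <- function(config, run_dir, seed) {
  pairs_from <- function(dirpath) {
    labeled <- sort(list.files(dirpath, pattern = "_labeled\\.(png|tif|tiff)$",
                               full.names = TRUE))
    lapply(labeled, function(lf) {
      of <- sub("_labeled\\.", ".", lf)
      if (!file.exists(of)) stop_dc("missing original for ", lf)
      decode_mask(decode_image_file(lf), decode_image_file(of),
                  tools::file_path_sans_ext(basename(of)))
    })
  }
  if (is.null(config$train_dir) || is.null(config$valid_dir))
    stop_dc("tilepipe task needs fields 'train_dir' and 'valid_dir'")
  tr_masked <- pairs_from(config$train_dir)
  va_masked <- pairs_from(config$valid_dir)
  s <- config$tile_side %||% 32L
  mm <- config$min_marked %||% 5L
  tiles_tr <- build_tile_dataset(tr_masked, s, mm, "balance", "train")
  tiles_va <- build_tile_dataset(va_masked, s, mm, "none", "valid")
  tc <- training_config_from_fields(config$training)
  if (!is.null(seed)) tc$seed <- as.integer(seed)
  model <- build_model(config$model %||% "lenet5", s,
                       image_geometry(tiles_tr)[3], 2L, seed = tc$seed)
  run_log(run_dir, "training tile classifier on ", n_images(tiles_tr),
          " tiles")
  res <- train_model(model, tiles_tr, tiles_va, tc, run_dir = run_dir)
  accs <- vapply(va_masked, function(m) {
    pm <- predict_tile_map(res$model, m$image, m$source_id)
    write_tile_map(pm$map,
                   file.path(run_dir, paste0(m$source_id, "_tilemap.csv")),
                   file.path(run_dir, paste0(m$source_id, "_tiles.csv")),
                   pm$probabilities)
    per_image_accuracy(pm$map, truth_tile_map(m, s, mm))
  }, numeric(1))
  ms <- mean_sd(accs)
  write_history_csv(res, file.path(run_dir, "history.csv"))
  run_log(run_dir, sprintf("per-image accuracy %.3f +/- %.3f over %d images",
                           ms$mean, ms$sd %||% NA, length(accs)))
}

run_export <- function(config, run_dir) {
  if (is.null(config$checkpoint)) stop_dc("export task needs 'checkpoint'")
  export_model(config$checkpoint, config$format %||% "native",
               file.path(run_dir, "model_export.rds"))
  run_log(run_dir, "exported checkpoint (", config$format %||% "native", ")")
}

#' Export a model checkpoint
#'
#' Re-serializes a checkpoint in a supported exchange format. Currently
#' the native serialized format is supported; requesting any other format
#' raises an error listing the supported ones. A native round trip
#' restores bit-identical predictions.
#'
#' @param checkpoint path to a checkpoint from [save_checkpoint()]
#' @param format export format
#' @param out output file path
#' @return `out`, invisibly
#' @export
export_model <- function(checkpoint, format = "native", out) {
  supported <- c("native")
  if (!format %in% supported)
    stop_dc("unsupported export format '", format, "'; supported: ",
            paste(supported, collapse = ", "))
  model <- load_checkpoint(checkpoint)
  save_checkpoint(model, out)
  invisible(out)
}
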