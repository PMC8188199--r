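#' Training configuration
#'
#' @param epochs number of training iterations (each: one pass of the
#'   sampled training data, then a full validation pass)
#' @param batch_size minibatch size
#' @param n_per_class per-epoch balanced sample size per class, or `NULL`
#'   for plain shuffled full-epoch batching
#' @param class_weights length-K positive loss weights, or `NULL` for
#'   uniform
#' @param learning_rate SGD learning rate
#' @param dropout_rate dropout probability on dense hidden layers, in
#'   `[0, 1)`
#' @param momentum SGD momentum coefficient
#' @param seed master seed; all sampling, dropout, and augmentation
#'   randomness derives from it
#' @param augmentation an [augmentation_config()] (identity by default)
#' @param normalization normalization method name (see
#'   [normalization_spec()]); fitted on the training split only
#' @return object of class `training_config`
#' @export
training_config <- function(epochs = 5L, batch_size = 32L, n_per_class = NULL,
                            class_weights = NULL, learning_rate = 0.01,
                            dropout_rate = 0, momentum = 0.9, seed = 1L,
                            augmentation = augmentation_config(),
                            normalization = "div255") {
  if (epochs < 1L) stop_dc("epochs must be >= 1")
  if (!is.null(class_weights) && any(class_weights <= 0))
    stop_dc("class_weights must all be > 0")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop_dc("dropout_rate must be in [0, 1)")
  stopifnot(inherits(augmentation, "augmentation_config"))
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 n_per_class = if (!is.null(n_per_class)) as.integer(n_per_class),
                 class_weights = class_weights,
                 learning_rate = learning_rate, dropout_rate = dropout_rate,
                 momentum = momentum, seed = as.integer(seed),
                 augmentation = augmentation,
                 normalization = match.arg(normalization,
                   c("div255", "dataset_standard", "per_image_standard"))),
            class = "training_config")
}

#' Balanced per-epoch sample of image indices
#'
#' Draws exactly `n_per_class` indices for every class — the imbalance
#' antidote used for, e.g., erythrocyte-dominated blood datasets. Classes
#' with fewer than `n_per_class` members are sampled with replacement; the
#' combined index vector is shuffled.
#'
#' @param labels integer label vector (0-based classes)
#' @param n_per_class sample size per class (0 gives an empty vector)
#' @param n_classes number of classes K; defaults to `max(labels) + 1`
#' @return integer vector of `K * n_per_class` 1-based indices
#' @export
balanced_epoch_sample <- function(labels, n_per_class,
                                  n_classes = max(labels) + 1L) {
  if (n_per_class < 0L) stop_dc("n_per_class must be >= 0")
  if (n_per_class == 0L) return(integer(0))
  out <- integer(0)
  for (k in seq_len(n_classes) - 1L) {
    members <- which(labels == k)
    if (length(members) == 0L)
      stop_dc("class ", k, " has no members; cannot sample")
    take <- if (length(members) >= n_per_class)
      members[sample.int(length(members), n_per_class)]
    else members[sample.int(length(members), n_per_class, replace = TRUE)]
    out <- c(out, take)
  }
  out[sample.int(length(out))]
}

#' Per-class loss weights
#'
#' `uniform` gives every class weight 1; `inverse_frequency` gives class k
#' weight `N / (K * N_k)` so rare classes contribute as much loss as
#' common ones; `manual` passes user coefficients through after a
#' positivity check.
#'
#' @param labels integer label vector (0-based), covering all K classes
#' @param mode `"uniform"`, `"inverse_frequency"`, or `"manual"`
#' @param coefficients length-K positive weights for `mode = "manual"`
#' @param n_classes number of classes
#' @return numeric weight vector of length K
#' @export
make_class_weights <- function(labels, mode = c("uniform", "inverse_frequency",
                                                "manual"),
                               coefficients = NULL,
                               n_classes = max(labels) + 1L) {
  mode <- match.arg(mode)
  k <- n_classes
  if (mode == "uniform") return(rep(1, k))
  if (mode == "manual") {
    if (is.null(coefficients) || length(coefficients) != k)
      stop_dc("manual mode needs ", k, " coefficients")
    if (any(coefficients <= 0)) stop_dc("class weights must be > 0")
    return(as.numeric(coefficients))
  }
  counts <- tabulate(labels + 1L, nbins = k)
  if (any(counts == 0L))
    stop_dc("class ", which(counts == 0L)[1] - 1L, " has no members")
  length(labels) / (k * counts)
}

# hyper-parameters adjustable between epochs via the control source
.live_params <- c("learning_rate", "n_per_class", "class_weights",
                  "dropout_rate",
                  "flip_horizontal", "flip_vertical", "rotation_max",
                  "shift_max", "zoom_delta", "brightness_add_max",
                  "brightness_mult_range", "noise_scale_max")

# read a control source (YAML path or epoch-keyed schedule list) and apply
# any changed values; returns list(config, events)
poll_control <- function(config, control_source, epoch) {
  updates <- NULL
  if (is.character(control_source)) {
    if (file.exists(control_source)) {
      updates <- tryCatch(yaml::yaml.load_file(control_source),
                          error = function(e) {
        warn_dc("unparseable control file at epoch ", epoch, ": ",
                conditionMessage(e), "; keeping previous values")
        NULL
      })
    }
  } else if (is.list(control_source)) {
    updates <- control_source[[as.character(epoch)]]
  }
  events <- list()
  if (is.null(updates)) return(list(config = config, events = events))
  for (key in intersect(names(updates), .live_params)) {
    new <- updates[[key]]
    if (key %in% names(config)) {
      old <- config[[key]]
      if (!isTRUE(all.equal(old, new, check.attributes = FALSE))) {
        config[[key]] <- if (key == "n_per_class") as.integer(new) else new
        events[[length(events) + 1L]] <-
          list(epoch = epoch, parameter = key,
               old = old, new = new)
      }
    } else {
      old <- config$augmentation[[key]]
      if (!isTRUE(all.equal(old, new, check.attributes = FALSE))) {
        config$augmentation[[key]] <- new
        events[[length(events) + 1L]] <-
          list(epoch = epoch, parameter = key, old = old, new = new)
      }
    }
  }
  list(config = config, events = events)
}

hyper_snapshot <- function(config) {
  a <- config$augmentation
  data.frame(learning_rate = config$learning_rate,
             dropout_rate = config$dropout_rate,
             n_per_class = config$n_per_class %||% NA_integer_,
             class_weights = paste(signif(config$class_weights, 6),
                                   collapse = ","),
             flip_horizontal = a$flip_horizontal,
             flip_vertical = a$flip_vertical,
             rotation_max = a$rotation_max, shift_max = a$shift_max,
             zoom_delta = a$zoom_delta,
             brightness_add_max = a$brightness_add_max,
             brightness_mult_lo = a$brightness_mult_range[1],
             brightness_mult_hi = a$brightness_mult_range[2],
             noise_scale_max = a$noise_scale_max,
             stringsAsFactors = FALSE)
}

#' Train a model with per-epoch validation and live hyper-parameter control
#'
#' Every epoch: (1) the control source (a YAML file re-read before each
#' epoch, or an epoch-keyed schedule list) is polled and any changed
#' hyper-parameters take effect immediately and are logged; (2) a balanced
#' per-class sample (or a full shuffle) of the training set is drawn;
#' (3) minibatches are augmented, normalized, and used for one SGD pass;
#' (4) validation accuracy is computed on the complete, un-augmented
#' validation split; the checkpoint with the highest validation accuracy
#' so far is kept as the best model. With a fixed seed and a static
#' control source the run is fully deterministic.
#'
#' @param model a `dl_model` from [build_model()] or [load_checkpoint()]
#' @param train_set,valid_set `image_set` containers sharing geometry and
#'   class set (the validation images are never used for updates)
#' @param config a [training_config()]
#' @param control_source path to a YAML control file, an epoch-keyed list
#'   of updates, or `NULL`
#' @param run_dir directory for checkpoints (created if missing)
#' @param verbose print one line per epoch
#' @return object of class `training_run`: `history` (one row per epoch
#'   with accuracy, validation accuracy, and the full hyper-parameter
#'   snapshot), `best_checkpoint`, `best_epoch`, `best_val_accuracy`,
#'   `change_events`, and the best `model`
#' @export
train_model <- function(model, train_set, valid_set, config,
                        control_source = NULL,
                        run_dir = tempfile("run"), verbose = FALSE) {
  stopifnot(inherits(model, "dl_model"), inherits(config, "training_config"))
  if (!identical(train_set$class_names, valid_set$class_names))
    stop_dc("train and valid sets disagree on classes: [",
            paste(train_set$class_names, collapse = ","), "] vs [",
            paste(valid_set$class_names, collapse = ","), "]")
  geom <- image_geometry(train_set)
  sp <- model$spec
  if (any(image_geometry(valid_set) != geom))
    stop_dc("train and valid sets differ in geometry")
  if (geom[1] < sp$input_side || geom[2] < sp$input_side ||
      geom[3] != sp$channels)
    stop_dc("dataset geometry ", paste(geom, collapse = "x"),
            " incompatible with model input ", sp$input_side, "x",
            sp$input_side, "x", sp$channels)
  k <- length(train_set$class_names)
  if (sp$n_classes != k)
    stop_dc("model has ", sp$n_classes, " outputs but dataset has ", k,
            " classes")
  dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)

  if (is.null(config$class_weights))
    config$class_weights <- rep(1, k)
  set.seed(config$seed)
  normalizer <- fit_normalizer(train_set, config$normalization)
  model$normalization <- normalizer

  history <- NULL
  change_events <- list()
  best_val <- -Inf; best_epoch <- NA_integer_
  best_path <- file.path(run_dir, "best_model.rds")
  labels <- train_set$labels
  n_train <- n_images(train_set)
  global_step <- 0L

  for (epoch in seq_len(config$epochs)) {
    polled <- poll_control(config, control_source, epoch)
    config <- polled$config
    change_events <- c(change_events, polled$events)
    model$dropout_rate <- config$dropout_rate

    idx <- if (!is.null(config$n_per_class))
      balanced_epoch_sample(labels, config$n_per_class, k)
    else sample.int(n_train)
    n_correct <- 0L; n_seen <- 0L
    if (length(idx)) for (start in seq(1L, length(idx), config$batch_size)) {
      bidx <- idx[start:min(start + config$batch_size - 1L, length(idx))]
      xb <- get_images(train_set, bidx)
      xb <- augment_batch(xb, config$augmentation, sp$input_side,
                          batch_index = global_step)
      global_step <- global_step + 1L
      xb <- apply_normalizer(xb, normalizer)
      xb <- aperm(xb, c(2L, 3L, 4L, 1L))
      yb <- labels[bidx]
      fw <- nn_forward(model, xb, train = TRUE,
                       dropout_rate = config$dropout_rate)
      bw <- nn_backward(model, fw, yb, config$class_weights)
      model <- sgd_step(model, bw$grads, config$learning_rate,
                        config$momentum)
      pred <- max.col(t(fw$probs)) - 1L
      n_correct <- n_correct + sum(pred == yb)
      n_seen <- n_seen + length(yb)
    }
    acc <- if (n_seen) n_correct / n_seen else NA_real_

    vp <- predict_proba(model, valid_set, normalizer)
    val_acc <- mean(max.col(vp) - 1L == valid_set$labels)

    if (val_acc > best_val) {
      best_val <- val_acc; best_epoch <- epoch
      save_checkpoint(model, best_path)
    }
    row <- cbind(data.frame(epoch = epoch, accuracy = acc,
                            val_accuracy = val_acc),
                 hyper_snapshot(config),
                 data.frame(timestamp = format(Sys.time(),
                                               "%Y-%m-%dT%H:%M:%S")))
    history <- rbind(history, row)
    if (verbose)
      message(sprintf("epoch %d: acc %.4f val_acc %.4f", epoch, acc, val_acc))
  }

  structure(list(history = history, best_checkpoint = best_path,
                 best_epoch = best_epoch, best_val_accuracy = best_val,
                 change_events = change_events,
                 model = load_checkpoint(best_path),
                 config = config, normalization = normalizer),
            class = "training_run")
}

#' @export
print.training_run <- function(x, ...) {
  cat(sprintf("<training_run> %d epochs, best val_accuracy %.4f (epoch %d), %d hyper-parameter change(s)\n",
              nrow(x$history), x$best_val_accuracy, x$best_epoch,
              length(x$change_events)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# provenance

#' Fingerprint an image container
#'
#' Content hash over pixels, labels, and class names; any modified
#' training image changes the fingerprint.
#' @param x an `image_set`
#' @return character sha1 digest
#' @export
dataset_fingerprint <- function(x) {
  digest::digest(list(round(as.numeric(x$images)), x$labels, x$class_names),
                 algo = "sha1")
}

#' Write the provenance meta-file of a training run
#'
#' Human-readable YAML capturing everything needed to re-execute the run
#' identically: software version, master seed, model architecture and
#' init seed, dataset fingerprints and class names, the full starting
#' configuration, every logged hyper-parameter change event, and the
#' per-epoch history snapshots.
#'
#' @param run a `training_run`
#' @param model_spec the `model_spec` of the trained model
#' @param train_set,valid_set the containers used
#' @param path output file, conventionally `<run>_meta.yaml`
#' @return `path`, invisibly
#' @export
write_meta <- function(run, model_spec, train_set, valid_set, path) {
  cfg <- run$config
  meta <- list(
    software = "deepclass",
    version = as.character(utils::packageVersion("deepclass")),
    seed = cfg$seed,
    model = list(name = model_spec$name, input_side = model_spec$input_side,
                 channels = model_spec$channels,
                 n_classes = model_spec$n_classes,
                 init_seed = model_spec$seed,
                 trainable = as.logical(model_spec$trainable)),
    datasets = list(
      train = list(fingerprint = dataset_fingerprint(train_set),
                   n = n_images(train_set)),
      valid = list(fingerprint = dataset_fingerprint(valid_set),
                   n = n_images(valid_set)),
      class_names = train_set$class_names),
    config = list(epochs = cfg$epochs, batch_size = cfg$batch_size,
                  n_per_class = cfg$n_per_class,
                  class_weights = as.numeric(cfg$class_weights),
                  learning_rate = cfg$learning_rate,
                  dropout_rate = cfg$dropout_rate, momentum = cfg$momentum,
                  normalization = cfg$normalization,
                  augmentation = unclass(cfg$augmentation)),
    change_events = run$change_events,
    best = list(epoch = run$best_epoch,
                val_accuracy = run$best_val_accuracy),
    history = lapply(seq_len(nrow(run$history)), function(i)
      as.list(run$history[i, setdiff(names(run$history), "timestamp")])))
  yaml::write_yaml(meta, path)
  invisible(path)
}

# rebuild the starting config recorded in a meta-file; change events are
# replayed as an epoch-keyed schedule
config_from_meta <- function(meta) {
  cfg <- meta$config
  aug <- cfg$augmentation
  start_aug <- do.call(augmentation_config, aug[setdiff(names(aug), NULL)])
  start <- training_config(epochs = cfg$epochs, batch_size = cfg$batch_size,
                           n_per_class = cfg$n_per_class,
                           class_weights = cfg$class_weights,
                           learning_rate = cfg$learning_rate,
                           dropout_rate = cfg$dropout_rate,
                           momentum = cfg$momentum, seed = meta$seed,
                           augmentation = start_aug,
                           normalization = cfg$normalization)
  # the meta records post-change values; to replay, schedule each event's
  # NEW value at its epoch, and rewind the starting config to the OLD value
  schedule <- list()
  for (ev in rev(meta$change_events)) {
    key <- ev$parameter
    if (key %in% names(start)) start[[key]] <- ev$old
    else start$augmentation[[key]] <- ev$old
  }
  for (ev in meta$change_events) {
    e <- as.character(ev$epoch)
    schedule[[e]] <- c(schedule[[e]], stats::setNames(list(ev$new),
                                                      ev$parameter))
  }
  list(config = start, schedule = schedule)
}

#' Re-execute a training run from its meta-file
#'
#' Verifies the dataset fingerprints, rebuilds the model from the recorded
#' architecture and init seed, replays all logged hyper-parameter changes
#' at their original epochs, and re-runs training. With unmodified data
#' this reproduces the original `TrainingHistory` exactly.
#'
#' @param meta_path meta-file written by [write_meta()]
#' @param train_set,valid_set the original containers
#' @param run_dir checkpoint directory for the re-run
#' @return a `training_run`
#' @export
rerun_from_meta <- function(meta_path, train_set, valid_set,
                            run_dir = tempfile("rerun")) {
  meta <- yaml::yaml.load_file(meta_path)
  if (!identical(meta$datasets$train$fingerprint,
                 dataset_fingerprint(train_set)))
    stop_dc("training-set fingerprint mismatch: data differ from the recorded run")
  if (!identical(meta$datasets$valid$fingerprint,
                 dataset_fingerprint(valid_set)))
    stop_dc("validation-set fingerprint mismatch")
  model <- build_model(meta$model$name, meta$model$input_side,
                       meta$model$channels, meta$model$n_classes,
                       seed = meta$model$init_seed)
  model <- set_trainable(model, unlist(meta$model$trainable))
  cm <- config_from_meta(meta)
  train_model(model, train_set, valid_set, cm$config,
              control_source = cm$schedule, run_dir = run_dir)
}

#' Export a training history as CSV
#'
#' One row per epoch: accuracy, validation accuracy, and one column per
#' hyper-parameter in force that epoch.
#' @param run a `training_run`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_history_csv <- function(run, path) {
  utils::write.csv(run$history, path, row.names = FALSE)
  invisible(path)
}
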