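test_that("balanced sampler returns exactly n per class for random label vectors", {
  set.seed(100)
  for (i in 1:100) {
    k <- sample(2:5, 1)
    labels <- sample(0:(k - 1L), sample(20:60, 1), replace = TRUE)
    # guarantee every class occurs
    labels[seq_len(k)] <- 0:(k - 1L)
    n <- sample(1:8, 1)
    idx <- balanced_epoch_sample(labels, n, k)
    expect_length(idx, k * n)
    expect_true(all(idx >= 1 & idx <= length(labels)))
    counts <- table(factor(labels[idx], levels = 0:(k - 1L)))
    expect_true(all(counts == n))
  }
})

test_that("undersized classes sample with replacement; degenerate inputs handled", {
  labels <- c(0L, 0L, 0L, 1L)       # class 1 has a single member
  set.seed(1)
  idx <- balanced_epoch_sample(labels, 3L)
  expect_length(idx, 6L)
  expect_equal(sum(idx == 4L), 3L)  # the lone member appears thrice
  expect_length(balanced_epoch_sample(labels, 0L), 0L)
  expect_error(balanced_epoch_sample(c(0L, 0L), 2L, n_classes = 2L),
               "class 1")
})

test_that("class weights follow the inverse-frequency formula", {
  expect_equal(make_class_weights(c(0L, 0L, 1L, 1L), "uniform"), c(1, 1))
  expect_equal(make_class_weights(c(0L, 0L, 1L, 1L), "inverse_frequency"),
               c(1, 1))
  labels <- c(rep(0L, 90), rep(1L, 10))
  w <- make_class_weights(labels, "inverse_frequency")
  expect_equal(w, c(100 / (2 * 90), 100 / (2 * 10)))
  expect_equal(round(w, 3), c(0.556, 5.000))
  expect_equal(make_class_weights(labels, "manual", c(2, 3)), c(2, 3))
  expect_error(make_class_weights(labels, "manual", c(1, -1)), "> 0")
})

shapes_run <- function(epochs = 3, seed = 1, control = NULL,
                       run_dir = tempfile("run")) {
  tr <- make_shapes_dataset(2, 16, 16, seed = 31)
  va <- make_shapes_dataset(2, 6, 16, seed = 32, split = "valid")
  m <- build_model("mlp_128", 16, 1, 2, seed = 4)
  cfg <- training_config(epochs = epochs, batch_size = 8,
                         learning_rate = 0.05, seed = seed,
                         augmentation = augmentation_config(
                           rotation_max = 5, seed = seed))
  list(run = train_model(m, tr, va, cfg, control_source = control,
                         run_dir = run_dir),
       train = tr, valid = va, cfg = cfg)
}

test_that("training is deterministic: identical seeds give bit-equal histories", {
  a <- shapes_run(seed = 9)$run
  b <- shapes_run(seed = 9)$run
  expect_identical(a$history$accuracy, b$history$accuracy)
  expect_identical(a$history$val_accuracy, b$history$val_accuracy)
  c_ <- shapes_run(seed = 10)$run
  expect_false(identical(a$history$accuracy, c_$history$accuracy))
})

test_that("best-checkpoint bookkeeping matches the history maximum", {
  r <- shapes_run(epochs = 4)$run
  expect_equal(r$best_val_accuracy, max(r$history$val_accuracy))
  expect_equal(r$history$val_accuracy[r$best_epoch], r$best_val_accuracy)
  expect_true(file.exists(r$best_checkpoint))
})

test_that("control updates take effect at their epoch and are logged", {
  sched <- list(`3` = list(rotation_max = 20))
  r <- shapes_run(epochs = 4, control = sched)$run
  expect_equal(r$history$rotation_max, c(5, 5, 20, 20))
  expect_length(r$change_events, 1L)
  ev <- r$change_events[[1]]
  expect_equal(ev$epoch, 3L)
  expect_equal(ev$parameter, "rotation_max")
  expect_equal(ev$new, 20)
})

test_that("a YAML control file is polled between epochs", {
  ctrl <- tempfile(fileext = ".yaml")
  writeLines("learning_rate: 0.001", ctrl)
  on.exit(unlink(ctrl))
  r <- shapes_run(epochs = 2, control = ctrl)$run
  expect_equal(r$history$learning_rate, c(0.001, 0.001))
  expect_length(r$change_events, 1L)
})

test_that("an unparseable control file warns and keeps previous values", {
  ctrl <- tempfile(fileext = ".yaml")
  writeLines("learning_rate: [unclosed", ctrl)
  on.exit(unlink(ctrl))
  expect_warning(r <- shapes_run(epochs = 1, control = ctrl)$run,
                 "unparseable")
  expect_equal(r$history$learning_rate, 0.05)
})

test_that("the meta-file reproduces the run and counts change events", {
  sched <- list(`2` = list(rotation_max = 10, learning_rate = 0.02))
  s <- shapes_run(epochs = 3, seed = 2, control = sched)
  meta <- tempfile(fileext = ".yaml")
  on.exit(unlink(meta))
  write_meta(s$run, s$run$model$spec, s$train, s$valid, meta)
  redo <- rerun_from_meta(meta, s$train, s$valid)
  expect_equal(redo$history$accuracy, s$run$history$accuracy)
  expect_equal(redo$history$val_accuracy, s$run$history$val_accuracy)
  expect_equal(redo$history$rotation_max, s$run$history$rotation_max)
  # tampered data are rejected
  tampered <- s$train
  tampered$images[1, 1, 1, 1] <- (tampered$images[1, 1, 1, 1] + 1) %% 256
  expect_error(rerun_from_meta(meta, tampered, s$valid), "fingerprint")
})

test_that("dataset fingerprints react to any modified image", {
  a <- tiny_imageset(seed = 5)
  f1 <- dataset_fingerprint(a)
  a$images[3, 2, 2, 1] <- (a$images[3, 2, 2, 1] + 1) %% 256
  expect_false(identical(dataset_fingerprint(a), f1))
})

test_that("class-set and geometry mismatches between splits are rejected", {
  tr <- make_shapes_dataset(2, 8, 16, seed = 1)
  va3 <- make_shapes_dataset(3, 4, 16, seed = 2, split = "valid")
  m <- build_model("mlp_128", 16, 1, 2, seed = 1)
  expect_error(train_model(m, tr, va3, training_config(epochs = 1, seed = 1)),
               "classes")
  va_big <- make_shapes_dataset(2, 4, 20, seed = 2, split = "valid")
  expect_error(train_model(m, tr, va_big,
                           training_config(epochs = 1, seed = 1)),
               "geometry")
})

test_that("history CSV export carries one column per hyper-parameter", {
  r <- shapes_run(epochs = 2)$run
  p <- tempfile(fileext = ".csv")
  on.exit(unlink(p))
  write_history_csv(r, p)
  hist <- read.csv(p)
  expect_equal(nrow(hist), 2L)
  expect_true(all(c("epoch", "accuracy", "val_accuracy", "learning_rate",
                    "rotation_max", "noise_scale_max") %in% names(hist)))
})
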