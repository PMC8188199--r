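test_that("the synth -> train -> evaluate chain runs end to end", {
  base <- tempfile("chain")
  dir.create(base)
  on.exit(unlink(base, recursive = TRUE))

  synth_dir <- run(run_config("synth", kind = "shapes", n_classes = 2L,
                              n_per_class = 12L, side = 16L,
                              out_dir = base), seed = 3)
  expect_true(file.exists(file.path(synth_dir, "train.h5")))
  expect_true(file.exists(file.path(synth_dir, "valid.h5")))

  train_dir <- run(run_config(
    "train", train_path = file.path(synth_dir, "train.h5"),
    valid_path = file.path(synth_dir, "valid.h5"),
    model = "mlp_128",
    training = list(epochs = 2L, batch_size = 8L, learning_rate = 0.05),
    out_dir = base), seed = 3)
  expect_true(file.exists(file.path(train_dir, "best_model.rds")))
  expect_true(file.exists(file.path(train_dir, "history.csv")))
  expect_length(list.files(train_dir, pattern = "_meta\\.yaml$"), 1L)
  expect_true(file.exists(file.path(train_dir, "run.log")))

  eval_dir <- run(run_config(
    "evaluate", checkpoint = file.path(train_dir, "best_model.rds"),
    data_path = file.path(synth_dir, "valid.h5"), out_dir = base))
  expect_true(file.exists(file.path(eval_dir, "evaluation_per_class.csv")))
  expect_true(file.exists(file.path(eval_dir, "evaluation.json")))
})

test_that("identical config and seed give identical history CSVs", {
  base <- tempfile("rerun")
  dir.create(base)
  on.exit(unlink(base, recursive = TRUE))
  synth_dir <- run(run_config("synth", kind = "shapes", n_classes = 2L,
                              n_per_class = 10L, side = 16L,
                              out_dir = base), seed = 5)
  cfg <- run_config("train", train_path = file.path(synth_dir, "train.h5"),
                    valid_path = file.path(synth_dir, "valid.h5"),
                    model = "mlp_128",
                    training = list(epochs = 2L, batch_size = 8L),
                    out_dir = base)
  d1 <- run(cfg, seed = 11)
  d2 <- run(cfg, seed = 11)
  h1 <- readLines(file.path(d1, "history.csv"))
  h2 <- readLines(file.path(d2, "history.csv"))
  # identical apart from wall-clock timestamps
  strip <- function(h) sub("[^,]*$", "", h)
  expect_identical(strip(h1), strip(h2))
})

test_that("invalid configurations fail naming the missing field", {
  expect_error(run(run_config("train", out_dir = tempdir())), "train_path")
  expect_error(run(run_config("evaluate", out_dir = tempdir())), "checkpoint")
  empty_cfg <- tempfile(fileext = ".yaml")
  writeLines("out_dir: /tmp", empty_cfg)
  on.exit(unlink(empty_cfg))
  expect_error(read_run_config(empty_cfg), "task")
})

test_that("export supports the native format and rejects others by name", {
  m <- build_model("mlp_128", 16, 1, 2, seed = 1)
  ck <- tempfile(fileext = ".rds"); out <- tempfile(fileext = ".rds")
  on.exit(unlink(c(ck, out)))
  save_checkpoint(m, ck)
  export_model(ck, "native", out)
  x <- array(runif(3 * 16 * 16, 0, 255), c(3, 16, 16, 1))
  expect_identical(predict_proba(load_checkpoint(out), x),
                   predict_proba(m, x))
  expect_error(export_model(ck, "coreml", out), "supported: native")
  expect_error(export_model(ck, "onnx", out), "unsupported")
})

test_that("the tilepipe task trains from paired PNGs and writes tile maps", {
  base <- tempfile("tp")
  dir.create(file.path(base, "train"), recursive = TRUE)
  dir.create(file.path(base, "valid"), recursive = TRUE)
  on.exit(unlink(base, recursive = TRUE))
  ms <- make_stained_culture(4, side = 64L, blob_count_range = c(2L, 4L),
                             blob_radius_range = c(6, 10), seed = 9)
  write_pair <- function(m, dir) {
    png::writePNG(m$image / 255, file.path(dir, paste0(m$source_id, ".png")))
    lab <- m$image
    for (ch in 1:3) {
      pl <- lab[, , ch]; pl[m$mask] <- c(0, 255, 0)[ch]; lab[, , ch] <- pl
    }
    png::writePNG(lab / 255, file.path(dir, paste0(m$source_id,
                                                   "_labeled.png")))
  }
  for (m in ms[1:3]) write_pair(m, file.path(base, "train"))
  write_pair(ms[[4]], file.path(base, "valid"))
  d <- run(run_config("tilepipe", train_dir = file.path(base, "train"),
                      valid_dir = file.path(base, "valid"),
                      tile_side = 16L, model = "mlp_128",
                      training = list(epochs = 2L, batch_size = 16L,
                                      normalization = "dataset_standard"),
                      out_dir = base), seed = 2)
  expect_true(file.exists(file.path(d, paste0(ms[[4]]$source_id,
                                              "_tilemap.csv"))))
  grid <- as.matrix(read.csv(file.path(d, paste0(ms[[4]]$source_id,
                                                 "_tilemap.csv")),
                             header = FALSE))
  expect_equal(dim(grid), c(4L, 4L))
})

test_that("the command-line entry point completes a synth task", {
  cli <- system.file("cli", "deepclass.R", package = "deepclass")
  expect_true(nzchar(cli))
  base <- tempfile("cli")
  dir.create(base)
  on.exit(unlink(base, recursive = TRUE))
  cfg <- file.path(base, "cfg.yaml")
  yaml::write_yaml(list(task = "synth", kind = "shapes", n_classes = 2L,
                        n_per_class = 4L, side = 16L, out_dir = base), cfg)
  res <- system2("Rscript", c(cli, "--config", cfg, "--seed", "1"),
                 stdout = TRUE, stderr = TRUE,
                 env = paste0("R_LIBS=", paste(.libPaths(), collapse = ":")))
  status <- attr(res, "status") %||% 0L
  expect_equal(status, 0L)
  expect_length(list.files(base, pattern = "^synth_"), 1L)
})
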