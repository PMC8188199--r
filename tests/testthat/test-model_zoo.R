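test_that("architectures have the documented conv/dense structure", {
  m <- build_model("lenet5", 32, 1, 10, seed = 1)
  expect_equal(m$spec$layer_names,
               c("conv1", "conv2", "dense1", "dense2", "output"))
  expect_equal(m$spec$n_classes, 10L)
  # classic LeNet-5 parameter count at 32x32x1, 10 classes
  expected <- (5 * 5 * 1 * 6 + 6) + (5 * 5 * 6 * 16 + 16) +
    (400 * 120 + 120) + (120 * 84 + 84) + (84 * 10 + 10)
  expect_equal(count_parameters(m), expected)

  n <- build_model("nitta_6layer", 32, 1, 10, seed = 1)
  expect_equal(length(n$spec$layer_names), 6L)   # 4 conv + 2 dense
  expect_equal(sum(grepl("^conv", n$spec$layer_names)), 4L)

  r <- build_model("resnet_6conv", 32, 3, 2, seed = 1)
  expect_equal(length(r$spec$layer_names), 10L)  # 6 conv + 4 dense
})

test_that("parameter count is reproducible across constructions", {
  a <- build_model("nitta_6layer", 32, 3, 5, seed = 1)
  b <- build_model("nitta_6layer", 32, 3, 5, seed = 99)
  expect_equal(count_parameters(a), count_parameters(b))
  # independent closed-form count: same-padded 3x3 convs + dense head
  expected <- (3 * 3 * 3 * 32 + 32) + (3 * 3 * 32 * 32 + 32) +
    (3 * 3 * 32 * 64 + 64) + (3 * 3 * 64 * 64 + 64) +
    (8 * 8 * 64 * 256 + 256) + (256 * 5 + 5)
  expect_equal(count_parameters(a), expected)
})

test_that("softmax outputs are normalized for every registered architecture", {
  set.seed(5)
  for (name in list_architectures()) {
    side <- if (name == "lenet5") 32L else 16L
    m <- build_model(name, side, 1, 3, seed = 2)
    x <- array(runif(2 * side * side, 0, 255), c(2, side, side, 1))
    p <- predict_proba(m, x)
    expect_equal(rowSums(p), c(1, 1), tolerance = 1e-5, info = name)
    expect_true(all(p >= 0), info = name)
  }
})

test_that("changing channels 1 <-> 3 alters only the first layer's parameters", {
  per_layer <- function(channels) {
    m <- build_model("lenet5", 32, channels, 4, seed = 1)
    vapply(deepclass:::parameterized_layers(m), function(p) {
      l <- deepclass:::get_player(m, p$path)
      length(l$W) + length(l$b)
    }, numeric(1))
  }
  c1 <- per_layer(1); c3 <- per_layer(3)
  expect_false(c1[1] == c3[1])
  expect_equal(c1[-1], c3[-1])
})

test_that("the registry accepts plug-in architectures", {
  register_architecture("tiny_mlp_plugin", function(input_side, channels, n_classes) {
    list(deepclass:::layer_flatten(),
         deepclass:::layer_dense(8L, "hidden"), deepclass:::layer_relu(),
         deepclass:::layer_dense(n_classes, "output"))
  })
  m <- build_model("tiny_mlp_plugin", 8, 1, 2, seed = 1)
  expect_equal(m$spec$layer_names, c("hidden", "output"))
  expect_error(build_model("nope", 8, 1, 2), "registered")
})

test_that("incompatible input sides are rejected with a helpful error", {
  expect_error(build_model("lenet5", 12, 1, 2), "too small")
  expect_error(build_model("nitta_6layer", 15, 1, 2), "even feature maps")
})

test_that("freezing prevents weight updates; partial freezing localizes them", {
  set.seed(11)
  train <- make_shapes_dataset(2, 10, 16, seed = 1)
  valid <- make_shapes_dataset(2, 4, 16, seed = 2, split = "valid")
  weights_of <- function(m) lapply(deepclass:::parameterized_layers(m),
    function(p) deepclass:::get_player(m, p$path)$W)

  m <- build_model("mlp_128", 16, 1, 2, seed = 3)
  frozen <- set_trainable(m, c(FALSE, FALSE))
  cfg <- training_config(epochs = 1, batch_size = 8, seed = 1)
  res <- train_model(frozen, train, valid, cfg)
  expect_identical(weights_of(res$model), weights_of(frozen))
  # fully frozen model: validation accuracy cannot move
  res2 <- train_model(frozen, train, valid,
                      training_config(epochs = 3, batch_size = 8, seed = 1))
  expect_equal(length(unique(res2$history$val_accuracy)), 1L)

  part <- set_trainable(m, c(FALSE, TRUE))
  res3 <- train_model(part, train, valid, cfg)
  w_before <- weights_of(part); w_after <- weights_of(res3$model)
  expect_identical(w_after[[1]], w_before[[1]])      # frozen hidden layer
  expect_false(identical(w_after[[2]], w_before[[2]]))

  expect_error(set_trainable(m, c(TRUE)), "mask length")
})

test_that("plateau detection proposes the deepest frozen layer only on a plateau", {
  m <- build_model("lenet5", 32, 1, 4, seed = 1)
  m <- set_trainable(m, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  flat <- data.frame(val_accuracy = rep(0.80, 8))
  expect_equal(plateau_unfreeze(m, flat, patience = 5, epsilon = 0.005), 4L)
  rising <- data.frame(val_accuracy = seq(0.5, 0.92, length.out = 8))
  expect_null(plateau_unfreeze(m, rising, patience = 5, epsilon = 0.005))
  all_on <- set_trainable(m, rep(TRUE, 5))
  expect_null(plateau_unfreeze(all_on, flat, patience = 5))
  # too-short history: no decision yet
  expect_null(plateau_unfreeze(m, flat[1:3, , drop = FALSE], patience = 5))
})

test_that("checkpoints round-trip predictions bit-exactly", {
  m <- build_model("mlp_128_64", 16, 1, 3, seed = 8)
  x <- array(runif(4 * 16 * 16, 0, 255), c(4, 16, 16, 1))
  p <- tempfile(fileext = ".rds")
  on.exit(unlink(p))
  save_checkpoint(m, p)
  back <- load_checkpoint(p)
  expect_identical(predict_proba(back, x), predict_proba(m, x))
  # geometry mismatch names both shapes
  bad <- array(0, c(2, 16, 16, 3))
  expect_error(predict_proba(back, bad), "16x16x3.*16x16x1")
})

test_that("transfer learning leaves early layers bit-identical", {
  task_a_tr <- make_shapes_dataset(2, 12, 16, seed = 5)
  task_a_va <- make_shapes_dataset(2, 4, 16, seed = 6, split = "valid")
  base <- build_model("mlp_128_64", 16, 1, 2, seed = 2)
  pre <- train_model(base, task_a_tr, task_a_va,
                     training_config(epochs = 1, batch_size = 8, seed = 1))
  # re-purpose on task B (different shape families), last layer only
  task_b_tr <- make_shapes_dataset(2, 12, 16, seed = 7)
  task_b_va <- make_shapes_dataset(2, 4, 16, seed = 8, split = "valid")
  tuned <- set_trainable(pre$model, c(FALSE, FALSE, TRUE))
  res <- train_model(tuned, task_b_tr, task_b_va,
                     training_config(epochs = 2, batch_size = 8, seed = 2))
  for (i in 1:2) {
    lw <- deepclass:::get_player(res$model,
      deepclass:::parameterized_layers(res$model)[[i]]$path)
    lw0 <- deepclass:::get_player(tuned,
      deepclass:::parameterized_layers(tuned)[[i]]$path)
    expect_identical(lw$W, lw0$W)
    expect_identical(lw$b, lw0$b)
  }
})
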