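# Architecture registry and model-level operations.

.architectures <- new.env(parent = emptyenv())

#' Register a network architecture
#'
#' The registry is the extension point for custom networks: a constructor
#' receives `(input_side, channels, n_classes)` and returns a list of
#' engine layers (see the built-in constructors for the pattern). Once
#' registered, the architecture is buildable by name via [build_model()].
#'
#' @param name architecture identifier
#' @param constructor `function(input_side, channels, n_classes)` returning
#'   a list of layers
#' @export
register_architecture <- function(name, constructor) {
  stopifnot(is.character(name), is.function(constructor))
  assign(name, constructor, envir = .architectures)
  invisible(name)
}

#' List registered architectures
#' @return character vector of names
#' @export
list_architectures <- function() sort(ls(.architectures))

# ---------------------------------------------------------------------------
# built-in architectures

arch_lenet5 <- function(input_side, channels, n_classes) {
  list(layer_conv(6L, 5L, "valid", "conv1"), layer_relu(), layer_pool(),
       layer_conv(16L, 5L, "valid", "conv2"), layer_relu(), layer_pool(),
       layer_flatten(),
       layer_dense(120L, "dense1"), layer_relu(), layer_dropout(),
       layer_dense(84L, "dense2"), layer_relu(), layer_dropout(),
       layer_dense(n_classes, "output"))
}

arch_nitta_6layer <- function(input_side, channels, n_classes) {
  list(layer_conv(32L, 3L, "same", "conv1"), layer_relu(),
       layer_conv(32L, 3L, "same", "conv2"), layer_relu(), layer_pool(),
       layer_conv(64L, 3L, "same", "conv3"), layer_relu(),
       layer_conv(64L, 3L, "same", "conv4"), layer_relu(), layer_pool(),
       layer_flatten(),
       layer_dense(256L, "dense1"), layer_relu(), layer_dropout(),
       layer_dense(n_classes, "output"))
}

arch_resnet_6conv <- function(input_side, channels, n_classes) {
  list(layer_conv(32L, 3L, "same", "conv1"), layer_relu(),
       layer_resblock(32L, 3L, "res1"), layer_pool(),
       layer_conv(128L, 3L, "same", "conv4"), layer_relu(),
       layer_resblock(128L, 3L, "res2"), layer_pool(),
       layer_flatten(),
       layer_dense(256L, "dense1"), layer_relu(), layer_dropout(),
       layer_dense(128L, "dense2"), layer_relu(), layer_dropout(),
       layer_dense(64L, "dense3"), layer_relu(),
       layer_dense(n_classes, "output"))
}

arch_mlp_128 <- function(input_side, channels, n_classes) {
  list(layer_flatten(),
       layer_dense(128L, "dense1"), layer_relu(), layer_dropout(),
       layer_dense(n_classes, "output"))
}

arch_mlp_128_64 <- function(input_side, channels, n_classes) {
  list(layer_flatten(),
       layer_dense(128L, "dense1"), layer_relu(), layer_dropout(),
       layer_dense(64L, "dense2"), layer_relu(), layer_dropout(),
       layer_dense(n_classes, "output"))
}

register_builtin_architectures <- function() {
  register_architecture("lenet5", arch_lenet5)
  register_architecture("nitta_6layer", arch_nitta_6layer)
  register_architecture("resnet_6conv", arch_resnet_6conv)
  register_architecture("mlp_128", arch_mlp_128)
  register_architecture("mlp_128_64", arch_mlp_128_64)
}

# ---------------------------------------------------------------------------
# weight initialization: He-normal for hidden layers, Glorot for output

init_weights <- function(model, seed) {
  # dry geometry pass to learn each parameterized layer's fan-in
  side <- model$spec$input_side; cin <- model$spec$channels
  with_local_seed(seed, {
    h <- side; w <- side; cc <- cin; feat <- NULL
    init_conv <- function(layer, cin) {
      fan_in <- layer$kernel^2 * cin
      sdv <- sqrt(2 / fan_in)
      layer$W <- matrix(stats::rnorm(fan_in * layer$filters, 0, sdv),
                        fan_in, layer$filters)
      layer$b <- numeric(layer$filters)
      layer
    }
    init_dense <- function(layer, fan_in, output = FALSE) {
      sdv <- if (output) sqrt(2 / (fan_in + layer$units)) else sqrt(2 / fan_in)
      layer$W <- matrix(stats::rnorm(layer$units * fan_in, 0, sdv),
                        layer$units, fan_in)
      layer$b <- numeric(layer$units)
      layer
    }
    n_layers <- length(model$layers)
    for (li in seq_len(n_layers)) {
      layer <- model$layers[[li]]
      if (layer$type == "conv") {
        layer <- init_conv(layer, cc)
        if (layer$pad == "valid") { h <- h - layer$kernel + 1L
                                    w <- w - layer$kernel + 1L }
        if (h < 1L || w < 1L)
          stop_dc("input side ", side, " too small for '", model$spec$name, "'")
        cc <- layer$filters
        model$layers[[li]] <- layer
      } else if (layer$type == "resblock") {
        layer$conv1 <- init_conv(layer$conv1, cc)
        layer$conv2 <- init_conv(layer$conv2, layer$conv1$filters)
        cc <- layer$conv2$filters
        model$layers[[li]] <- layer
      } else if (layer$type == "pool") {
        if (h %% 2L != 0L || w %% 2L != 0L)
          stop_dc("input side ", side, " incompatible with pooling depth of '",
                  model$spec$name, "' (needs even feature maps; try side ",
                  2L^sum(vapply(model$layers, function(l) l$type == "pool",
                                logical(1))) *
                    ceiling(side / 2L^sum(vapply(model$layers,
                            function(l) l$type == "pool", logical(1)))), ")")
        h <- h %/% 2L; w <- w %/% 2L
      } else if (layer$type == "flatten") {
        feat <- h * w * cc
      } else if (layer$type == "dense") {
        layer <- init_dense(layer, feat, output = li == n_layers)
        feat <- layer$units
        model$layers[[li]] <- layer
      }
    }
  })
  model
}

#' Build a neural network for a given input geometry and class count
#'
#' Builds one of the registered architectures with the input layer sized
#' to `input_side`/`channels` and a softmax output of width `n_classes`.
#' All parameterized layers start trainable. Built-ins:
#' \describe{
#'   \item{lenet5}{2 convolutional (5x5, 6/16 filters, valid) + 3 dense
#'     layers (120/84/K)}
#'   \item{nitta_6layer}{4 convolutional (3x3 same, 32/32/64/64) + 2 dense
#'     layers (256/K)}
#'   \item{resnet_6conv}{6 convolutional layers (32 to 128 filters) with
#'     identity residual connections around each conv pair + 4 dense layers
#'     (256/128/64/K)}
#'   \item{mlp_128, mlp_128_64}{plain multilayer perceptrons}
#' }
#'
#' @param name registered architecture name
#' @param input_side input image side in pixels
#' @param channels 1 (grayscale) or 3 (RGB)
#' @param n_classes number of output classes (>= 2)
#' @param seed integer used for the deterministic He/Glorot weight draw
#' @return object of class `dl_model`; its `$spec` (class `model_spec`)
#'   records the architecture name, geometry, parameterized layer names,
#'   and per-layer trainable flags
#' @export
build_model <- function(name, input_side, channels, n_classes, seed = 1L) {
  if (!exists(name, envir = .architectures))
    stop_dc("unknown architecture '", name, "'; registered: ",
            paste(list_architectures(), collapse = ", "))
  if (!channels %in% c(1L, 3L)) stop_dc("channels must be 1 or 3")
  if (n_classes < 2L) stop_dc("n_classes must be >= 2")
  ctor <- get(name, envir = .architectures)
  layers <- ctor(as.integer(input_side), as.integer(channels),
                 as.integer(n_classes))
  model <- structure(
    list(layers = layers,
         spec = NULL, opt_state = list(), normalization = NULL,
         dropout_rate = 0),
    class = "dl_model")
  model$spec <- structure(
    list(name = name, input_side = as.integer(input_side),
         channels = as.integer(channels), n_classes = as.integer(n_classes),
         layer_names = character(), trainable = logical(), seed = as.integer(seed)),
    class = "model_spec")
  model <- init_weights(model, seed)
  pls <- parameterized_layers(model)
  model$spec$layer_names <- vapply(pls, function(p) p$name %||% p$key,
                                   character(1))
  model$spec$trainable <- rep(TRUE, length(pls))
  model
}

#' @export
print.dl_model <- function(x, ...) {
  cat(sprintf("<dl_model> %s: %dx%dx%d -> %d classes, %d parameterized layers, %s parameters\n",
              x$spec$name, x$spec$input_side, x$spec$input_side,
              x$spec$channels, x$spec$n_classes, length(x$spec$layer_names),
              format(count_parameters(x), big.mark = ",")))
  frozen <- x$spec$layer_names[!x$spec$trainable]
  if (length(frozen)) cat("frozen:", paste(frozen, collapse = ", "), "\n")
  invisible(x)
}

#' Total trainable-parameter count of a model
#' @param model a `dl_model`
#' @return integer number of weights and biases
#' @export
count_parameters <- function(model) {
  pls <- parameterized_layers(model)
  sum(vapply(pls, function(p) {
    l <- get_player(model, p$path)
    length(l$W) + length(l$b)
  }, numeric(1)))
}

#' Freeze or unfreeze layers
#'
#' Frozen layers receive no weight updates during subsequent training —
#' the transfer-learning primitive ("all layers but the last one were
#' frozen").
#'
#' @param model a `dl_model`
#' @param mask logical vector, one entry per parameterized layer (order as
#'   `model$spec$layer_names`); `TRUE` = trainable
#' @return the model with updated trainable flags
#' @export
set_trainable <- function(model, mask) {
  pls <- parameterized_layers(model)
  if (length(mask) != length(pls))
    stop_dc("mask length ", length(mask), " != parameterized layer count ",
            length(pls))
  mask <- as.logical(mask)
  for (i in seq_along(pls)) {
    layer <- get_player(model, pls[[i]]$path)
    layer$trainable <- mask[i]
    model <- set_player(model, pls[[i]]$path, layer)
  }
  model$spec$trainable <- mask
  model
}

#' Decide whether a validation-accuracy plateau warrants unfreezing
#'
#' Gradual unfreezing rule for transfer learning: when the best validation
#' accuracy of the last `patience` epochs improves on the best of all
#' earlier epochs by less than `epsilon`, the deepest (closest to the
#' output) still-frozen layer is proposed for unfreezing.
#'
#' @param model a `dl_model` (its trainable flags identify frozen layers)
#' @param history `TrainingHistory` data frame with a `val_accuracy` column
#' @param patience plateau window in epochs
#' @param epsilon minimum accuracy improvement counted as progress
#' @return the parameterized-layer index to unfreeze, or `NULL`
#' @export
plateau_unfreeze <- function(model, history, patience = 5L, epsilon = 0.005) {
  frozen <- which(!model$spec$trainable)
  if (length(frozen) == 0L) return(NULL)
  va <- history$val_accuracy
  if (length(va) < patience + 1L) return(NULL)
  recent <- max(va[(length(va) - patience + 1L):length(va)])
  before <- max(va[seq_len(length(va) - patience)])
  if (recent - before < epsilon) max(frozen) else NULL
}

# ---------------------------------------------------------------------------
# prediction and checkpoints

#' Class probabilities for a batch or image set
#'
#' @param model a `dl_model`
#' @param x an `image_set`/`image_set_disk` or a raw `N x H x W x C` array
#'   of 0--255 intensities
#' @param normalizer a `normalization_spec`; defaults to the spec stored in
#'   the model by [train_model()], else `div255`
#' @param batch_size inference batch size
#' @return `N x K` matrix of class probabilities (rows sum to 1)
#' @export
predict_proba <- function(model, x, normalizer = NULL, batch_size = 256L) {
  if (inherits(x, c("image_set", "image_set_disk"))) {
    n <- n_images(x)
    geom <- image_geometry(x)
    fetch <- function(idx) get_images(x, idx)
  } else {
    if (length(dim(x)) == 3L) dim(x) <- c(1L, dim(x))
    n <- dim(x)[1]; geom <- dim(x)[2:4]
    fetch <- function(idx) x[idx, , , , drop = FALSE]
  }
  sp <- model$spec
  if (geom[1] != sp$input_side || geom[2] != sp$input_side ||
      geom[3] != sp$channels)
    stop_dc("data geometry ", geom[1], "x", geom[2], "x", geom[3],
            " does not match model input ", sp$input_side, "x",
            sp$input_side, "x", sp$channels)
  normalizer <- normalizer %||% model$normalization %||%
    normalization_spec("div255")
  out <- matrix(0, n, sp$n_classes)
  for (start in seq(1L, n, batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    xb <- apply_normalizer(fetch(idx), normalizer)
    xb <- aperm(xb, c(2L, 3L, 4L, 1L))      # engine layout (H,W,C,N)
    fw <- nn_forward(model, xb, train = FALSE)
    out[idx, ] <- t(fw$probs)
  }
  colnames(out) <- NULL
  out
}

#' Save a model checkpoint
#'
#' Native serialized checkpoint containing weights, architecture spec,
#' optimizer state, and the normalization spec, so training can resume
#' identically and predictions round-trip bit-exactly.
#'
#' @param model a `dl_model`
#' @param path output file (conventionally `.rds`)
#' @return `path`, invisibly
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' Load a model checkpoint
#' @param path file written by [save_checkpoint()]
#' @return a `dl_model`
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "dl_model"))
    stop_dc(path, " is not a deepclass checkpoint")
  model
}
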