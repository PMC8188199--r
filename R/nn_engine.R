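# Vectorized neural-network engine.
#
# Activations travel as arrays (H, W, C, N) through convolutional stages and
# as matrices (features x N) through dense stages.  Convolution is stride-1
# im2col: the kernel is a ((kh*kw*Cin) x F) matrix whose column order matches
# R's column-major flattening of a (kh, kw, Cin, F) array, so the im2col
# columns are assembled a-fastest, then b, then channel.

# ---------------------------------------------------------------------------
# layer constructors (weights filled in by init_weights)

layer_conv <- function(filters, kernel = 3L, pad = c("same", "valid"),
                       name = NULL) {
  pad <- match.arg(pad)
  list(type = "conv", filters = as.integer(filters), kernel = as.integer(kernel),
       pad = pad, name = name, W = NULL, b = NULL, trainable = TRUE)
}
layer_dense <- function(units, name = NULL) {
  list(type = "dense", units = as.integer(units), name = name,
       W = NULL, b = NULL, trainable = TRUE)
}
layer_pool <- function() list(type = "pool")
layer_relu <- function() list(type = "relu")
layer_flatten <- function() list(type = "flatten")
layer_dropout <- function() list(type = "dropout")   # rate set at train time
layer_resblock <- function(filters, kernel = 3L, name = NULL) {
  # two same-padded convs with an identity skip when channel counts allow
  list(type = "resblock",
       conv1 = layer_conv(filters, kernel, "same", paste0(name, "_a")),
       conv2 = layer_conv(filters, kernel, "same", paste0(name, "_b")),
       name = name)
}

# ---------------------------------------------------------------------------
# im2col convolution

pad_same <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2L * p, d[2] + 2L * p, d[3], d[4]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- x
  out
}

im2col <- function(xp, kh, kw, ho, wo) {
  d <- dim(xp)   # padded (Hp, Wp, C, N)
  n <- d[4]; cin <- d[3]
  Xc <- matrix(0, ho * wo * n, kh * kw * cin)
  j <- 0L
  for (cc in seq_len(cin)) for (b in seq_len(kw)) for (a in seq_len(kh)) {
    j <- j + 1L
    Xc[, j] <- xp[a:(a + ho - 1L), b:(b + wo - 1L), cc, , drop = FALSE]
  }
  Xc
}

conv_forward <- function(layer, x) {
  d <- dim(x)
  k <- layer$kernel
  p <- if (layer$pad == "same") (k - 1L) %/% 2L else 0L
  ho <- d[1] + 2L * p - k + 1L
  wo <- d[2] + 2L * p - k + 1L
  if (ho < 1L || wo < 1L)
    stop_dc("feature map vanished in conv layer '", layer$name,
            "'; input side too small")
  xp <- pad_same(x, p)
  Xc <- im2col(xp, k, k, ho, wo)
  Ymat <- Xc %*% layer$W                      # (ho*wo*N) x F
  Ymat <- sweep(Ymat, 2L, layer$b, "+")
  f <- layer$filters; n <- d[4]
  y <- aperm(array(Ymat, c(ho, wo, n, f)), c(1L, 2L, 4L, 3L))
  list(out = y, cache = list(Xc = Xc, xdim = d, p = p, ho = ho, wo = wo))
}

conv_backward <- function(layer, dy, cache) {
  d <- cache$xdim; k <- layer$kernel; p <- cache$p
  ho <- cache$ho; wo <- cache$wo; n <- d[4]; cin <- d[3]
  dYmat <- array(aperm(dy, c(1L, 2L, 4L, 3L)), c(ho * wo * n, layer$filters))
  dW <- crossprod(cache$Xc, dYmat)
  db <- colSums(dYmat)
  dXc <- tcrossprod(dYmat, layer$W)           # (ho*wo*N) x (k*k*cin)
  dxp <- array(0, c(d[1] + 2L * p, d[2] + 2L * p, cin, n))
  j <- 0L
  for (cc in seq_len(cin)) for (b in seq_len(k)) for (a in seq_len(k)) {
    j <- j + 1L
    dxp[a:(a + ho - 1L), b:(b + wo - 1L), cc, ] <-
      dxp[a:(a + ho - 1L), b:(b + wo - 1L), cc, , drop = FALSE] +
      array(dXc[, j], c(ho, wo, 1L, n))
  }
  dx <- if (p > 0L) dxp[p + seq_len(d[1]), p + seq_len(d[2]), , , drop = FALSE]
        else dxp
  list(dx = dx, dW = dW, db = db)
}

# ---------------------------------------------------------------------------
# 2x2 max pooling, stride 2 (ties resolve to the first window position)

pool_forward <- function(x) {
  d <- dim(x)
  if (d[1] %% 2L != 0L || d[2] %% 2L != 0L)
    stop_dc("pooling needs even feature-map sides, got ", d[1], "x", d[2])
  s1 <- seq(1L, d[1], 2L); s2 <- seq(1L, d[2], 2L)
  a11 <- x[s1, s2, , , drop = FALSE];      a21 <- x[s1 + 1L, s2, , , drop = FALSE]
  a12 <- x[s1, s2 + 1L, , , drop = FALSE]; a22 <- x[s1 + 1L, s2 + 1L, , , drop = FALSE]
  m <- pmax(a11, a21, a12, a22)
  m1 <- a11 == m
  m2 <- (a21 == m) & !m1
  m3 <- (a12 == m) & !(m1 | m2)
  m4 <- !(m1 | m2 | m3)
  list(out = m, cache = list(masks = list(m1, m2, m3, m4), xdim = d))
}

pool_backward <- function(dy, cache) {
  d <- cache$xdim
  s1 <- seq(1L, d[1], 2L); s2 <- seq(1L, d[2], 2L)
  dx <- array(0, d)
  ms <- cache$masks
  dx[s1, s2, , ]           <- dy * ms[[1]]
  dx[s1 + 1L, s2, , ]      <- dy * ms[[2]]
  dx[s1, s2 + 1L, , ]      <- dy * ms[[3]]
  dx[s1 + 1L, s2 + 1L, , ] <- dy * ms[[4]]
  dx
}

# ---------------------------------------------------------------------------
# forward / backward over the layer sequence

nn_forward <- function(model, x, train = FALSE, dropout_rate = 0) {
  caches <- vector("list", length(model$layers))
  for (li in seq_along(model$layers)) {
    layer <- model$layers[[li]]
    res <- switch(layer$type,
      conv = conv_forward(layer, x),
      pool = pool_forward(x),
      relu = list(out = pmax(x, 0), cache = x > 0),
      flatten = {
        d <- dim(x)
        list(out = matrix(x, ncol = d[4]), cache = d)
      },
      dense = {
        y <- layer$W %*% x + matrix(layer$b, nrow = length(layer$b),
                                    ncol = ncol(x))
        list(out = y, cache = x)
      },
      dropout = {
        if (train && dropout_rate > 0) {
          keep <- matrix(stats::runif(length(x)) >= dropout_rate,
                         nrow(x), ncol(x)) / (1 - dropout_rate)
          list(out = x * keep, cache = keep)
        } else list(out = x, cache = NULL)
      },
      resblock = {
        r1 <- conv_forward(layer$conv1, x)
        h <- pmax(r1$out, 0)
        r2 <- conv_forward(layer$conv2, h)
        y <- r2$out
        skip <- dim(x)[3] == dim(y)[3]
        if (skip) y <- y + x
        list(out = pmax(y, 0),
             cache = list(c1 = r1$cache, c2 = r2$cache,
                          relu1 = r1$out > 0, relu2 = y > 0, skip = skip))
      },
      stop_dc("unknown layer type ", layer$type))
    caches[[li]] <- res$cache
    x <- res$out
  }
  # softmax over the final K x N logits
  z <- sweep(x, 2L, apply(x, 2L, max), "-")
  e <- exp(z)
  probs <- sweep(e, 2L, colSums(e), "/")
  list(probs = probs, logits = x, caches = caches)
}

# backward pass from softmax cross-entropy; labels 0-based, weights length K.
# Returns per-parameterized-layer gradients (same flat order as
# parameterized_layers()) and the mean weighted loss.
nn_backward <- function(model, fw, labels, class_weights) {
  probs <- fw$probs
  n <- ncol(probs); k <- nrow(probs)
  idx <- cbind(labels + 1L, seq_len(n))
  w <- class_weights[labels + 1L]
  loss <- -sum(w * log(pmax(probs[idx], 1e-12))) / n
  dz <- probs
  dz[idx] <- dz[idx] - 1
  dz <- sweep(dz, 2L, w / n, "*")
  grads <- list()
  dy <- dz
  for (li in rev(seq_along(model$layers))) {
    layer <- model$layers[[li]]
    cache <- fw$caches[[li]]
    if (layer$type == "dense") {
      grads[[paste0("L", li)]] <- list(dW = tcrossprod(dy, cache),
                                       db = rowSums(dy))
      dy <- crossprod(layer$W, dy)
    } else if (layer$type == "conv") {
      g <- conv_backward(layer, dy, cache)
      grads[[paste0("L", li)]] <- list(dW = g$dW, db = g$db)
      dy <- g$dx
    } else if (layer$type == "resblock") {
      dy <- dy * cache$relu2
      dskip <- if (cache$skip) dy else 0
      g2 <- conv_backward(layer$conv2, dy, cache$c2)
      dh <- g2$dx * cache$relu1
      g1 <- conv_backward(layer$conv1, dh, cache$c1)
      grads[[paste0("L", li, "b")]] <- list(dW = g2$dW, db = g2$db)
      grads[[paste0("L", li, "a")]] <- list(dW = g1$dW, db = g1$db)
      dy <- g1$dx
      if (cache$skip) dy <- dy + dskip
    } else if (layer$type == "relu") {
      dy <- dy * cache
    } else if (layer$type == "pool") {
      dy <- pool_backward(dy, cache)
    } else if (layer$type == "flatten") {
      dy <- array(dy, cache)
    } else if (layer$type == "dropout") {
      if (!is.null(cache)) dy <- dy * cache
    }
  }
  list(loss = loss, grads = grads)
}

# addresses of parameterized layers in construction order:
# list of list(path) where path is either li or c(li, "conv1"/"conv2")
parameterized_layers <- function(model) {
  out <- list()
  for (li in seq_along(model$layers)) {
    layer <- model$layers[[li]]
    if (layer$type %in% c("conv", "dense")) {
      out[[length(out) + 1L]] <- list(path = li, key = paste0("L", li),
                                      name = layer$name)
    } else if (layer$type == "resblock") {
      out[[length(out) + 1L]] <- list(path = c(li, 1L), key = paste0("L", li, "a"),
                                      name = layer$conv1$name)
      out[[length(out) + 1L]] <- list(path = c(li, 2L), key = paste0("L", li, "b"),
                                      name = layer$conv2$name)
    }
  }
  out
}

get_player <- function(model, path) {
  if (length(path) == 1L) model$layers[[path]]
  else model$layers[[path[1]]][[c("conv1", "conv2")[path[2]]]]
}

set_player <- function(model, path, layer) {
  if (length(path) == 1L) model$layers[[path]] <- layer
  else model$layers[[path[1]]][[c("conv1", "conv2")[path[2]]]] <- layer
  model
}

# one SGD-with-momentum step; frozen layers are untouched
sgd_step <- function(model, grads, lr, momentum = 0.9) {
  pls <- parameterized_layers(model)
  for (i in seq_along(pls)) {
    pl <- pls[[i]]
    layer <- get_player(model, pl$path)
    if (!isTRUE(layer$trainable)) next
    g <- grads[[pl$key]]
    if (is.null(g)) next
    st <- model$opt_state[[pl$key]] %||%
      list(vW = array(0, dim(layer$W)), vb = numeric(length(layer$b)))
    st$vW <- momentum * st$vW - lr * g$dW
    st$vb <- momentum * st$vb - lr * g$db
    layer$W <- layer$W + st$vW
    layer$b <- layer$b + st$vb
    model <- set_player(model, pl$path, layer)
    model$opt_state[[pl$key]] <- st
  }
  model
}
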