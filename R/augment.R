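#' Stochastic augmentation configuration
#'
#' Parameters of one training run's augmentation stream. Geometric
#' operators resample with nearest neighbor and fill vacated pixels with
#' 0; brightness operators act on raw 0--255 intensities (before
#' normalization); the final clip to `[0, 255]` happens once, after the
#' noise stage.
#'
#' @param flip_horizontal flip along the central vertical axis with
#'   probability 1/2
#' @param flip_vertical flip along the central horizontal axis with
#'   probability 1/2
#' @param rotation_max degrees; per-image angle uniform in
#'   `[-rotation_max, rotation_max]`
#' @param shift_max pixels; per-axis integer shift uniform in
#'   `{-shift_max, ..., shift_max}`
#' @param zoom_delta dimensionless; per-image scale uniform in
#'   `[1 - zoom_delta, 1 + zoom_delta]`
#' @param brightness_add_max intensity units; additive offset uniform in
#'   `[-brightness_add_max, brightness_add_max]`
#' @param brightness_mult_range length-2 vector; multiplicative factor
#'   uniform in the range
#' @param noise_scale_max per-image Gaussian noise SD uniform in
#'   `[0, noise_scale_max]`
#' @param seed integer; together with the batch index this fully
#'   determines every random draw
#' @return object of class `augmentation_config`
#' @export
augmentation_config <- function(flip_horizontal = FALSE,
                                flip_vertical = FALSE,
                                rotation_max = 0,
                                shift_max = 0,
                                zoom_delta = 0,
                                brightness_add_max = 0,
                                brightness_mult_range = c(1, 1),
                                noise_scale_max = 0,
                                seed = 0L) {
  if (rotation_max < 0 || shift_max < 0 || zoom_delta < 0 ||
      brightness_add_max < 0 || noise_scale_max < 0)
    stop_dc("augmentation maxima must be >= 0")
  if (length(brightness_mult_range) != 2L ||
      brightness_mult_range[1] > brightness_mult_range[2] ||
      any(brightness_mult_range <= 0))
    stop_dc("brightness_mult_range must be 0 < low <= high")
  structure(list(flip_horizontal = isTRUE(flip_horizontal),
                 flip_vertical = isTRUE(flip_vertical),
                 rotation_max = rotation_max, shift_max = as.integer(shift_max),
                 zoom_delta = zoom_delta,
                 brightness_add_max = brightness_add_max,
                 brightness_mult_range = as.numeric(brightness_mult_range),
                 noise_scale_max = noise_scale_max, seed = as.integer(seed)),
            class = "augmentation_config")
}

#' Published augmentation presets
#'
#' `cifar_gray`: horizontal flip, rotation up to ±5°, ±1 pixel shifts,
#' zoom ±0.35, brightness add ±15 and multiply 0.6--1.4, Gaussian noise
#' scale up to 10. `fashion_mnist`: horizontal flip, rotation ±10°,
#' ±1 pixel shifts, brightness add ±15 and multiply 0.7--1.3, noise scale
#' up to 5.
#'
#' @param name preset name
#' @param seed seed stored in the returned config
#' @return an [augmentation_config()]
#' @export
preset_config <- function(name, seed = 0L) {
  presets <- list(
    cifar_gray = augmentation_config(
      flip_horizontal = TRUE, rotation_max = 5, shift_max = 1,
      zoom_delta = 0.35, brightness_add_max = 15,
      brightness_mult_range = c(0.6, 1.4), noise_scale_max = 10, seed = seed),
    fashion_mnist = augmentation_config(
      flip_horizontal = TRUE, rotation_max = 10, shift_max = 1,
      zoom_delta = 0, brightness_add_max = 15,
      brightness_mult_range = c(0.7, 1.3), noise_scale_max = 5, seed = seed))
  if (!name %in% names(presets))
    stop_dc("unknown preset '", name, "'; available: ",
            paste(names(presets), collapse = ", "))
  presets[[name]]
}

# nearest-neighbor rotation about the image center; vacated pixels 0
rotate_nn <- function(img, angle_deg) {
  d <- dim(img)
  h <- d[1]; w <- d[2]
  cy <- (h - 1) / 2; cx <- (w - 1) / 2
  th <- angle_deg * pi / 180
  r <- matrix(rep(0:(h - 1), w), h, w)
  c_ <- matrix(rep(0:(w - 1), each = h), h, w)
  dy <- r - cy; dx <- c_ - cx
  # inverse map: source = R(-theta) * dest
  sy <- cos(th) * dy + sin(th) * dx + cy
  sx <- -sin(th) * dy + cos(th) * dx + cx
  iy <- round_half_up(sy); ix <- round_half_up(sx)
  ok <- as.vector(iy >= 0 & iy < h & ix >= 0 & ix < w)
  idx <- cbind(as.vector(pmin(pmax(iy, 0), h - 1)) + 1L,
               as.vector(pmin(pmax(ix, 0), w - 1)) + 1L)
  out <- array(0, d)
  for (ch in seq_len(d[3])) {
    plane <- img[, , ch][idx]
    plane[!ok] <- 0
    out[, , ch] <- plane
  }
  out
}

# nearest-neighbor zoom about the center at fixed canvas size
zoom_nn <- function(img, factor) {
  d <- dim(img)
  h <- d[1]; w <- d[2]
  cy <- (h - 1) / 2; cx <- (w - 1) / 2
  r <- matrix(rep(0:(h - 1), w), h, w)
  c_ <- matrix(rep(0:(w - 1), each = h), h, w)
  sy <- (r - cy) / factor + cy
  sx <- (c_ - cx) / factor + cx
  iy <- round_half_up(sy); ix <- round_half_up(sx)
  ok <- as.vector(iy >= 0 & iy < h & ix >= 0 & ix < w)
  idx <- cbind(as.vector(pmin(pmax(iy, 0), h - 1)) + 1L,
               as.vector(pmin(pmax(ix, 0), w - 1)) + 1L)
  out <- array(0, d)
  for (ch in seq_len(d[3])) {
    plane <- img[, , ch][idx]
    plane[!ok] <- 0
    out[, , ch] <- plane
  }
  out
}

# integer shift with zero fill; (dy, dx) moves content down/right
shift_int <- function(img, dy, dx) {
  d <- dim(img)
  out <- array(0, d)
  sy <- seq_len(d[1]) - dy; sx <- seq_len(d[2]) - dx
  oky <- sy >= 1 & sy <= d[1]; okx <- sx >= 1 & sx <= d[2]
  if (any(oky) && any(okx))
    out[which(oky), which(okx), ] <- img[sy[oky], sx[okx], , drop = FALSE]
  out
}

#' Augment a batch of images
#'
#' Applies the augmentation operator chain in fixed order: flips,
#' rotation, shift, zoom, brightness add, brightness multiply, Gaussian
#' noise, then rounding/clipping to 8-bit and a final center crop to
#' `target_side` (cropping last avoids rotation edge artifacts). The
#' batch must arrive at a working size at least `target_side`. Output is
#' bit-reproducible for a given `(config$seed, batch_index)`.
#'
#' @param batch array `N x H x W x C`, raw 0--255 intensities
#' @param config an [augmentation_config()]
#' @param target_side side of the returned square images
#' @param batch_index integer identifying the batch within the run
#' @return array `N x target_side x target_side x C`, integer-valued in
#'   `[0, 255]`
#' @export
augment_batch <- function(batch, config, target_side = dim(batch)[2],
                          batch_index = 0L) {
  stopifnot(inherits(config, "augmentation_config"))
  d <- dim(batch)
  if (length(d) != 4L) stop_dc("batch must be N x H x W x C")
  if (d[2] < target_side || d[3] < target_side)
    stop_dc("working side (", d[2], "x", d[3],
            ") smaller than target side ", target_side)
  n <- d[1]
  identity_cfg <- !config$flip_horizontal && !config$flip_vertical &&
    config$rotation_max == 0 && config$shift_max == 0 &&
    config$zoom_delta == 0 && config$brightness_add_max == 0 &&
    all(config$brightness_mult_range == 1) && config$noise_scale_max == 0
  if (identity_cfg)
    return(center_crop_batch(batch, target_side))

  with_local_seed(derive_seed(config$seed, batch_index), {
    # draw all per-image parameters up front, in fixed order
    do_hflip <- if (config$flip_horizontal) stats::runif(n) < 0.5 else rep(FALSE, n)
    do_vflip <- if (config$flip_vertical) stats::runif(n) < 0.5 else rep(FALSE, n)
    angles <- if (config$rotation_max > 0)
      stats::runif(n, -config$rotation_max, config$rotation_max) else numeric(n)
    shifts_y <- shifts_x <- integer(n)
    if (config$shift_max > 0) {
      shifts_y <- sample.int(2L * config$shift_max + 1L, n, replace = TRUE) -
        config$shift_max - 1L
      shifts_x <- sample.int(2L * config$shift_max + 1L, n, replace = TRUE) -
        config$shift_max - 1L
    }
    zooms <- if (config$zoom_delta > 0)
      stats::runif(n, 1 - config$zoom_delta, 1 + config$zoom_delta) else rep(1, n)
    adds <- if (config$brightness_add_max > 0)
      stats::runif(n, -config$brightness_add_max, config$brightness_add_max)
      else numeric(n)
    mr <- config$brightness_mult_range
    mults <- if (mr[1] != 1 || mr[2] != 1)
      stats::runif(n, mr[1], mr[2]) else rep(1, n)
    noise_sds <- if (config$noise_scale_max > 0)
      stats::runif(n, 0, config$noise_scale_max) else numeric(n)

    out <- batch
    for (i in seq_len(n)) {
      img <- out[i, , , , drop = TRUE]
      if (length(dim(img)) == 2L) dim(img) <- c(d[2], d[3], 1L)
      if (do_hflip[i]) img <- img[, rev(seq_len(d[3])), , drop = FALSE]
      if (do_vflip[i]) img <- img[rev(seq_len(d[2])), , , drop = FALSE]
      if (angles[i] != 0) img <- rotate_nn(img, angles[i])
      if (shifts_y[i] != 0L || shifts_x[i] != 0L)
        img <- shift_int(img, shifts_y[i], shifts_x[i])
      if (zooms[i] != 1) img <- zoom_nn(img, zooms[i])
      if (adds[i] != 0) img <- img + adds[i]
      if (mults[i] != 1) img <- img * mults[i]
      if (noise_sds[i] > 0)
        img <- img + array(stats::rnorm(length(img), 0, noise_sds[i]), dim(img))
      out[i, , , ] <- img
    }
    out <- clip(round_half_up(out), 0, 255)
    center_crop_batch(out, target_side)
  })
}
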