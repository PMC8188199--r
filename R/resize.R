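#' Size-equalization specification
#'
#' @param target_side requested square side in pixels
#' @param mode `"center_crop"` (remove equal margins, extra pixel taken
#'   from the trailing side), `"pad"` (add equal zero margins, extra pixel
#'   on the trailing side), or `"scale_then_equalize"` (scale by
#'   `scale_factor` first, then crop/pad per axis as needed)
#' @param interpolation resampling kernel used when scaling
#' @param scale_factor ratio used by `scale_then_equalize`
#' @return an object of class `size_spec`
#' @export
size_spec <- function(target_side,
                      mode = c("center_crop", "pad", "scale_then_equalize"),
                      interpolation = c("nearest", "linear", "quadratic", "cubic"),
                      scale_factor = 1) {
  mode <- match.arg(mode)
  interpolation <- match.arg(interpolation)
  if (target_side < 1) stop_dc("target_side must be >= 1")
  if (scale_factor <= 0) stop_dc("scale_factor must be > 0")
  structure(list(target_side = as.integer(target_side), mode = mode,
                 interpolation = interpolation, scale_factor = scale_factor),
            class = "size_spec")
}

# 1-D resampling matrix mapping `n_in` samples to `n_out = floor(n_in * f)`
# samples.  Output coordinate i (0-based) samples input coordinate
# (i + 0.5)/f - 0.5 (center-aligned, so f = 1 is the identity).  Kernels:
# nearest (1 tap), linear (2-tap), quadratic (3-point Lagrange), cubic
# (4-point Lagrange); border taps are clamped so weights always sum to 1
# and a constant signal stays constant.
interp_matrix <- function(n_in, factor, interpolation) {
  n_out <- floor(n_in * factor)
  if (n_out < 1) stop_dc("scale factor ", factor, " collapses a ", n_in,
                         "-pixel axis to zero size")
  src <- (seq_len(n_out) - 0.5) / factor - 0.5   # 0-based source coords
  M <- matrix(0, n_out, n_in)
  cl <- function(j) pmin(pmax(j, 0L), n_in - 1L)
  if (interpolation == "nearest") {
    j <- cl(floor(src + 0.5))
    M[cbind(seq_len(n_out), j + 1L)] <- 1
  } else if (interpolation == "linear") {
    j0 <- floor(src); w <- src - j0
    M[cbind(seq_len(n_out), cl(j0) + 1L)] <-
      M[cbind(seq_len(n_out), cl(j0) + 1L)] + (1 - w)
    M[cbind(seq_len(n_out), cl(j0 + 1) + 1L)] <-
      M[cbind(seq_len(n_out), cl(j0 + 1) + 1L)] + w
  } else {
    # Lagrange interpolation through p support points
    p <- if (interpolation == "quadratic") 3L else 4L
    base <- if (p == 3L) floor(src + 0.5) - 1L else floor(src) - 1L
    offs <- 0:(p - 1L)
    for (i in seq_len(n_out)) {
      xs <- base[i] + offs          # support abscissae (may repeat at edges)
      w <- vapply(seq_len(p), function(a) {
        others <- xs[-a]
        prod((src[i] - others) / (xs[a] - others))
      }, numeric(1))
      js <- cl(xs) + 1L
      for (a in seq_len(p)) M[i, js[a]] <- M[i, js[a]] + w[a]
    }
  }
  M
}

#' Scale an image by a magnification factor
#'
#' The output side is `floor(side * factor)`. Four resampling kernels are
#' available: nearest neighbor, linear, quadratic, and cubic (separable
#' Lagrange interpolation). A 28x28 image scaled by 1.15 with nearest
#' neighbor becomes 32x32.
#'
#' @param img `H x W x C` array (or `H x W` matrix)
#' @param factor magnification ratio, > 0
#' @param interpolation one of `"nearest"`, `"linear"`, `"quadratic"`,
#'   `"cubic"`
#' @return scaled array `floor(H*factor) x floor(W*factor) x C`
#' @export
scale_image <- function(img, factor,
                        interpolation = c("nearest", "linear", "quadratic", "cubic")) {
  interpolation <- match.arg(interpolation)
  if (factor <= 0) stop_dc("scale factor must be > 0")
  was_mat <- is.matrix(img)
  if (was_mat) dim(img) <- c(dim(img), 1L)
  d <- dim(img)
  Mr <- interp_matrix(d[1], factor, interpolation)
  Mc <- interp_matrix(d[2], factor, interpolation)
  out <- array(0, c(nrow(Mr), nrow(Mc), d[3]))
  for (ch in seq_len(d[3]))
    out[, , ch] <- Mr %*% img[, , ch] %*% t(Mc)
  if (interpolation == "nearest") out <- round_half_up(out)
  if (was_mat) out <- out[, , 1]
  out
}

# crop/pad one axis length n to target t; returns 1-based index window for
# crop (negative action = pad amounts).  Odd remainders go to the trailing
# (bottom/right) side.
axis_crop_window <- function(n, t) {
  start <- floor((n - t) / 2)
  (start + 1L):(start + t)
}

#' Equalize an image to a square target size by cropping or padding
#'
#' Center cropping removes equal margins (the extra pixel for odd
#' remainders is taken from the trailing side); padding adds equal
#' zero-valued margins (extra pixel on the trailing side).
#' `scale_then_equalize` scales by `spec$scale_factor` first and then
#' crops or pads per axis as required. Rectangular inputs are handled per
#' axis.
#'
#' @param img `H x W x C` array (or `H x W` matrix)
#' @param spec a [size_spec()]
#' @return array `target_side x target_side x C`
#' @export
equalize_size <- function(img, spec) {
  stopifnot(inherits(spec, "size_spec"))
  was_mat <- is.matrix(img)
  if (was_mat) dim(img) <- c(dim(img), 1L)
  t <- spec$target_side
  if (spec$mode == "scale_then_equalize") {
    img <- scale_image(img, spec$scale_factor, spec$interpolation)
    out <- equalize_axis(img, t, strict = NULL)
  } else if (spec$mode == "center_crop") {
    d <- dim(img)
    if (d[1] < t || d[2] < t)
      stop_dc("input (", d[1], "x", d[2], ") smaller than target ", t,
              "; use mode = \"pad\"")
    out <- equalize_axis(img, t, strict = "crop")
  } else {
    d <- dim(img)
    if (d[1] > t || d[2] > t)
      stop_dc("input (", d[1], "x", d[2], ") larger than target ", t,
              "; use mode = \"center_crop\"")
    out <- equalize_axis(img, t, strict = "pad")
  }
  if (was_mat) out <- out[, , 1]
  out
}

# per-axis crop/pad worker; strict = "crop"/"pad" enforces one action,
# NULL picks per axis.
equalize_axis <- function(img, t, strict = NULL) {
  d <- dim(img)
  # rows
  if (d[1] > t) img <- img[axis_crop_window(d[1], t), , , drop = FALSE]
  else if (d[1] < t) {
    before <- floor((t - d[1]) / 2); after <- t - d[1] - before
    z <- function(n) array(0, c(n, dim(img)[2], dim(img)[3]))
    img <- abind_rows(z(before), img, z(after))
  }
  d <- dim(img)
  if (d[2] > t) img <- img[, axis_crop_window(d[2], t), , drop = FALSE]
  else if (d[2] < t) {
    before <- floor((t - d[2]) / 2); after <- t - d[2] - before
    z <- function(n) array(0, c(dim(img)[1], n, dim(img)[3]))
    img <- abind_cols(z(before), img, z(after))
  }
  img
}

# minimal 3-d binds along rows / cols (avoids an abind dependency)
abind_rows <- function(a, b, d) {
  out <- array(0, c(dim(a)[1] + dim(b)[1] + dim(d)[1], dim(b)[2], dim(b)[3]))
  i <- 0L
  for (x in list(a, b, d)) {
    if (dim(x)[1] > 0) out[i + seq_len(dim(x)[1]), , ] <- x
    i <- i + dim(x)[1]
  }
  out
}
abind_cols <- function(a, b, d) {
  out <- array(0, c(dim(b)[1], dim(a)[2] + dim(b)[2] + dim(d)[2], dim(b)[3]))
  i <- 0L
  for (x in list(a, b, d)) {
    if (dim(x)[2] > 0) out[, i + seq_len(dim(x)[2]), ] <- x
    i <- i + dim(x)[2]
  }
  out
}

# center crop a batch (N,H,W,C) to side t (used by the augmentation engine)
center_crop_batch <- function(batch, t) {
  d <- dim(batch)
  if (d[2] < t || d[3] < t)
    stop_dc("working side (", d[2], "x", d[3], ") smaller than target ", t)
  batch[, axis_crop_window(d[2], t), axis_crop_window(d[3], t), , drop = FALSE]
}
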