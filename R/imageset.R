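#' Uniform labeled image container
#'
#' Every pipeline stage in deepclass consumes and produces the same
#' container: a rank-4 array of `N` images (`N x H x W x C`, 8-bit
#' intensities 0--255 before normalization), an integer label per image
#' (`0 .. K-1`), the `K` class names, a per-image source identifier, and a
#' split tag.
#'
#' @param images numeric array `N x H x W x C`; `C` must be 1 (grayscale)
#'   or 3 (RGB). A 3-d array is interpreted as `N x H x W` single-channel.
#' @param labels integer vector of length `N` with values in `0 .. K-1`
#' @param class_names character vector of length `K`
#' @param source_ids character vector of length `N` (file path or fixture
#'   id); defaults to `img000001, ...`
#' @param split one of `"train"`, `"valid"`, `"test"`
#' @return an object of class `image_set`
#' @export
image_set <- function(images, labels, class_names,
                      source_ids = NULL, split = "train") {
  if (length(dim(images)) == 3L)
    dim(images) <- c(dim(images), 1L)
  if (length(dim(images)) != 4L)
    stop_dc("`images` must be a rank-4 array (N x H x W x C)")
  d <- dim(images)
  if (!d[4] %in% c(1L, 3L))
    stop_dc("channel count must be 1 or 3, got ", d[4])
  labels <- as.integer(labels)
  if (length(labels) != d[1])
    stop_dc("length(labels) [", length(labels), "] != number of images [", d[1], "]")
  k <- length(class_names)
  if (k < 1L) stop_dc("at least one class name required")
  if (any(labels < 0L | labels >= k))
    stop_dc("labels must lie in [0, ", k - 1L, "]")
  if (is.null(source_ids))
    source_ids <- sprintf("img%06d", seq_len(d[1]))
  if (length(source_ids) != d[1])
    stop_dc("length(source_ids) != number of images")
  split <- match.arg(split, c("train", "valid", "test"))
  structure(
    list(images = images, labels = labels,
         class_names = as.character(class_names),
         source_ids = as.character(source_ids), split = split),
    class = "image_set")
}

#' @export
print.image_set <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<image_set> %d images, %dx%dx%d, %d classes, split '%s'\n",
              d[1], d[2], d[3], d[4], length(x$class_names), x$split))
  tab <- table(factor(x$labels, levels = seq_along(x$class_names) - 1L,
                      labels = x$class_names))
  print(tab)
  invisible(x)
}

#' Number of images in a container
#' @param x an `image_set` or disk-backed `image_set_disk`
#' @return integer count
#' @export
n_images <- function(x) UseMethod("n_images")

#' @export
n_images.image_set <- function(x) dim(x$images)[1]

#' Fetch images by index from a container
#'
#' The single access path shared by the RAM-resident and the disk-backed
#' container, so training code is agnostic to where pixels live.
#' @param x container
#' @param idx 1-based indices
#' @return array `length(idx) x H x W x C`
#' @export
get_images <- function(x, idx) UseMethod("get_images")

#' @export
get_images.image_set <- function(x, idx) {
  x$images[idx, , , , drop = FALSE]
}

#' Subset an image container
#' @param x an `image_set`
#' @param idx 1-based indices to keep
#' @param split optional new split tag
#' @return an `image_set`
#' @export
subset_imageset <- function(x, idx, split = x$split) {
  image_set(x$images[idx, , , , drop = FALSE], x$labels[idx],
            x$class_names, x$source_ids[idx], split)
}

#' Geometry of a container
#' @param x an `image_set` or `image_set_disk`
#' @return integer vector `c(H, W, C)`
#' @export
image_geometry <- function(x) UseMethod("image_geometry")

#' @export
image_geometry.image_set <- function(x) dim(x$images)[2:4]

# ---------------------------------------------------------------------------
# folder loading

# Decode one image file to an H x W x C array of 8-bit intensities.
# EBImage stores pixels width-first in [0,1]; transpose to row-major and
# rescale to 0..255.
decode_image_file <- function(path) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) {
    a <- aperm(a, c(2L, 1L))
    dim(a) <- c(dim(a), 1L)
  } else {
    if (dim(a)[3] == 4L) a <- a[, , 1:3, drop = FALSE]  # drop alpha
    if (dim(a)[3] == 2L) a <- a[, , 1L, drop = FALSE]   # gray + alpha
    a <- aperm(a, c(2L, 1L, 3L))
  }
  round_half_up(clip(a * 255, 0, 255))
}

#' Load a one-subdirectory-per-class image folder
#'
#' Each subdirectory of `root` is one class; its name becomes the class
#' name (classes sorted alphabetically, labels `0 .. K-1` in that order).
#' PNG, TIFF, and JPEG files are decoded to 8-bit. Unreadable files are
#' skipped with a warning; all decodable images must share one geometry.
#'
#' @param root directory containing one subdirectory per class
#' @param split split tag recorded in the container
#' @return an `image_set`
#' @export
load_folder <- function(root, split = "train") {
  if (!dir.exists(root)) stop_dc("folder not found: ", root)
  classes <- sort(list.dirs(root, full.names = FALSE, recursive = FALSE))
  if (length(classes) == 0L) stop_dc("no classes found under ", root)
  exts <- "\\.(png|tif|tiff|jpg|jpeg)$"
  imgs <- list(); labels <- integer(); ids <- character()
  for (k in seq_along(classes)) {
    files <- sort(list.files(file.path(root, classes[k]),
                             pattern = exts, ignore.case = TRUE,
                             full.names = TRUE))
    for (f in files) {
      a <- tryCatch(decode_image_file(f), error = function(e) {
        warn_dc("skipping unreadable file ", f, ": ", conditionMessage(e))
        NULL
      })
      if (is.null(a)) next
      imgs[[length(imgs) + 1L]] <- a
      labels <- c(labels, k - 1L)
      ids <- c(ids, f)
    }
  }
  if (length(imgs) == 0L) stop_dc("no usable images under ", root)
  dims <- vapply(imgs, function(a) dim(a), integer(3))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]) ||
      any(dims[3, ] != dims[3, 1]))
    stop_dc("images differ in size (e.g., ", dims[1, 1], "x", dims[2, 1],
            " vs ", dims[1, which(dims[1, ] != dims[1, 1] |
                                  dims[2, ] != dims[2, 1])[1]],
            "x...); equalize sizes first with scale_image()/equalize_size()")
  h <- dims[1, 1]; w <- dims[2, 1]; cc <- dims[3, 1]
  arr <- array(0, c(length(imgs), h, w, cc))
  for (i in seq_along(imgs)) arr[i, , , ] <- imgs[[i]]
  image_set(arr, labels, classes, ids, split)
}

# ---------------------------------------------------------------------------
# color conversion

#' Convert RGB images to grayscale (luminosity method)
#'
#' Weighted channel sum `0.21 R + 0.72 G + 0.07 B`, reflecting the eye's
#' higher sensitivity to green; results are rounded half-up and clipped to
#' `[0, 255]` for 8-bit storage.
#'
#' @param img an `H x W x 3` array, an `N x H x W x 3` batch, or an
#'   `image_set` with 3-channel images
#' @return same structure with a single channel
#' @export
rgb_to_gray <- function(img) {
  if (inherits(img, "image_set")) {
    out <- img
    out$images <- rgb_to_gray(img$images)
    return(out)
  }
  d <- dim(img)
  nd <- length(d)
  if (d[nd] == 1L) stop_dc("image is already grayscale")
  if (d[nd] != 3L) stop_dc("expected a 3-channel image, got ", d[nd], " channels")
  if (nd == 3L) {
    g <- 0.21 * img[, , 1] + 0.72 * img[, , 2] + 0.07 * img[, , 3]
    out <- round_half_up(clip(g))
    dim(out) <- c(d[1], d[2], 1L)
  } else if (nd == 4L) {
    g <- 0.21 * img[, , , 1] + 0.72 * img[, , , 2] + 0.07 * img[, , , 3]
    out <- round_half_up(clip(g))
    dim(out) <- c(d[1], d[2], d[3], 1L)
  } else stop_dc("expected a 3-d image or 4-d batch")
  out
}

#' Convert grayscale images to RGB by channel stacking
#'
#' Three identical copies of the grayscale channel; the luminosity weights
#' sum to 1, so `rgb_to_gray(gray_to_rgb(x))` returns `x`.
#' @inheritParams rgb_to_gray
#' @return same structure with three identical channels
#' @export
gray_to_rgb <- function(img) {
  if (inherits(img, "image_set")) {
    out <- img
    out$images <- gray_to_rgb(img$images)
    return(out)
  }
  d <- dim(img)
  nd <- length(d)
  if (d[nd] == 3L) stop_dc("image is already RGB")
  if (d[nd] != 1L) stop_dc("expected a 1-channel image")
  if (nd == 3L) {
    out <- array(img, c(d[1], d[2], 3L))
  } else if (nd == 4L) {
    out <- array(0, c(d[1:3], 3L))
    for (ch in 1:3) out[, , , ch] <- img[, , , 1]
  } else stop_dc("expected a 3-d image or 4-d batch")
  out
}
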