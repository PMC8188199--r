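# Canonical on-disk container: one HDF5 file with datasets
#   images  (N x H x W x C, uint8; C may be absent for grayscale)
#   labels  (N, integer, 0-based)
# and root attributes class_names, source_ids, split.

#' Write an image set to the canonical HDF5 layout
#'
#' @param x an `image_set`
#' @param path output `.h5` file (overwritten)
#' @return `path`, invisibly
#' @export
write_imageset_h5 <- function(x, path) {
  stopifnot(inherits(x, "image_set"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  d <- dim(x$images)
  rhdf5::h5createDataset(path, "images", dims = d, storage.mode = "integer",
                         chunk = c(min(d[1], 64L), d[2], d[3], d[4]),
                         level = 4)
  rhdf5::h5write(array(as.integer(round(x$images)), d), path, "images")
  rhdf5::h5write(x$labels, path, "labels")
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(x$class_names, fid, "class_names")
  rhdf5::h5writeAttribute(x$source_ids, fid, "source_ids")
  rhdf5::h5writeAttribute(x$split, fid, "split")
  rhdf5::H5Fclose(fid)
  invisible(path)
}

read_h5_meta <- function(path) {
  att <- rhdf5::h5readAttributes(path, "/")
  list(class_names = as.character(att$class_names),
       source_ids = if (!is.null(att$source_ids)) as.character(att$source_ids),
       split = if (!is.null(att$split)) as.character(att$split) else "train")
}

#' Read an image set from the canonical HDF5 layout
#'
#' Loads the whole container into RAM. A 3-d `images` dataset is
#' interpreted as single-channel.
#'
#' @param path `.h5` file written by [write_imageset_h5()] (or any file
#'   following the layout)
#' @return an `image_set`
#' @export
read_imageset_h5 <- function(path) {
  if (!file.exists(path)) stop_dc("file not found: ", path)
  imgs <- rhdf5::h5read(path, "images")
  labels <- as.integer(rhdf5::h5read(path, "labels"))
  meta <- read_h5_meta(path)
  image_set(imgs, labels, meta$class_names,
            meta$source_ids %||% NULL, meta$split)
}

#' Open an HDF5 image set for streamed (disk-backed) access
#'
#' Presents the same container contract as an in-RAM `image_set` —
#' [n_images()], [get_images()], [image_geometry()], `$labels`,
#' `$class_names` — but reads pixel batches from disk on demand, so
#' datasets larger than RAM can be trained on.
#'
#' @param path `.h5` file in the canonical layout
#' @return object of class `image_set_disk`
#' @export
open_imageset_h5 <- function(path) {
  if (!file.exists(path)) stop_dc("file not found: ", path)
  labels <- as.integer(rhdf5::h5read(path, "labels"))
  meta <- read_h5_meta(path)
  fid <- rhdf5::H5Fopen(path)
  did <- rhdf5::H5Dopen(fid, "images")
  sid <- rhdf5::H5Dget_space(did)
  dims <- rhdf5::H5Sget_simple_extent_dims(sid)$size
  rhdf5::H5Sclose(sid); rhdf5::H5Dclose(did); rhdf5::H5Fclose(fid)
  if (length(dims) == 3L) dims <- c(dims, 1L)
  structure(list(path = path, dim = as.integer(dims), labels = labels,
                 class_names = meta$class_names,
                 source_ids = meta$source_ids %||%
                   sprintf("img%06d", seq_len(dims[1])),
                 split = meta$split),
            class = "image_set_disk")
}

#' @export
n_images.image_set_disk <- function(x) x$dim[1]

#' @export
image_geometry.image_set_disk <- function(x) x$dim[2:4]

#' @export
get_images.image_set_disk <- function(x, idx) {
  out <- rhdf5::h5read(x$path, "images",
                       index = list(idx, NULL, NULL, NULL))
  if (length(dim(out)) == 3L) dim(out) <- c(dim(out), 1L)
  storage.mode(out) <- "double"
  out
}

#' @export
print.image_set_disk <- function(x, ...) {
  cat(sprintf("<image_set_disk> %d images, %dx%dx%d (streamed from %s)\n",
              x$dim[1], x$dim[2], x$dim[3], x$dim[4], x$path))
  invisible(x)
}
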