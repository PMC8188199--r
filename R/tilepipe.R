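# Segmentation-as-classification: partition stained-culture micrographs
# into square tiles, label tiles from expert pixel masks, balance by
# oversampling positive tiles, and reconstruct per-image tile maps.

#' Image plus expert pixel mask
#'
#' @param image `H x W x 3` array, 8-bit intensities
#' @param mask `H x W` logical matrix; `TRUE` marks expert-annotated
#'   (differentiated) pixels
#' @param source_id identifier of the source micrograph
#' @return object of class `masked_image`
#' @export
masked_image <- function(image, mask, source_id = "img") {
  if (is.matrix(image)) dim(image) <- c(dim(image), 1L)
  d <- dim(image)
  if (!is.matrix(mask) || !all(dim(mask) == d[1:2]))
    stop_dc("mask must be an H x W logical matrix matching the image")
  structure(list(image = image, mask = mask != 0,
                 source_id = as.character(source_id)),
            class = "masked_image")
}

#' Recover the pixel mask from a green-overlay labeled image
#'
#' Expert annotations are stored as a uniform pure-green overlay
#' (RGB exactly (0, 255, 0)); the mask is true exactly at those pixels.
#' Near-green pixels do not match.
#'
#' @param labeled `H x W x 3` labeled image
#' @param original optional unlabeled original (stored as the image;
#'   defaults to `labeled`)
#' @param source_id identifier
#' @return a [masked_image()]
#' @export
decode_mask <- function(labeled, original = NULL, source_id = "img") {
  d <- dim(labeled)
  if (length(d) != 3L || d[3] != 3L)
    stop_dc("labeled image must be H x W x 3")
  mask <- labeled[, , 1] == 0 & labeled[, , 2] == 255 & labeled[, , 3] == 0
  masked_image(original %||% labeled, mask, source_id)
}

#' Grid of per-tile class labels or predictions
#'
#' Tile `(r, c)` (0-based) covers pixel rows `[r*s, (r+1)*s)` and columns
#' `[c*s, (c+1)*s)` of the source image (row-major, origin top-left,
#' half-open intervals).
#'
#' @param grid `R x C` integer matrix of tile classes
#' @param tile_side tile side `s` in pixels
#' @param source_id source image identifier
#' @return object of class `tile_map`
#' @export
tile_map <- function(grid, tile_side, source_id = "img") {
  structure(list(grid = grid, tile_side = as.integer(tile_side),
                 source_id = as.character(source_id)),
            class = "tile_map")
}

#' Partition an image into non-overlapping square tiles
#'
#' Produces `floor(H/s) * floor(W/s)` tiles in row-major order; residual
#' border pixels (when `H` or `W` is not divisible by `s`) are discarded
#' with a warning. A 320 x 320 image at `s = 32` yields exactly 100 tiles.
#'
#' @param img `H x W x C` array or `H x W` matrix
#' @param tile_side tile side `s >= 1`
#' @return list: `tiles` (array `n x s x s x C`), `grid_dim` `c(R, C)`,
#'   `offsets` data frame with 0-based `row0`, `col0` per tile
#' @export
partition_tiles <- function(img, tile_side) {
  was_mat <- is.matrix(img)
  if (was_mat) dim(img) <- c(dim(img), 1L)
  d <- dim(img)
  s <- as.integer(tile_side)
  if (s < 1L) stop_dc("tile_side must be >= 1")
  if (s > min(d[1], d[2]))
    stop_dc("tile_side ", s, " exceeds image size ", d[1], "x", d[2])
  nr <- d[1] %/% s; nc <- d[2] %/% s
  if (d[1] %% s != 0L || d[2] %% s != 0L)
    warn_dc("image ", d[1], "x", d[2], " not divisible by ", s,
            "; discarding border pixels")
  n <- nr * nc
  tiles <- array(0, c(n, s, s, d[3]))
  row0 <- col0 <- integer(n)
  i <- 0L
  for (r in seq_len(nr) - 1L) for (cc in seq_len(nc) - 1L) {
    i <- i + 1L
    tiles[i, , , ] <- img[r * s + seq_len(s), cc * s + seq_len(s), ,
                          drop = FALSE]
    row0[i] <- r * s; col0[i] <- cc * s
  }
  list(tiles = tiles, grid_dim = c(nr, nc),
       offsets = data.frame(row0 = row0, col0 = col0))
}

#' Label tiles from their marked-pixel counts
#'
#' A tile is class 1 ("with differentiation") iff it contains at least
#' `min_marked` marked pixels, else class 0.
#'
#' @param mask_tiles tile array `n x s x s x 1` (or `n x s x s`) from
#'   [partition_tiles()] of the mask
#' @param min_marked threshold in pixels (default 5)
#' @return integer vector of classes (0/1)
#' @export
label_tiles <- function(mask_tiles, min_marked = 5L) {
  if (length(dim(mask_tiles)) == 3L)
    dim(mask_tiles) <- c(dim(mask_tiles), 1L)
  counts <- apply(mask_tiles != 0, 1L, sum)
  as.integer(counts >= min_marked)
}

#' Draw extra positive tiles from random locations
#'
#' Rebalances tile datasets: draws tiles at uniformly random fully-inside
#' offsets, keeping those containing more than `min_marked - 1` (i.e., at
#' least `min_marked`) marked pixels, by rejection sampling with a bounded
#' attempt budget. Random placement also yields positive structures at
#' varied positions within the tile.
#'
#' @param masked a [masked_image()]
#' @param n_extra number of positive tiles requested
#' @param tile_side tile side in pixels
#' @param min_marked positivity threshold (default 5)
#' @param max_attempts total rejection-sampling budget (default 1000 per
#'   requested tile)
#' @return list: `tiles` (`m x s x s x C`, `m <= n_extra`), `offsets`
#'   (0-based data frame); fewer than `n_extra` tiles (with a warning)
#'   when the mask is too sparse
#' @export
oversample_positive_tiles <- function(masked, n_extra, tile_side,
                                      min_marked = 5L,
                                      max_attempts = 1000L * n_extra) {
  stopifnot(inherits(masked, "masked_image"))
  s <- as.integer(tile_side)
  d <- dim(masked$image)
  if (sum(masked$mask) < min_marked)
    stop_dc("mask of ", masked$source_id, " contains fewer than ",
            min_marked, " marked pixels")
  if (n_extra == 0L)
    return(list(tiles = array(0, c(0L, s, s, d[3])),
                offsets = data.frame(row0 = integer(), col0 = integer())))
  max_r <- d[1] - s; max_c <- d[2] - s
  tiles <- array(0, c(n_extra, s, s, d[3]))
  row0 <- col0 <- integer(n_extra)
  found <- 0L; attempts <- 0L
  while (found < n_extra && attempts < max_attempts) {
    attempts <- attempts + 1L
    r <- sample.int(max_r + 1L, 1L) - 1L
    cc <- sample.int(max_c + 1L, 1L) - 1L
    if (sum(masked$mask[r + seq_len(s), cc + seq_len(s)]) >= min_marked) {
      found <- found + 1L
      tiles[found, , , ] <- masked$image[r + seq_len(s), cc + seq_len(s), ,
                                         drop = FALSE]
      row0[found] <- r; col0[found] <- cc
    }
  }
  if (found < n_extra) {
    warn_dc("attempt budget exhausted for ", masked$source_id, ": got ",
            found, " of ", n_extra, " positive tiles")
    tiles <- tiles[seq_len(found), , , , drop = FALSE]
    row0 <- row0[seq_len(found)]; col0 <- col0[seq_len(found)]
  }
  list(tiles = tiles, offsets = data.frame(row0 = row0, col0 = col0))
}

#' Assemble a two-class tile dataset from masked images
#'
#' Runs the full pipeline on every masked image: grid partition, tile
#' labeling at `min_marked`, and (optionally) oversampling of positive
#' tiles at random locations until the class counts balance. Per-tile
#' provenance is kept in `source_ids` as `"<source_id>@<row0>:<col0>"`.
#'
#' @param masked_list list of [masked_image()] objects
#' @param tile_side tile side in pixels (default 32)
#' @param min_marked positivity threshold in pixels (default 5)
#' @param oversample `"balance"` to add positive tiles until the classes
#'   are even, `"none"` for grid tiles only
#' @param split split tag for the returned container
#' @return an `image_set` with classes `c("0", "1")`
#' @export
build_tile_dataset <- function(masked_list, tile_side = 32L, min_marked = 5L,
                               oversample = c("balance", "none"),
                               split = "train") {
  oversample <- match.arg(oversample)
  if (length(masked_list) == 0L) stop_dc("need at least one masked image")
  tiles_l <- list(); labels <- integer(); ids <- character()
  for (m in masked_list) {
    stopifnot(inherits(m, "masked_image"))
    pt <- partition_tiles(m$image, tile_side)
    pm <- partition_tiles(m$mask * 1, tile_side)
    cls <- label_tiles(pm$tiles, min_marked)
    tiles_l[[length(tiles_l) + 1L]] <- pt$tiles
    labels <- c(labels, cls)
    ids <- c(ids, sprintf("%s@%d:%d", m$source_id, pt$offsets$row0,
                          pt$offsets$col0))
  }
  if (oversample == "balance") {
    deficit <- sum(labels == 0L) - sum(labels == 1L)
    eligible <- Filter(function(m) sum(m$mask) >= min_marked, masked_list)
    if (deficit > 0L && length(eligible) > 0L) {
      per_img <- diff(round(seq(0, deficit, length.out = length(eligible) + 1L)))
      for (i in seq_along(eligible)) {
        if (per_img[i] == 0L) next
        ex <- oversample_positive_tiles(eligible[[i]], per_img[i], tile_side,
                                        min_marked)
        if (dim(ex$tiles)[1] == 0L) next
        tiles_l[[length(tiles_l) + 1L]] <- ex$tiles
        labels <- c(labels, rep(1L, dim(ex$tiles)[1]))
        ids <- c(ids, sprintf("%s@%d:%d", eligible[[i]]$source_id,
                              ex$offsets$row0, ex$offsets$col0))
      }
    }
  }
  n <- length(labels)
  s <- as.integer(tile_side); ch <- dim(tiles_l[[1]])[4]
  all_tiles <- array(0, c(n, s, s, ch))
  i <- 0L
  for (tl in tiles_l) {
    k <- dim(tl)[1]
    if (k > 0L) all_tiles[i + seq_len(k), , , ] <- tl
    i <- i + k
  }
  image_set(all_tiles, labels, c("0", "1"), ids, split)
}

#' Parse tile provenance ids back to offsets
#' @param source_ids ids of the form `"<source>@<row0>:<col0>"`
#' @return data frame with `source_id`, `row0`, `col0`
#' @export
parse_tile_ids <- function(source_ids) {
  m <- regmatches(source_ids,
                  regexec("^(.*)@([0-9]+):([0-9]+)$", source_ids))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) stop_dc("unparseable tile id: ", source_ids[bad][1])
  data.frame(source_id = vapply(m, `[`, character(1), 2L),
             row0 = as.integer(vapply(m, `[`, character(1), 3L)),
             col0 = as.integer(vapply(m, `[`, character(1), 4L)))
}

#' Predict the tile map of a whole image
#'
#' Partitions the image, classifies every tile with a two-class model, and
#' returns the predicted grid (argmax class) with per-tile class-1
#' probabilities.
#'
#' @param model a two-class `dl_model` with input side equal to the tile
#'   side
#' @param img `H x W x C` image
#' @param source_id identifier stored in the map
#' @param normalizer optional `normalization_spec`
#' @return list: `map` (a [tile_map()]), `probabilities` (`R x C` matrix
#'   of class-1 probabilities)
#' @export
predict_tile_map <- function(model, img, source_id = "img",
                             normalizer = NULL) {
  if (model$spec$n_classes != 2L)
    stop_dc("tile classification expects a 2-class model")
  s <- model$spec$input_side
  pt <- partition_tiles(img, s)
  probs <- predict_proba(model, pt$tiles, normalizer)
  pred <- max.col(probs, ties.method = "first") - 1L
  nr <- pt$grid_dim[1]; nc <- pt$grid_dim[2]
  # tiles are row-major; fill by row
  grid <- matrix(pred, nr, nc, byrow = TRUE)
  pmat <- matrix(probs[, 2], nr, nc, byrow = TRUE)
  list(map = tile_map(grid, s, source_id), probabilities = pmat)
}

#' Ground-truth tile map of a masked image
#' @param masked a [masked_image()]
#' @param tile_side tile side
#' @param min_marked positivity threshold
#' @return a [tile_map()]
#' @export
truth_tile_map <- function(masked, tile_side = 32L, min_marked = 5L) {
  pm <- partition_tiles(masked$mask * 1, tile_side)
  cls <- label_tiles(pm$tiles, min_marked)
  tile_map(matrix(cls, pm$grid_dim[1], pm$grid_dim[2], byrow = TRUE),
           tile_side, masked$source_id)
}

#' Per-image tile-map accuracy
#'
#' Fraction of grid cells on which a predicted and a ground-truth tile map
#' agree; summarize across images with [mean_sd()].
#'
#' @param pred,truth `tile_map` objects with identical grid shape
#' @return agreement fraction in `[0, 1]`
#' @export
per_image_accuracy <- function(pred, truth) {
  stopifnot(inherits(pred, "tile_map"), inherits(truth, "tile_map"))
  if (!all(dim(pred$grid) == dim(truth$grid)))
    stop_dc("grid shapes differ: ", paste(dim(pred$grid), collapse = "x"),
            " vs ", paste(dim(truth$grid), collapse = "x"))
  mean(pred$grid == truth$grid)
}

#' Export a tile map
#'
#' Writes the grid as a CSV matrix and, optionally, a flattened tile table
#' (`source_id, row0, col0, row1, col1, class, probability`) with 0-based
#' half-open pixel coordinates.
#'
#' @param map a [tile_map()]
#' @param path output CSV path for the grid
#' @param table_path optional output path for the flattened tile table
#' @param probabilities optional `R x C` matrix of class-1 probabilities
#' @return `path`, invisibly
#' @export
write_tile_map <- function(map, path, table_path = NULL,
                           probabilities = NULL) {
  utils::write.table(map$grid, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  if (!is.null(table_path)) {
    nr <- nrow(map$grid); nc <- ncol(map$grid); s <- map$tile_side
    r <- rep(seq_len(nr) - 1L, each = nc)
    cc <- rep(seq_len(nc) - 1L, nr)
    tab <- data.frame(source_id = map$source_id,
                      row0 = r * s, col0 = cc * s,
                      row1 = (r + 1L) * s, col1 = (cc + 1L) * s,
                      class = as.integer(t(map$grid)),
                      probability = if (!is.null(probabilities))
                        as.numeric(t(probabilities)) else NA_real_)
    utils::write.csv(tab, table_path, row.names = FALSE)
  }
  invisible(path)
}
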