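# Synthetic fixtures: separable shape classes, stained-culture micrographs
# with ground-truth masks, and single-cell event images with population
# structure in area and brightness.  All generators are pure functions of
# their seed.

shape_families <- c("disk", "square", "cross", "ring", "bar", "triangle")

draw_shape <- function(side, family, cy, cx, size, intensity) {
  r <- matrix(rep(seq_len(side) - 1L, side), side, side)
  c_ <- matrix(rep(seq_len(side) - 1L, each = side), side, side)
  dy <- r - cy; dx <- c_ - cx
  mask <- switch(family,
    disk = dy^2 + dx^2 <= size^2,
    square = abs(dy) <= size & abs(dx) <= size,
    cross = (abs(dy) <= size / 3 & abs(dx) <= size) |
            (abs(dx) <= size / 3 & abs(dy) <= size),
    ring = {
      d2 <- dy^2 + dx^2
      d2 <= size^2 & d2 >= (0.55 * size)^2
    },
    bar = abs(dy) <= size / 3 & abs(dx) <= size,
    triangle = dy >= -size & dy <= size & abs(dx) <= (dy + size) / 2)
  img <- matrix(0, side, side)
  img[mask] <- intensity
  img
}

#' Generate a multi-class shape image set
#'
#' Each class is one shape family (disk, square, cross, ring, bar,
#' triangle) drawn in grayscale with random position, size, and intensity
#' jitter over a noisy dark background — classes a small CNN (and even a
#' nearest-centroid baseline, for the easiest pairs) can separate.
#'
#' @param n_classes number of classes (<= 6)
#' @param n_per_class images per class
#' @param side image side in pixels (>= 16)
#' @param seed generator seed; identical seeds give bit-identical sets
#' @param split split tag
#' @return an `image_set` (`N = n_classes * n_per_class`, 1 channel)
#' @export
make_shapes_dataset <- function(n_classes = 4L, n_per_class = 100L,
                                side = 32L, seed = 1L, split = "train") {
  if (n_classes > length(shape_families))
    stop_dc("at most ", length(shape_families), " shape classes available")
  if (side < 16L) stop_dc("side must be >= 16")
  n <- n_classes * n_per_class
  with_local_seed(derive_seed(seed, 101L), {
    imgs <- array(0, c(n, side, side, 1L))
    labels <- integer(n)
    ids <- character(n)
    i <- 0L
    for (k in seq_len(n_classes) - 1L) for (j in seq_len(n_per_class)) {
      i <- i + 1L
      cy <- (side - 1) / 2 + stats::runif(1, -2, 2)
      cx <- (side - 1) / 2 + stats::runif(1, -2, 2)
      size <- side * stats::runif(1, 0.27, 0.31)
      intensity <- stats::runif(1, 190, 215)
      img <- draw_shape(side, shape_families[k + 1L], cy, cx, size, intensity)
      img <- img + matrix(stats::rnorm(side * side, 0, 6), side, side)
      imgs[i, , , 1] <- clip(round_half_up(img))
      labels[i] <- k
      ids[i] <- sprintf("shape_%s_%04d", shape_families[k + 1L], j)
    }
    image_set(imgs, labels, shape_families[seq_len(n_classes)], ids, split)
  })
}

#' Generate stained-culture micrographs with ground-truth masks
#'
#' Emulates brightfield images of lipid-stained adipocyte cultures:
#' 320 x 320 RGB images whose background tint varies image to image (the
#' dominant nuisance in real stained cultures), with reddish elliptical
#' stained blobs; the mask is true exactly on blob pixels.
#'
#' @param n_images number of images
#' @param blob_count_range integer range of blobs per image
#' @param blob_radius_range pixel range of blob semi-axes
#' @param background_tint_range intensity range of the background base
#'   tint
#' @param side image side (default 320)
#' @param seed generator seed
#' @return list of [masked_image()] objects
#' @export
make_stained_culture <- function(n_images = 10L,
                                 blob_count_range = c(4L, 12L),
                                 blob_radius_range = c(8, 24),
                                 background_tint_range = c(120, 220),
                                 side = 320L, seed = 1L) {
  with_local_seed(derive_seed(seed, 202L), {
    r <- matrix(rep(seq_len(side) - 1L, side), side, side)
    c_ <- matrix(rep(seq_len(side) - 1L, each = side), side, side)
    out <- vector("list", n_images)
    for (i in seq_len(n_images)) {
      tint <- stats::runif(1, background_tint_range[1],
                           background_tint_range[2])
      # warm background with a gentle illumination gradient
      grad <- (r + c_) / (2 * side) * stats::runif(1, -25, 25)
      img <- array(0, c(side, side, 3L))
      img[, , 1] <- tint + grad
      img[, , 2] <- tint * stats::runif(1, 0.88, 1.0) + grad
      img[, , 3] <- tint * stats::runif(1, 0.75, 0.95) + grad
      mask <- matrix(FALSE, side, side)
      n_blobs <- sample(seq(blob_count_range[1], blob_count_range[2]), 1L)
      for (b in seq_len(n_blobs)) {
        cy <- stats::runif(1, 0, side - 1); cx <- stats::runif(1, 0, side - 1)
        ay <- stats::runif(1, blob_radius_range[1], blob_radius_range[2])
        ax <- stats::runif(1, blob_radius_range[1], blob_radius_range[2])
        th <- stats::runif(1, 0, pi)
        dy <- r - cy; dx <- c_ - cx
        u <- cos(th) * dy + sin(th) * dx
        v <- -sin(th) * dy + cos(th) * dx
        bm <- (u / ay)^2 + (v / ax)^2 <= 1
        red <- stats::runif(1, 170, 230)
        img_r <- img[, , 1]; img_g <- img[, , 2]; img_b <- img[, , 3]
        img_r[bm] <- red
        img_g[bm] <- red * stats::runif(1, 0.30, 0.45)
        img_b[bm] <- red * stats::runif(1, 0.35, 0.55)
        img[, , 1] <- img_r; img[, , 2] <- img_g; img[, , 3] <- img_b
        mask <- mask | bm
      }
      img <- img + array(stats::rnorm(side * side * 3, 0, 4),
                         c(side, side, 3L))
      out[[i]] <- masked_image(clip(round_half_up(img)), mask,
                               sprintf("culture_%03d", i))
    }
    out
  })
}

#' Cell-population specification
#'
#' Gaussian population model for single-cell event images: cross-sectional
#' area (pixels squared) and mean brightness (intensity units) are each
#' normal, with a relative abundance.
#'
#' @param name population name
#' @param area_mean,area_sd area distribution in pixels squared
#' @param brightness_mean,brightness_sd brightness distribution in
#'   intensity units
#' @param abundance relative frequency; abundances of all populations of a
#'   run must sum to 1
#' @return object of class `population_spec`
#' @export
population_spec <- function(name, area_mean, area_sd,
                            brightness_mean, brightness_sd, abundance) {
  if (area_sd <= 0 || brightness_sd <= 0) stop_dc("sds must be > 0")
  structure(list(name = name, area_mean = area_mean, area_sd = area_sd,
                 brightness_mean = brightness_mean,
                 brightness_sd = brightness_sd, abundance = abundance),
            class = "population_spec")
}

#' Generate single-cell event images from population specs
#'
#' Each event is one cell: a disk whose area is drawn from the
#' population's area distribution and whose interior intensity is drawn
#' from its brightness distribution, placed near the center of a fixed
#' dark background crop (the per-cell region of interest of an imaging
#' flow cytometer). The truth label is the population index.
#'
#' @param populations list of [population_spec()] (abundances sum to 1)
#' @param n_events number of cells to generate
#' @param image_side crop side in pixels
#' @param background background intensity
#' @param seed generator seed
#' @return list: `events` (an `image_set`), `masks` (`N x side x side`
#'   logical array of cell pixels), `features` (data frame `event_id`,
#'   `area`, `brightness`, `truth_label`)
#' @export
make_cell_events <- function(populations, n_events = 500L, image_side = 48L,
                             background = 30, seed = 1L) {
  ab <- vapply(populations, `[[`, numeric(1), "abundance")
  if (abs(sum(ab) - 1) > 1e-8) stop_dc("abundances must sum to 1")
  # warn when ±1 sd feature boxes overlap (gating would mislabel)
  if (length(populations) > 1L) {
    for (i in seq_along(populations)) for (j in seq_along(populations)) {
      if (i >= j) next
      a <- populations[[i]]; b <- populations[[j]]
      overlap <- function(m1, s1, m2, s2) (m1 + s1) >= (m2 - s2) &&
                                          (m2 + s2) >= (m1 - s1)
      if (overlap(a$area_mean, a$area_sd, b$area_mean, b$area_sd) &&
          overlap(a$brightness_mean, a$brightness_sd,
                  b$brightness_mean, b$brightness_sd))
        warn_dc("populations '", a$name, "' and '", b$name,
                "' overlap within ±1 sd; gating will mislabel events")
    }
  }
  with_local_seed(derive_seed(seed, 303L), {
    side <- as.integer(image_side)
    imgs <- array(0, c(n_events, side, side, 1L))
    masks <- array(FALSE, c(n_events, side, side))
    labels <- integer(n_events)
    area <- bright <- numeric(n_events)
    r <- matrix(rep(seq_len(side) - 1L, side), side, side)
    c_ <- matrix(rep(seq_len(side) - 1L, each = side), side, side)
    pop_draw <- sample.int(length(populations), n_events, replace = TRUE,
                           prob = ab)
    for (i in seq_len(n_events)) {
      p <- populations[[pop_draw[i]]]
      a_target <- max(stats::rnorm(1, p$area_mean, p$area_sd), 4)
      radius <- sqrt(a_target / pi)
      cy <- (side - 1) / 2 + stats::runif(1, -2, 2)
      cx <- (side - 1) / 2 + stats::runif(1, -2, 2)
      cell <- (r - cy)^2 + (c_ - cx)^2 <= radius^2
      level <- clip(stats::rnorm(1, p$brightness_mean, p$brightness_sd))
      img <- matrix(background, side, side)
      img[cell] <- level
      img <- img + matrix(stats::rnorm(side * side, 0, 2), side, side)
      imgs[i, , , 1] <- clip(round_half_up(img))
      masks[i, , ] <- cell
      labels[i] <- pop_draw[i] - 1L
      area[i] <- sum(cell)
      bright[i] <- mean(imgs[i, , , 1][cell])
    }
    names_k <- vapply(populations, `[[`, character(1), "name")
    list(events = image_set(imgs, labels, names_k,
                            sprintf("event_%05d", seq_len(n_events))),
         masks = masks,
         features = data.frame(event_id = sprintf("event_%05d",
                                                  seq_len(n_events)),
                               area = area, brightness = bright,
                               truth_label = labels))
  })
}

#' Area and brightness of one cell event
#'
#' The standard imaging-flow-cytometry features: cross-sectional area is
#' the marked-pixel count; brightness is the mean grayscale value of all
#' pixels belonging to the cell.
#'
#' @param image `H x W` matrix or `H x W x 1` array
#' @param cell_mask `H x W` logical matrix, non-empty
#' @return named numeric vector `c(area =, brightness =)`
#' @export
event_features <- function(image, cell_mask) {
  if (length(dim(image)) == 3L) image <- image[, , 1]
  if (!any(cell_mask)) stop_dc("empty cell mask")
  c(area = sum(cell_mask), brightness = mean(image[cell_mask]))
}

#' Rectangular feature gate
#'
#' Half-open rectangle in the area x brightness plane:
#' `lo <= value < hi` on both axes.
#' @param area_range,brightness_range length-2 `(lo, hi)` with `lo < hi`
#' @return object of class `feature_gate`
#' @export
feature_gate <- function(area_range, brightness_range) {
  if (area_range[1] >= area_range[2] ||
      brightness_range[1] >= brightness_range[2])
    stop_dc("gate ranges need lo < hi")
  structure(list(area_range = as.numeric(area_range),
                 brightness_range = as.numeric(brightness_range)),
            class = "feature_gate")
}

#' Select events inside a rectangular gate
#'
#' @param features data frame with `area` and `brightness` columns (as
#'   from [make_cell_events()] or [event_features()])
#' @param gate a [feature_gate()]
#' @return integer vector of selected (1-based) row indices
#' @export
apply_gate <- function(features, gate) {
  stopifnot(inherits(gate, "feature_gate"))
  which(features$area >= gate$area_range[1] &
        features$area < gate$area_range[2] &
        features$brightness >= gate$brightness_range[1] &
        features$brightness < gate$brightness_range[2])
}

#' Write a cell-event feature table as CSV
#' @param features data frame from [make_cell_events()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_feature_table <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}
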