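test_that("pure-green overlays decode to exact pixel masks", {
  img <- array(100, c(10, 10, 3))
  img[2, 3, ] <- c(0, 255, 0)
  img[5, 5, ] <- c(0, 255, 0)
  img[7, 7, ] <- c(0, 254, 0)         # near-green must not match
  m <- decode_mask(img)
  expect_equal(sum(m$mask), 2L)
  expect_true(m$mask[2, 3] && m$mask[5, 5])
  expect_false(m$mask[7, 7])

  all_green <- array(rep(c(0, 255, 0), each = 16), c(4, 4, 3))
  expect_true(all(decode_mask(all_green)$mask))
  none <- decode_mask(array(10, c(4, 4, 3)))
  expect_false(any(none$mask))
})

test_that("tile partition yields floor(H/s)*floor(W/s) tiles in row-major order", {
  img <- matrix(seq_len(320 * 320), 320, 320)
  pt <- partition_tiles(img, 32)
  expect_equal(dim(pt$tiles)[1], 100L)
  expect_equal(pt$grid_dim, c(10L, 10L))
  # row-major: second tile starts at column 32
  expect_equal(pt$offsets[2, ], data.frame(row0 = 0L, col0 = 32L),
               ignore_attr = TRUE)
  expect_equal(pt$tiles[2, , , 1], img[1:32, 33:64])

  one <- partition_tiles(matrix(7, 32, 32), 32)
  expect_equal(dim(one$tiles)[1], 1L)
  expect_equal(one$tiles[1, , , 1], matrix(7, 32, 32))

  expect_warning(four <- partition_tiles(matrix(0, 70, 70), 32), "border")
  expect_equal(dim(four$tiles)[1], 4L)
  expect_error(partition_tiles(matrix(0, 20, 20), 32), "exceeds")
})

test_that("tiles reassemble into the cropped source image", {
  set.seed(6)
  img <- matrix(sample(0:255, 70 * 70, TRUE), 70, 70)
  suppressWarnings(pt <- partition_tiles(img, 32))
  rebuilt <- matrix(0, 64, 64)
  for (i in seq_len(4)) {
    r0 <- pt$offsets$row0[i]; c0 <- pt$offsets$col0[i]
    rebuilt[r0 + 1:32, c0 + 1:32] <- pt$tiles[i, , , 1]
  }
  expect_equal(rebuilt, img[1:64, 1:64])
})

test_that("tile labeling uses the >= 5 marked-pixel rule", {
  mk <- function(n_marked) {
    m <- matrix(0, 32, 32)
    if (n_marked > 0) m[seq_len(n_marked)] <- 1
    array(m, c(1, 32, 32, 1))
  }
  expect_equal(label_tiles(mk(4)), 0L)
  expect_equal(label_tiles(mk(5)), 1L)
  expect_equal(label_tiles(mk(0)), 0L)
  # monotone: adding marked pixels never flips 1 -> 0
  set.seed(3)
  base <- matrix(runif(32 * 32) < 0.01, 32, 32)
  more <- base; more[1:10, 1] <- TRUE
  l1 <- label_tiles(array(base, c(1, 32, 32, 1)))
  l2 <- label_tiles(array(more, c(1, 32, 32, 1)))
  expect_gte(l2, l1)
})

test_that("positive-tile oversampling draws valid in-bounds positive tiles", {
  side <- 64L
  mask <- square_blob_mask(side, at = c(20L, 30L), blob = 4L)  # 16 pixels
  img <- array(50, c(side, side, 3L))
  mi <- masked_image(img, mask, "fix")
  set.seed(12)
  ex <- oversample_positive_tiles(mi, 20L, 16L)
  expect_equal(dim(ex$tiles)[1], 20L)
  for (i in 1:20) {
    r0 <- ex$offsets$row0[i]; c0 <- ex$offsets$col0[i]
    expect_true(r0 >= 0 && r0 + 16 <= side && c0 >= 0 && c0 + 16 <= side)
    expect_gte(sum(mask[r0 + 1:16, c0 + 1:16]), 5)
  }
  expect_gte(length(unique(paste(ex$offsets$row0, ex$offsets$col0))), 2L)

  empty <- masked_image(img, matrix(FALSE, side, side))
  expect_error(oversample_positive_tiles(empty, 5L, 16L), "fewer than")
  # sparse mask exhausts the budget and warns
  sparse <- masked_image(img, square_blob_mask(side, c(1L, 1L), 3L))
  expect_warning(
    few <- oversample_positive_tiles(sparse, 50L, 16L, max_attempts = 30L),
    "budget")
  expect_lt(dim(few$tiles)[1], 50L)
})

test_that("tile datasets compose grid labels with balancing oversampling", {
  side <- 320L
  blank <- masked_image(array(10, c(side, side, 3L)),
                        matrix(FALSE, side, side), "blank")
  tiles <- build_tile_dataset(list(blank), 32, 5, "none")
  expect_equal(n_images(tiles), 100L)
  expect_true(all(tiles$labels == 0L))
  expect_equal(tiles$class_names, c("0", "1"))

  blob <- masked_image(array(10, c(side, side, 3L)),
                       square_blob_mask(side, c(40L, 40L), 20L), "blob")
  set.seed(5)
  bal <- build_tile_dataset(list(blank, blob), 32, 5, "balance")
  expect_equal(sum(bal$labels == 0L), sum(bal$labels == 1L))
  # provenance ids parse back to recoverable offsets
  parsed <- parse_tile_ids(bal$source_ids)
  expect_true(all(parsed$row0 >= 0 & parsed$row0 <= side - 32))
  expect_true(all(parsed$source_id %in% c("blank", "blob")))
})

test_that("predicted tile maps have the right shape and constant-model behavior", {
  img <- array(runif(320 * 320 * 1, 0, 255), c(320, 320, 1))
  m <- build_model("mlp_128", 32, 1, 2, seed = 1)
  # force a constant class-0 predictor: zero last layer, bias toward class 0
  pls <- deepclass:::parameterized_layers(m)
  out_l <- deepclass:::get_player(m, pls[[2]]$path)
  out_l$W[] <- 0; out_l$b <- c(5, 0)
  m <- deepclass:::set_player(m, pls[[2]]$path, out_l)
  pm <- predict_tile_map(m, img)
  expect_equal(dim(pm$map$grid), c(10L, 10L))
  expect_true(all(pm$map$grid == 0L))
  expect_true(all(pm$probabilities < 0.5))

  truth <- tile_map(matrix(0L, 10, 10), 32)
  expect_equal(per_image_accuracy(pm$map, truth), 1)
  one_off <- truth; one_off$grid[4, 7] <- 1L
  expect_equal(per_image_accuracy(pm$map, one_off), 0.99)
  flipped <- truth; flipped$grid[] <- 1L
  expect_equal(per_image_accuracy(pm$map, flipped), 0)
  small <- tile_map(matrix(0L, 5, 5), 32)
  expect_error(per_image_accuracy(pm$map, small), "shapes differ")
})

test_that("ground-truth maps and tile-table export agree with the mask", {
  side <- 64L
  mi <- masked_image(array(0, c(side, side, 3L)),
                     square_blob_mask(side, c(4L, 4L), 10L), "x")
  tm <- truth_tile_map(mi, 32, 5)
  expect_equal(dim(tm$grid), c(2L, 2L))
  expect_equal(tm$grid[1, 1], 1L)         # blob sits in the first tile
  expect_equal(sum(tm$grid), 1L)
  g <- tempfile(fileext = ".csv"); tb <- tempfile(fileext = ".csv")
  on.exit(unlink(c(g, tb)))
  write_tile_map(tm, g, tb, matrix(0.5, 2, 2))
  tab <- read.csv(tb)
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$row1 - tab$row0, rep(32L, 4))
  expect_equal(tab$class[1], 1L)
})
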