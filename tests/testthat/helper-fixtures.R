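# Fixtures built in code at test time.

`%||%` <- function(a, b) if (is.null(a)) b else a

# write a one-subdir-per-class PNG folder; images constant-valued per class
make_png_folder <- function(root, classes = c("a", "b"), n_per_class = 3L,
                            side = 8L) {
  for (k in seq_along(classes)) {
    d <- file.path(root, classes[k])
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    for (j in seq_len(n_per_class)) {
      img <- matrix((k * 40 + j) / 255, side, side)
      png::writePNG(img, file.path(d, sprintf("img%02d.png", j)))
    }
  }
  root
}

# tiny labeled image set with a known geometry
tiny_imageset <- function(n = 8L, side = 8L, k = 2L, channels = 1L,
                          seed = 1L) {
  set.seed(seed)
  imgs <- array(sample(0:255, n * side * side * channels, replace = TRUE),
                c(n, side, side, channels))
  image_set(imgs, rep_len(seq_len(k) - 1L, n), letters[seq_len(k)])
}

# deterministic mask with one solid square blob
square_blob_mask <- function(side = 64L, at = c(10L, 10L), blob = 6L) {
  m <- matrix(FALSE, side, side)
  m[at[1] + seq_len(blob), at[2] + seq_len(blob)] <- TRUE
  m
}

# a linear scorer turned into fake probabilities for metric tests
random_predictions <- function(n, k, seed) {
  set.seed(seed)
  p <- matrix(stats::runif(n * k), n, k)
  p <- p / rowSums(p)
  list(truth = sample(0:(k - 1L), n, replace = TRUE), probs = p)
}
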