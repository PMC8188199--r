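#' Intensity normalization specification
#'
#' Three methods are supported: `div255` maps 8-bit intensities to
#' `[0, 1]`; `dataset_standard` standardizes by the mean and SD of all
#' pixels of the *training* set (population moments, fitted once with
#' [fit_normalizer()] and then frozen); `per_image_standard` standardizes
#' each image by its own mean and SD.
#'
#' @param method one of `"div255"`, `"dataset_standard"`,
#'   `"per_image_standard"`
#' @param fitted_mean,fitted_sd training-set pixel moments; required (and
#'   only meaningful) for `dataset_standard`
#' @return object of class `normalization_spec`
#' @export
normalization_spec <- function(method = c("div255", "dataset_standard",
                                          "per_image_standard"),
                               fitted_mean = NULL, fitted_sd = NULL) {
  method <- match.arg(method)
  if (method == "dataset_standard" && !is.null(fitted_sd) && fitted_sd <= 0)
    stop_dc("fitted_sd must be > 0")
  structure(list(method = method, fitted_mean = fitted_mean,
                 fitted_sd = fitted_sd),
            class = "normalization_spec")
}

#' Fit a normalizer on a training set
#'
#' For `dataset_standard` the mean and SD are computed over every pixel of
#' the training images (population SD, `1/n` denominator). The returned
#' spec is self-contained: applying it to validation or test data never
#' touches their statistics.
#'
#' @param train an `image_set` (training split)
#' @param method see [normalization_spec()]
#' @return a fitted `normalization_spec`
#' @export
fit_normalizer <- function(train, method = c("div255", "dataset_standard",
                                             "per_image_standard")) {
  method <- match.arg(method)
  if (method != "dataset_standard") return(normalization_spec(method))
  x <- as.numeric(train$images)
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) { warn_dc("constant training set; using sd = 1"); s <- 1 }
  normalization_spec("dataset_standard", fitted_mean = m, fitted_sd = s)
}

#' Apply a fitted normalizer to images
#'
#' @param x image array (`H x W x C` or `N x H x W x C`) of 8-bit
#'   intensities
#' @param spec a `normalization_spec` from [fit_normalizer()]
#' @return real-valued array of the same shape
#' @export
apply_normalizer <- function(x, spec) {
  stopifnot(inherits(spec, "normalization_spec"))
  single <- length(dim(x)) == 3L
  if (single) dim(x) <- c(1L, dim(x))
  out <- switch(spec$method,
    div255 = x / 255,
    dataset_standard = {
      if (is.null(spec$fitted_mean) || is.null(spec$fitted_sd))
        stop_dc("dataset_standard spec was not fitted; call fit_normalizer() on the training set")
      (x - spec$fitted_mean) / spec$fitted_sd
    },
    per_image_standard = {
      n <- dim(x)[1]
      flat <- matrix(x, nrow = n)   # N images x pixels (dim 1 is fastest? no)
      # dim(x) = (N,H,W,C): element (i, ...) stride — flatten keeps N fastest,
      # so matrix(x, nrow = n) puts image i in row i.
      m <- rowMeans(flat)
      s <- sqrt(rowMeans((flat - m)^2))
      zero <- s == 0
      if (any(zero)) {
        warn_dc(sum(zero), " constant image(s): using sd = 1")
        s[zero] <- 1
      }
      array((flat - m) / s, dim(x))
    })
  if (single) {
    d <- dim(out)
    out <- array(out, d[2:4])
  }
  out
}
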