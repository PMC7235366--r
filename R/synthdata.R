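#' Configuration for the synthetic labeled-image generator
#'
#' Describes a balanced K-class set of small square RGB images. Each class is
#' defined by a deterministic low-frequency spatial template (a short random
#' Fourier series per channel, fixed by `seed`); images are the template plus
#' optional integer-pixel translation jitter and i.i.d. Gaussian pixel noise,
#' clipped to `[0, 1]`. The generator stands in for small natural-image
#' benchmarks (10-class, balanced, pixel values normalized to `[0, 1]`) so
#' the whole pipeline runs at desk scale.
#'
#' @param image_side Side length in pixels (square images). Default 16.
#' @param channels Number of color channels. Default 3.
#' @param num_classes Number of classes K (>= 2). Default 10.
#' @param per_class_count Images per class in each split. Default 100.
#' @param template_contrast Peak-to-peak amplitude of the class template on
#'   the `[0, 1]` intensity scale, in (0, 1]. Default 0.9.
#' @param pixel_noise_sd Standard deviation of additive Gaussian pixel noise
#'   applied at generation time (>= 0). Default 0.05.
#' @param jitter_pixels Maximum absolute circular translation, in pixels,
#'   applied independently per axis (>= 0). Default 1.
#' @param seed Integer seed; identical configs (including seed) produce
#'   byte-identical datasets.
#'
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(image_side = 16, channels = 3, num_classes = 10,
                         per_class_count = 100, template_contrast = 0.9,
                         pixel_noise_sd = 0.05, jitter_pixels = 1,
                         seed = 1L) {
  if (num_classes < 2) stop("num_classes must be >= 2")
  if (per_class_count < 1) stop("per_class_count must be >= 1")
  if (image_side < 4) stop("image_side must be >= 4")
  if (channels < 1) stop("channels must be >= 1")
  if (template_contrast <= 0 || template_contrast > 1)
    stop("template_contrast must be in (0, 1]")
  if (pixel_noise_sd < 0) stop("pixel_noise_sd must be >= 0")
  if (jitter_pixels < 0) stop("jitter_pixels must be >= 0")
  structure(list(
    image_side = as.integer(image_side), channels = as.integer(channels),
    num_classes = as.integer(num_classes),
    per_class_count = as.integer(per_class_count),
    template_contrast = template_contrast, pixel_noise_sd = pixel_noise_sd,
    jitter_pixels = as.integer(jitter_pixels), seed = as.integer(seed)
  ), class = "synth_config")
}

new_image_set <- function(images, labels, split_name, seed, ids = NULL) {
  n <- dim(images)[1]
  if (is.null(ids)) ids <- seq_len(n)
  structure(list(images = images, labels = as.integer(labels),
                 split_name = split_name, seed = as.integer(seed),
                 ids = as.integer(ids)),
            class = "labeled_image_set")
}

#' @export
print.labeled_image_set <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<labeled_image_set '%s': %d images %dx%dx%d, %d classes>\n",
              x$split_name, d[1], d[2], d[3], d[4],
              length(unique(x$labels))))
  invisible(x)
}

n_images <- function(data) dim(data$images)[1]

#' Class templates for a synthetic configuration
#'
#' One smooth spatial pattern per class and channel: a sum of four
#' low-frequency cosines with seeded random frequencies, orientations and
#' phases, rescaled so each class template spans
#' `0.5 +/- template_contrast/2` on the intensity scale.
#'
#' @param config A [synth_config()].
#' @return Array `K x side x side x channels` of noiseless class images.
#' @export
class_templates <- function(config) {
  s <- config$image_side
  K <- config$num_classes
  C <- config$channels
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  u <- matrix(rep(seq_len(s), s), s, s)         # row coordinate
  v <- t(u)                                     # column coordinate
  tpl <- array(0, dim = c(K, s, s, C))
  for (k in seq_len(K)) {
    base <- matrix(0, s, s)
    for (j in 1:4) {
      fx <- sample(0:2, 1)
      fy <- sample(0:2, 1)
      if (fx == 0 && fy == 0) fx <- 1
      ph <- stats::runif(1, 0, 2 * pi)
      amp <- stats::runif(1, 0.5, 1)
      base <- base + amp * cos(2 * pi * (fx * u + fy * v) / s + ph)
    }
    rng <- range(base)
    base <- (base - rng[1]) / (rng[2] - rng[1]) - 0.5   # [-0.5, 0.5]
    for (ch in seq_len(C)) {
      gain <- stats::runif(1, 0.6, 1)
      tpl[k, , , ch] <- 0.5 + config$template_contrast * gain * base
    }
  }
  tpl
}

# Save/restore the global RNG state so generators are pure in (config, seed)
# without clobbering the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

circ_shift <- function(m, dr, dc) {
  s <- nrow(m)
  if (dr != 0) m <- m[((seq_len(s) - 1 - dr) %% s) + 1, , drop = FALSE]
  if (dc != 0) m <- m[, ((seq_len(s) - 1 - dc) %% s) + 1, drop = FALSE]
  m
}

generate_split <- function(config, tpl, split_name, seed) {
  s <- config$image_side; C <- config$channels
  K <- config$num_classes; m <- config$per_class_count
  n <- K * m
  set.seed(seed)
  labels <- rep(0:(K - 1), each = m)
  images <- array(0, dim = c(n, s, s, C))
  for (i in seq_len(n)) {
    k <- labels[i] + 1L
    dr <- dc <- 0L
    if (config$jitter_pixels > 0) {
      dr <- sample(seq(-config$jitter_pixels, config$jitter_pixels), 1)
      dc <- sample(seq(-config$jitter_pixels, config$jitter_pixels), 1)
    }
    for (ch in seq_len(C)) {
      img <- circ_shift(tpl[k, , , ch], dr, dc)
      if (config$pixel_noise_sd > 0)
        img <- img + stats::rnorm(s * s, sd = config$pixel_noise_sd)
      images[i, , , ch] <- pmin(pmax(img, 0), 1)
    }
  }
  new_image_set(images, labels, split_name, seed)
}

#' Generate a balanced synthetic labeled-image dataset
#'
#' Produces disjoint train and test splits (independent draws of jitter and
#' pixel noise around the same class templates), each with exactly
#' `per_class_count` images per class, all pixels in `[0, 1]`. Deterministic
#' in the config, including its seed.
#'
#' @param config A [synth_config()].
#' @return List with elements `train` and `test` (each a `labeled_image_set`),
#'   `templates` (from [class_templates()]), and `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  tpl <- class_templates(config)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  train <- generate_split(config, tpl, "train", config$seed + 1000L)
  test <- generate_split(config, tpl, "test", config$seed + 2000L)
  list(train = train, test = test, templates = tpl, config = config)
}

#' Add Gaussian pixel noise to an image set
#'
#' Adds i.i.d. Gaussian noise with mean 0 and standard deviation `sigma` to
#' every pixel. The result is deliberately NOT re-clipped to `[0, 1]`:
#' clipping would truncate the noise distribution and the analyses assume an
#' exact Gaussian perturbation of normalized images.
#'
#' @param data A `labeled_image_set` with pixels in `[0, 1]`.
#' @param sigma Noise standard deviation (>= 0).
#' @param seed Integer seed for the noise draw.
#' @return A new `labeled_image_set`; labels and stimulus ids unchanged.
#' @export
add_gaussian_noise <- function(data, sigma, seed = 1L) {
  stopifnot(inherits(data, "labeled_image_set"))
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(data)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  noisy <- data$images +
    array(stats::rnorm(length(data$images), sd = sigma), dim = dim(data$images))
  new_image_set(noisy, data$labels, paste0(data$split_name, "+noise"),
                seed, ids = data$ids)
}

#' Subsample stimuli without replacement
#'
#' Uniform sampling without replacement from the set (optionally restricted
#' to `restrict_to` row positions), deterministic given `seed`. Stimulus ids
#' are carried along so downstream row alignment survives resampling.
#'
#' @param data A `labeled_image_set`.
#' @param size Number of stimuli to draw (0 allowed; a warning flags it).
#' @param seed Integer seed.
#' @param restrict_to Optional integer vector of row positions forming the
#'   sampling pool.
#' @return A `labeled_image_set` of `size` stimuli.
#' @export
subsample_stimuli <- function(data, size, seed = 1L, restrict_to = NULL) {
  stopifnot(inherits(data, "labeled_image_set"))
  pool <- if (is.null(restrict_to)) seq_len(n_images(data))
          else as.integer(restrict_to)
  if (size > length(pool)) stop("size exceeds sampling pool")
  if (size == 0) warning("subsample of size 0 requested")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  idx <- if (size == 0) integer(0) else sample(pool, size)
  new_image_set(data$images[idx, , , , drop = FALSE], data$labels[idx],
                data$split_name, seed, ids = data$ids[idx])
}

#' Nearest-template oracle accuracy
#'
#' Classifies each image by the class template with minimum Euclidean pixel
#' distance. A generator diagnostic: with full contrast and low noise this
#' oracle must be perfect, and its accuracy is non-increasing in the noise
#' level.
#'
#' @param data A `labeled_image_set`.
#' @param templates Array from [class_templates()].
#' @return Fraction of images assigned to their true class.
#' @export
nearest_template_accuracy <- function(data, templates) {
  K <- dim(templates)[1]
  n <- n_images(data)
  X <- matrix(data$images, nrow = n)               # n x (s*s*C)
  Tm <- matrix(templates, nrow = K)                # K x (s*s*C)
  # squared distances via expansion; n and K are small
  d2 <- outer(rowSums(X^2), rep(1, K)) - 2 * X %*% t(Tm) +
    outer(rep(1, n), rowSums(Tm^2))
  pred <- max.col(-d2, ties.method = "first") - 1L
  mean(pred == data$labels)
}
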