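#' Write a labeled image set as PNG files with a CSV manifest
#'
#' The on-disk layout is a directory of one PNG per stimulus plus
#' `manifest.csv` with columns `filename`, `label`, `split`, `id`. Pixel
#' values are clamped to `[0, 1]` on write (PNG cannot represent values
#' outside it, so noise-perturbed sets are better kept in memory or exported
#' via [write_representation()]-style CSVs).
#'
#' @param data A `labeled_image_set`.
#' @param dir Target directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
write_image_set <- function(data, dir) {
  stopifnot(inherits(data, "labeled_image_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- n_images(data)
  fnames <- sprintf("img_%05d.png", data$ids)
  for (i in seq_len(n)) {
    img <- data$images[i, , , ]
    png::writePNG(pmin(pmax(img, 0), 1), file.path(dir, fnames[i]))
  }
  manifest <- data.frame(filename = fnames, label = data$labels,
                         split = data$split_name, id = data$ids)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(file.path(dir, "manifest.csv"))
}

#' Read a labeled image set from a PNG directory with a CSV manifest
#'
#' Inverse of [write_image_set()]; also reads externally supplied image
#' directories in the same layout.
#'
#' @param dir Directory containing `manifest.csv` and the PNG files.
#' @return A `labeled_image_set`.
#' @export
read_image_set <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath)) stop(sprintf("no manifest.csv under '%s'", dir))
  manifest <- utils::read.csv(mpath)
  first <- png::readPNG(file.path(dir, manifest$filename[1]))
  d <- dim(first)
  images <- array(0, dim = c(nrow(manifest), d[1], d[2], d[3]))
  for (i in seq_len(nrow(manifest)))
    images[i, , , ] <- png::readPNG(file.path(dir, manifest$filename[i]))
  new_image_set(images, manifest$label, manifest$split[1],
                seed = 0L, ids = manifest$id)
}

#' Save a trained network checkpoint
#'
#' Stores parameters, architecture tokens, input shape and seed in a single
#' RDS file, and a human-readable JSON summary (tokens, M, N, seed, test
#' accuracy) alongside it.
#'
#' @param net A `trained_network`.
#' @param path Checkpoint path (`.rds`).
#' @return Invisibly, `path`.
#' @export
save_network <- function(net, path) {
  stopifnot(inherits(net, "trained_network"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(list(tokens = net$arch$tokens,
               input_shape = unname(net$arch$input_shape),
               num_classes = net$arch$N, params = net$params,
               seed = net$seed, test_accuracy = net$test_accuracy,
               log = net$log), path)
  jsonlite::write_json(
    list(tokens = net$arch$tokens, M = net$arch$M, N = net$arch$N,
         seed = net$seed, test_accuracy = net$test_accuracy),
    paste0(sub("\\.rds$", "", path), "_summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a trained network checkpoint
#'
#' @param path Path written by [save_network()].
#' @return A `trained_network` (architecture indices rebuilt from tokens).
#' @export
load_network <- function(path) {
  ck <- readRDS(path)
  arch <- parse_architecture(ck$tokens, ck$input_shape, ck$num_classes)
  structure(list(arch = arch, params = ck$params, seed = ck$seed,
                 test_accuracy = ck$test_accuracy, log = ck$log),
            class = "trained_network")
}

#' Write a representation matrix as CSV
#'
#' One row per stimulus: `stimulus_id` followed by the M neuron activations.
#'
#' @param rep Representation matrix with stimulus ids.
#' @param path Target CSV path.
#' @return Invisibly, `path`.
#' @export
write_representation <- function(rep, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  df <- data.frame(stimulus_id = rep_ids(rep), rep)
  names(df)[-1] <- sprintf("n%03d", seq_len(ncol(rep)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a representation matrix written by [write_representation()]
#'
#' @param path CSV path.
#' @return Matrix with `stimulus_ids` attribute restored.
#' @export
read_representation <- function(path) {
  df <- utils::read.csv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- NULL
  attr(m, "stimulus_ids") <- df$stimulus_id
  m
}
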