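#' Parse a network architecture from the configuration grammar
#'
#' Tokens are drawn from a small grammar of column-style CNN configurations:
#' `Conv<k>-<c>` or `Conv<k>-bn-<c>` (k x k convolution, k in {3, 5}, same
#' padding, c output channels; `bn` inserts batch normalization between the
#' convolution and the ReLU), `Max-pool` (2 x 2, stride 2), and `Fc-<u>`
#' (fully connected with u units, ReLU when hidden). The final token must be
#' the `Fc` classification head with `num_classes` units; the width of the
#' layer feeding it is the penultimate width M.
#'
#' @param tokens Character vector of layer tokens, e.g.
#'   `c("Conv5-32", "Max-pool", "Conv5-32", "Max-pool", "Conv5-64",
#'      "Max-pool", "Fc-64", "Fc-10")`.
#' @param input_shape Integer vector `c(side, side, channels)`.
#' @param num_classes Number of output classes N.
#' @return An `architecture_spec`: layer descriptors with resolved shapes,
#'   plus `M` (penultimate width) and `N`.
#' @export
parse_architecture <- function(tokens, input_shape = c(16, 16, 3),
                               num_classes = 10) {
  stopifnot(length(input_shape) == 3, input_shape[1] == input_shape[2])
  H <- as.integer(input_shape[1]); W <- H; C <- as.integer(input_shape[3])
  N <- as.integer(num_classes)
  layers <- list()
  seen_fc <- FALSE
  for (tok in tokens) {
    if (grepl("^Conv", tok)) {
      m <- regmatches(tok, regexec("^Conv([0-9]+)(-bn)?-([0-9]+)$", tok))[[1]]
      if (length(m) == 0)
        stop(sprintf("unparseable token '%s'", tok))
      k <- as.integer(m[2])
      if (!k %in% c(3L, 5L))
        stop(sprintf("token '%s': kernel size %d outside grammar {3, 5}",
                     tok, k))
      if (seen_fc)
        stop(sprintf("token '%s': convolution after a fully connected layer",
                     tok))
      cout <- as.integer(m[4])
      layers[[length(layers) + 1]] <- list(
        type = "conv", token = tok, k = k, bn = m[3] == "-bn",
        cin = C, cout = cout, H = H, W = W,
        idx = conv_indices(H, W, k))
      C <- cout
    } else if (tok == "Max-pool") {
      if (seen_fc)
        stop(sprintf("token '%s': pooling after a fully connected layer", tok))
      if (H < 2 || H %% 2 != 0)
        stop(sprintf("token '%s': spatial size %d cannot be pooled 2x2",
                     tok, H))
      layers[[length(layers) + 1]] <- list(
        type = "pool", token = tok, cin = C, Hin = H, Win = W,
        Hout = H %/% 2L, Wout = W %/% 2L, idx = pool_indices(H, W))
      H <- H %/% 2L; W <- W %/% 2L
    } else if (grepl("^Fc-", tok)) {
      m <- regmatches(tok, regexec("^Fc-([0-9]+)$", tok))[[1]]
      if (length(m) == 0) stop(sprintf("unparseable token '%s'", tok))
      u <- as.integer(m[2])
      if (!seen_fc) {
        layers[[length(layers) + 1]] <- list(
          type = "flatten", token = "(flatten)", H = H, W = W, C = C)
        din <- H * W * C
      } else {
        din <- layers[[length(layers)]]$dout
      }
      layers[[length(layers) + 1]] <- list(
        type = "fc", token = tok, din = din, dout = u)
      seen_fc <- TRUE
    } else {
      stop(sprintf("unknown token '%s'", tok))
    }
  }
  if (length(layers) == 0 || layers[[length(layers)]]$type != "fc")
    stop("architecture must end with an Fc head")
  head <- layers[[length(layers)]]
  if (head$dout != N)
    stop(sprintf("final token '%s' has %d units but num_classes = %d",
                 head$token, head$dout, N))
  # hidden fc layers get a ReLU; the head does not
  for (i in seq_along(layers))
    if (layers[[i]]$type == "fc")
      layers[[i]]$hidden <- i < length(layers)
  structure(list(tokens = tokens, input_shape = c(H0 = input_shape[1],
                                                  W0 = input_shape[2],
                                                  C0 = input_shape[3]),
                 layers = layers, M = head$din, N = N),
            class = "architecture_spec")
}

#' @export
print.architecture_spec <- function(x, ...) {
  cat(sprintf("<architecture_spec: %s | M = %d, N = %d>\n",
              paste(x$tokens, collapse = " "), x$M, x$N))
  invisible(x)
}

# Precomputed gather indices for same-padding im2col convolution on an
# H x W grid (positions column-major: pos = (col-1)*H + row).
conv_indices <- function(H, W, k) {
  p <- (k - 1L) %/% 2L
  Hp <- H + 2L * p; Wp <- W + 2L * p
  r <- rep(seq_len(H), W)
  cc <- rep(seq_len(W), each = H)
  P <- H * W
  nbr <- matrix(0L, P, k * k)
  o <- 0L
  for (dc in -p:p) for (dr in -p:p) {
    o <- o + 1L
    nbr[, o] <- (cc + p + dc - 1L) * Hp + (r + p + dr)
  }
  inner <- (cc + p - 1L) * Hp + (r + p)
  list(nbr = nbr, inner = inner, P = P, Pp = Hp * Wp, p = p)
}

pool_indices <- function(H, W) {
  Ho <- H %/% 2L; Wo <- W %/% 2L
  r2 <- rep(seq_len(Ho), Wo)
  c2 <- rep(seq_len(Wo), each = Ho)
  base <- (2L * c2 - 2L) * H + (2L * r2 - 1L)
  cbind(base, base + 1L, base + H, base + H + 1L)
}

# expand a per-image position index to a batch of B images
batch_idx <- function(q, B, Pin) {
  rep(q, times = B) + rep((seq_len(B) - 1L) * Pin, each = length(q))
}

#' Initialize a network from an architecture spec
#'
#' Fan-in-scaled Gaussian weights (`sd = sqrt(2 / fan_in)`), zero biases;
#' batch-norm scale 1, shift 0, running mean 0 and running variance 1. Fully
#' deterministic in `seed`.
#'
#' @param arch An [parse_architecture()] result.
#' @param seed Integer seed controlling every weight draw.
#' @return A `trained_network` (untrained until passed through a training
#'   scheme).
#' @export
init_network <- function(arch, seed = 1L) {
  stopifnot(inherits(arch, "architecture_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  params <- vector("list", length(arch$layers))
  for (i in seq_along(arch$layers)) {
    ly <- arch$layers[[i]]
    if (ly$type == "conv") {
      fan_in <- ly$k^2 * ly$cin
      params[[i]] <- list(
        W = matrix(stats::rnorm(fan_in * ly$cout, sd = sqrt(2 / fan_in)),
                   fan_in, ly$cout),
        b = numeric(ly$cout))
      if (ly$bn)
        params[[i]] <- c(params[[i]], list(
          gamma = rep(1, ly$cout), beta = numeric(ly$cout),
          run_mean = numeric(ly$cout), run_var = rep(1, ly$cout)))
    } else if (ly$type == "fc") {
      params[[i]] <- list(
        W = matrix(stats::rnorm(ly$din * ly$dout, sd = sqrt(2 / ly$din)),
                   ly$din, ly$dout),
        b = numeric(ly$dout))
    } else {
      params[[i]] <- list()
    }
  }
  structure(list(arch = arch, params = params, seed = as.integer(seed),
                 test_accuracy = NULL, log = NULL),
            class = "trained_network")
}

#' @export
print.trained_network <- function(x, ...) {
  acc <- if (is.null(x$test_accuracy)) "untrained"
         else sprintf("test acc %.3f", x$test_accuracy)
  cat(sprintf("<trained_network: %s | %s>\n",
              paste(x$arch$tokens, collapse = " "), acc))
  invisible(x)
}

#' Extract the classifier head (final fully connected layer)
#'
#' @param net A `trained_network`.
#' @return A `classifier_head`: `W` (N x M) and `b` (length N).
#' @export
classifier_head <- function(net) {
  i <- length(net$arch$layers)
  new_classifier_head(t(net$params[[i]]$W), net$params[[i]]$b)
}

#' Construct a classifier head from a weight matrix and bias
#'
#' @param W N x M weight matrix (M > N for pseudo-inverse constructions).
#' @param b Length-N bias vector.
#' @return A `classifier_head`.
#' @export
new_classifier_head <- function(W, b) {
  stopifnot(is.matrix(W), length(b) == nrow(W))
  structure(list(W = W, b = as.numeric(b)), class = "classifier_head")
}

images_to_feature <- function(images) {
  # (n, H, W, C) array -> (n*P) x C matrix, rows image-major,
  # positions column-major over the H x W grid
  d <- dim(images)
  matrix(aperm(images, c(2, 3, 1, 4)), ncol = d[4])
}

flatten_feature <- function(F, B, P, C) {
  a <- array(F, dim = c(P, B, C))
  t(matrix(aperm(a, c(1, 3, 2)), ncol = B))     # B x (P*C)
}

unflatten_feature <- function(X, B, P, C) {
  a <- array(t(X), dim = c(P, C, B))
  matrix(aperm(a, c(1, 3, 2)), ncol = C)        # (B*P) x C
}

bn_eps <- 1e-5

# Forward pass over one batch. Returns logits, penultimate representation and
# (optionally) the per-layer cache needed for backpropagation.
net_forward_batch <- function(net, images, train_mode = FALSE,
                              keep_cache = FALSE) {
  arch <- net$arch
  B <- dim(images)[1]
  F <- images_to_feature(images)
  cache <- if (keep_cache) vector("list", length(arch$layers)) else NULL
  penult <- NULL
  new_params <- net$params
  nl <- length(arch$layers)
  for (i in seq_len(nl)) {
    ly <- arch$layers[[i]]
    pr <- net$params[[i]]
    if (ly$type == "conv") {
      ix <- ly$idx
      Fpad <- matrix(0, B * ix$Pp, ly$cin)
      Fpad[batch_idx(ix$inner, B, ix$Pp), ] <- F
      kk <- ly$k^2
      cols <- matrix(0, B * ix$P, kk * ly$cin)
      for (o in seq_len(kk))
        cols[, (o - 1L) * ly$cin + seq_len(ly$cin)] <-
          Fpad[batch_idx(ix$nbr[, o], B, ix$Pp), , drop = FALSE]
      out <- cols %*% pr$W
      out <- out + matrix(pr$b, nrow(out), ly$cout, byrow = TRUE)
      bn_cache <- NULL
      if (ly$bn) {
        if (train_mode) {
          mu <- colMeans(out)
          xc <- out - matrix(mu, nrow(out), ly$cout, byrow = TRUE)
          v <- colMeans(xc^2)
          invstd <- 1 / sqrt(v + bn_eps)
          xhat <- xc * matrix(invstd, nrow(out), ly$cout, byrow = TRUE)
          new_params[[i]]$run_mean <- 0.9 * pr$run_mean + 0.1 * mu
          new_params[[i]]$run_var <- 0.9 * pr$run_var + 0.1 * v
        } else {
          invstd <- 1 / sqrt(pr$run_var + bn_eps)
          xhat <- (out - matrix(pr$run_mean, nrow(out), ly$cout,
                                byrow = TRUE)) *
            matrix(invstd, nrow(out), ly$cout, byrow = TRUE)
        }
        out <- xhat * matrix(pr$gamma, nrow(out), ly$cout, byrow = TRUE) +
          matrix(pr$beta, nrow(out), ly$cout, byrow = TRUE)
        bn_cache <- list(xhat = xhat, invstd = invstd)
      }
      act <- pmax(out, 0)
      if (keep_cache)
        cache[[i]] <- list(cols = cols, bn = bn_cache, relu_mask = out > 0,
                           B = B)
      F <- act
    } else if (ly$type == "pool") {
      Pin <- ly$Hin * ly$Win
      A <- lapply(1:4, function(j)
        F[batch_idx(ly$idx[, j], B, Pin), , drop = FALSE])
      M <- pmax(A[[1]], pmax(A[[2]], pmax(A[[3]], A[[4]])))
      if (keep_cache) {
        w <- matrix(4L, nrow(M), ncol(M))
        w[A[[3]] == M] <- 3L
        w[A[[2]] == M] <- 2L
        w[A[[1]] == M] <- 1L      # first-child tie break
        cache[[i]] <- list(which = w, B = B, Pin = Pin)
      }
      F <- M
    } else if (ly$type == "flatten") {
      F <- flatten_feature(F, B, ly$H * ly$W, ly$C)
      if (keep_cache) cache[[i]] <- list(B = B)
      if (i == nl - 1L) penult <- F
    } else { # fc
      input <- F
      out <- F %*% pr$W + matrix(pr$b, B, ly$dout, byrow = TRUE)
      if (ly$hidden) {
        act <- pmax(out, 0)
        if (keep_cache)
          cache[[i]] <- list(input = input, relu_mask = out > 0)
        F <- act
        if (i == nl - 1L) penult <- F
      } else {
        if (keep_cache) cache[[i]] <- list(input = input)
        F <- out
      }
    }
  }
  if (is.null(penult)) {
    # single-Fc architecture: the representation is the flattened input
    fl <- arch$layers[[nl - 1L]]
    penult <- cache_safe_flatten(images, arch)
  }
  list(logits = F, penult = penult, cache = cache, bn_updates = new_params)
}

cache_safe_flatten <- function(images, arch) {
  d <- dim(images)
  flatten_feature(images_to_feature(images), d[1], d[2] * d[3], d[4])
}

#' Forward pass collecting representations, logits and predictions
#'
#' Runs the network in evaluation mode (batch-norm uses running statistics)
#' over a stimulus set and returns the penultimate-layer representation
#' matrix (one row per stimulus, the object representation), the logit
#' matrix, and argmax predicted labels (ties broken toward the lowest index).
#'
#' @param net A `trained_network`.
#' @param data A `labeled_image_set` whose image shape matches the spec.
#' @param chunk Internal evaluation batch size.
#' @return List with `rep` (n x M matrix, stimulus ids in
#'   `attr(, "stimulus_ids")`), `logits` (n x N), `pred` (integer labels in
#'   0..N-1).
#' @export
forward_collect <- function(net, data, chunk = 256L) {
  stopifnot(inherits(net, "trained_network"),
            inherits(data, "labeled_image_set"))
  d <- dim(data$images)
  ex <- net$arch$input_shape
  if (d[2] != ex[1] || d[3] != ex[2] || d[4] != ex[3])
    stop(sprintf("image shape %dx%dx%d does not match architecture %dx%dx%d",
                 d[2], d[3], d[4], ex[1], ex[2], ex[3]))
  n <- d[1]
  rep_m <- matrix(0, n, net$arch$M)
  logits <- matrix(0, n, net$arch$N)
  at <- 1L
  while (at <= n) {
    hi <- min(at + chunk - 1L, n)
    fw <- net_forward_batch(net, data$images[at:hi, , , , drop = FALSE])
    rep_m[at:hi, ] <- fw$penult
    logits[at:hi, ] <- fw$logits
    at <- hi + 1L
  }
  attr(rep_m, "stimulus_ids") <- data$ids
  list(rep = rep_m, logits = logits,
       pred = max.col(logits, ties.method = "first") - 1L)
}

#' Categorization accuracy
#'
#' @param predicted Integer vector of predicted labels.
#' @param truth Integer vector of true labels, same length.
#' @return Fraction of exact matches, in `[0, 1]`.
#' @export
accuracy <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("predicted and truth must have equal length")
  mean(predicted == truth)
}

# Backward pass for one batch. dlogits is B x N; dpenult (optional, B x M) is
# an extra gradient injected at the penultimate representation (the Euclidean
# pull of the second training scheme). Returns gradients shaped like params.
net_backward_batch <- function(net, cache, dlogits, dpenult = NULL) {
  arch <- net$arch
  nl <- length(arch$layers)
  grads <- vector("list", nl)
  d <- dlogits
  for (i in rev(seq_len(nl))) {
    ly <- arch$layers[[i]]
    pr <- net$params[[i]]
    ca <- cache[[i]]
    if (ly$type == "fc") {
      if (ly$hidden) {
        if (i == nl - 1L && !is.null(dpenult)) d <- d + dpenult
        d <- d * ca$relu_mask
      }
      grads[[i]] <- list(W = crossprod(ca$input, d), b = colSums(d))
      d <- d %*% t(pr$W)
    } else if (ly$type == "flatten") {
      if (i == nl - 1L && !is.null(dpenult)) d <- d + dpenult
      d <- unflatten_feature(d, ca$B, ly$H * ly$W, ly$C)
    } else if (ly$type == "pool") {
      B <- ca$B
      dIn <- matrix(0, B * ca$Pin, ly$cin)
      for (j in 1:4) {
        idx <- batch_idx(ly$idx[, j], B, ca$Pin)
        dIn[idx, ] <- dIn[idx, ] + d * (ca$which == j)
      }
      d <- dIn
    } else { # conv
      B <- ca$B
      d <- d * ca$relu_mask
      g <- list()
      if (ly$bn) {
        bn <- ca$bn
        m <- nrow(d)
        g$gamma <- colSums(d * bn$xhat)
        g$beta <- colSums(d)
        dxhat <- d * matrix(pr$gamma, m, ly$cout, byrow = TRUE)
        s1 <- colSums(dxhat)
        s2 <- colSums(dxhat * bn$xhat)
        d <- (dxhat - matrix(s1 / m, m, ly$cout, byrow = TRUE) -
                bn$xhat * matrix(s2 / m, m, ly$cout, byrow = TRUE)) *
          matrix(bn$invstd, m, ly$cout, byrow = TRUE)
      }
      g$W <- crossprod(ca$cols, d)
      g$b <- colSums(d)
      grads[[i]] <- g
      dcols <- d %*% t(pr$W)
      ix <- ly$idx
      kk <- ly$k^2
      dFpad <- matrix(0, B * ix$Pp, ly$cin)
      for (o in seq_len(kk)) {
        idx <- batch_idx(ix$nbr[, o], B, ix$Pp)
        dFpad[idx, ] <- dFpad[idx, ] +
          dcols[, (o - 1L) * ly$cin + seq_len(ly$cin), drop = FALSE]
      }
      d <- dFpad[batch_idx(ix$inner, B, ix$Pp), , drop = FALSE]
    }
  }
  grads
}
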