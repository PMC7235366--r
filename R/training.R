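#' Training configuration
#'
#' Defaults describe the desk-scale reference profile: a D1-style column
#' shrunk to 16 x 16 inputs with quartered channel widths, stochastic
#' gradient descent with momentum 0.9 and a cosine-decayed learning rate,
#' optimizing softmax cross-entropy only (scheme 1) or cross-entropy plus a
#' Euclidean pull of the penultimate layer toward pseudo-inverse targets
#' (scheme 2, weight `scheme2_lambda`).
#'
#' @param tokens Architecture tokens (see [parse_architecture()]).
#' @param input_shape `c(side, side, channels)`.
#' @param num_classes Number of classes N.
#' @param epochs Training epochs (> 0; 0 returns the initialized network).
#' @param batch_size Minibatch size.
#' @param learning_rate Initial learning rate (> 0), cosine-decayed per epoch.
#' @param momentum SGD momentum coefficient.
#' @param grad_clip Maximum global gradient norm per step (`Inf` disables).
#'   Mostly inert for cross-entropy training; it guards the scheme-2
#'   Euclidean phase, whose pseudo-inverse targets can dwarf the activations
#'   early in training.
#' @param seed Integer seed controlling initialization and batch shuffling.
#' @param scheme 1 or 2.
#' @param scheme2_lambda Euclidean-loss weight (>= 0), scheme 2 only. The
#'   default 0.001 balances the two objectives at desk scale, where the
#'   pseudo-inverse targets (squared logits pulled back through the head)
#'   are orders of magnitude larger than typical activations; larger values
#'   trade categorization accuracy for target fit.
#' @param transform_name Registered transform for scheme-2 targets.
#' @return A `train_config`.
#' @export
train_config <- function(tokens = reference_tokens(),
                         input_shape = c(16, 16, 3), num_classes = 10,
                         epochs = 10L, batch_size = 64L,
                         learning_rate = 0.02, momentum = 0.9,
                         grad_clip = 5, seed = 1L, scheme = 1L,
                         scheme2_lambda = 0.001,
                         transform_name = "abs_x_x") {
  if (epochs < 0) stop("epochs must be >= 0")
  if (batch_size < 1) stop("batch_size must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (!scheme %in% c(1L, 2L)) stop("scheme must be 1 or 2")
  if (scheme2_lambda < 0) stop("scheme2_lambda must be >= 0")
  structure(list(tokens = tokens, input_shape = input_shape,
                 num_classes = as.integer(num_classes),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, momentum = momentum,
                 grad_clip = grad_clip,
                 seed = as.integer(seed), scheme = as.integer(scheme),
                 scheme2_lambda = scheme2_lambda,
                 transform_name = transform_name),
            class = "train_config")
}

#' Reference architecture tokens
#'
#' The desk-scale profile: the 5-layer column (5 x 5 convolutions, three
#' pooling stages, one hidden fully connected layer) with channel widths
#' quartered for 16 x 16 inputs. Penultimate width M = 16 over N = 10
#' classes, preserving M > N.
#'
#' @return Character vector of tokens.
#' @export
reference_tokens <- function() {
  c("Conv5-8", "Max-pool", "Conv5-8", "Max-pool", "Conv5-16", "Max-pool",
    "Fc-16", "Fc-10")
}

softmax_xent <- function(logits, labels) {
  # labels 0-based; returns list(loss, dlogits) with gradient averaged
  # over the batch
  B <- nrow(logits)
  P <- softmax_rows(logits)
  idx <- cbind(seq_len(B), labels + 1L)
  loss <- -mean(log(pmax(P[idx], 1e-300)))
  dl <- P
  dl[idx] <- dl[idx] - 1
  list(loss = loss, dlogits = dl / B)
}

zero_like_params <- function(params) {
  lapply(params, function(p) lapply(p, function(x) x * 0))
}

trainable_names <- c("W", "b", "gamma", "beta")

grad_global_norm <- function(grads) {
  s <- 0
  for (g in grads)
    for (nm in intersect(names(g), trainable_names))
      s <- s + sum(g[[nm]]^2)
  sqrt(s)
}

# rescale so the global gradient norm is at most clip (guards the Euclidean
# phase of scheme 2, whose targets can be orders of magnitude larger than
# the activations early in training)
clip_grads <- function(grads, clip) {
  gn <- grad_global_norm(grads)
  if (is.finite(clip) && gn > clip) {
    sc <- clip / gn
    for (i in seq_along(grads))
      for (nm in intersect(names(grads[[i]]), trainable_names))
        grads[[i]][[nm]] <- grads[[i]][[nm]] * sc
  }
  grads
}

sgd_step <- function(params, grads, vel, lr, momentum) {
  for (i in seq_along(params)) {
    if (is.null(grads[[i]])) next
    for (nm in intersect(names(grads[[i]]), trainable_names)) {
      vel[[i]][[nm]] <- momentum * vel[[i]][[nm]] - lr * grads[[i]][[nm]]
      params[[i]][[nm]] <- params[[i]][[nm]] + vel[[i]][[nm]]
    }
  }
  list(params = params, vel = vel)
}

# Core minibatch loop shared by both schemes. target_fn(row_idx) returns the
# penultimate targets for those training rows, or NULL for pure
# cross-entropy. With lambda = 0 the loop is exactly scheme-1 training.
train_loop <- function(net, data, config, target_fn = NULL, lambda = 0) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 7L)
  n <- n_images(data$train)
  M <- net$arch$M
  log_rows <- list()
  vel <- zero_like_params(net$params)
  for (ep in seq_len(config$epochs)) {
    lr <- config$learning_rate *
      0.5 * (1 + cos(pi * (ep - 1) / config$epochs))
    ord <- sample.int(n)
    ce_sum <- 0; eu_sum <- 0; nb <- 0
    batch_ce <- numeric(0)
    for (start in seq(1, n, by = config$batch_size)) {
      rows <- ord[start:min(start + config$batch_size - 1L, n)]
      imgs <- data$train$images[rows, , , , drop = FALSE]
      labs <- data$train$labels[rows]
      fw <- net_forward_batch(net, imgs, train_mode = TRUE,
                              keep_cache = TRUE)
      net$params <- fw$bn_updates          # running batch-norm statistics
      ce <- softmax_xent(fw$logits, labs)
      dpen <- NULL
      eu <- 0
      if (!is.null(target_fn) && lambda > 0) {
        tgt <- target_fn(rows)
        diff <- fw$penult - tgt
        eu <- mean(diff^2)
        dpen <- (2 * lambda / length(diff)) * diff
      }
      grads <- net_backward_batch(net, fw$cache, ce$dlogits, dpen)
      grads <- clip_grads(grads, config$grad_clip)
      st <- sgd_step(net$params, grads, vel, lr, config$momentum)
      net$params <- st$params; vel <- st$vel
      ce_sum <- ce_sum + ce$loss; eu_sum <- eu_sum + eu; nb <- nb + 1
      batch_ce <- c(batch_ce, ce$loss)
    }
    log_rows[[ep]] <- list(epoch = ep, mean_ce = ce_sum / nb,
                           mean_euclid = eu_sum / nb, lr = lr,
                           batch_ce = batch_ce)
    if (!is.finite(ce_sum)) stop("training diverged: non-finite loss")
  }
  fw <- forward_collect(net, data$test)
  net$test_accuracy <- accuracy(fw$pred, data$test$labels)
  net$log <- log_rows
  net
}

#' Train a single network with softmax cross-entropy only
#'
#' Scheme-1 semantics: the only objective is categorization. Deterministic
#' in `(config, seed)`; `epochs = 0` returns the freshly initialized network
#' (whose accuracy sits at chance for a balanced set).
#'
#' @param config A [train_config()].
#' @param data A dataset from [generate_dataset()] (train/test splits).
#' @return A `trained_network` with `test_accuracy` and a per-epoch `log`.
#' @export
train_single <- function(config, data) {
  stopifnot(inherits(config, "train_config"))
  arch <- parse_architecture(config$tokens, config$input_shape,
                             config$num_classes)
  net <- init_network(arch, config$seed)
  if (config$epochs == 0) {
    fw <- forward_collect(net, data$test)
    net$test_accuracy <- accuracy(fw$pred, data$test$labels)
    return(net)
  }
  train_loop(net, data, config)
}

#' Train a similar-performing pair by independent random initialization
#'
#' Scheme 1: the same architecture trained twice from different seeds
#' (initialization and batch order both reseeded). The pair is gated on
#' matched accuracy before any equivalence analysis.
#'
#' @param config A [train_config()] (its seed field is overridden per net).
#' @param data Dataset with train/test splits.
#' @param seed1,seed2 Distinct integer seeds.
#' @param gate_threshold Maximum allowed accuracy difference (fraction).
#' @return A `pair_result`: `net1`, `net2`, `acc1`, `acc2`, `gate`
#'   (TRUE when `|acc1 - acc2| <= gate_threshold`), `scheme`.
#' @export
train_pair_scheme1 <- function(config, data, seed1, seed2,
                               gate_threshold = 0.05) {
  if (seed1 == seed2) stop("seed1 and seed2 must differ")
  c1 <- config; c1$seed <- as.integer(seed1)
  c2 <- config; c2$seed <- as.integer(seed2)
  net1 <- train_single(c1, data)
  net2 <- train_single(c2, data)
  new_pair_result(net1, net2, scheme = 1L, gate_threshold = gate_threshold)
}

new_pair_result <- function(net1, net2, scheme, gate_threshold = 0.05,
                            extra = list()) {
  acc1 <- net1$test_accuracy; acc2 <- net2$test_accuracy
  structure(c(list(net1 = net1, net2 = net2, acc1 = acc1, acc2 = acc2,
                   gate = abs(acc1 - acc2) <= gate_threshold,
                   gate_threshold = gate_threshold, scheme = scheme),
              extra),
            class = "pair_result")
}

#' @export
print.pair_result <- function(x, ...) {
  cat(sprintf(
    "<pair_result scheme %d: acc1 = %.3f, acc2 = %.3f, gate %s>\n",
    x$scheme, x$acc1, x$acc2, if (x$gate) "passed" else "FAILED"))
  invisible(x)
}

#' Penultimate-layer targets for the second training scheme
#'
#' For a batch of images, computes the first network's logits `x'`, applies
#' the monotone transform, and returns the minimum-norm preimage under the
#' (frozen) second head: exactly the counterpart construction, evaluated per
#' stimulus. Pure in `(net1, head2, f, batch)`.
#'
#' @param net1 Trained first network (frozen).
#' @param head2 Full-row-rank `classifier_head` defining the targets.
#' @param transform A [monotone_transform()].
#' @param images `n x side x side x channels` array.
#' @return `n x M` matrix of target representations.
#' @export
compute_scheme2_targets <- function(net1, head2, transform, images) {
  data <- new_image_set(images, rep(0L, dim(images)[1]), "batch", 0L)
  construct_counterpart_representation(net1, transform, head2, data)$rep
}

#' Train the second network of a pair toward pseudo-inverse targets
#'
#' Scheme 2: the first network is trained beforehand with cross-entropy
#' alone; the second is trained on
#' `CE(logits2, labels) + lambda * mean((penult2 - target)^2)`,
#' where the targets are the counterpart representations computed from the
#' first network's logits through the second network's own head frozen at
#' initialization (fixed targets keep the Euclidean objective well-posed;
#' the trainable head receives gradients only from the cross-entropy term).
#' With `lambda = 0` the loop reduces exactly to scheme-1 training.
#'
#' @param config A [train_config()] with `scheme = 2`; its `seed` initializes
#'   the second network.
#' @param data Dataset with train/test splits.
#' @param net1 The already-trained first network.
#' @return A `pair_result` with additional fields `euclid_by_epoch` (mean
#'   per-unit Euclidean loss per epoch) and `head2_frozen`.
#' @export
train_scheme2 <- function(config, data, net1) {
  stopifnot(inherits(net1, "trained_network"))
  arch <- parse_architecture(config$tokens, config$input_shape,
                             config$num_classes)
  if (arch$M <= arch$N)
    stop("scheme 2 requires penultimate width M > N")
  net2 <- init_network(arch, config$seed)
  head2 <- classifier_head(net2)               # frozen copy at initialization
  lambda <- config$scheme2_lambda
  target_fn <- NULL
  if (lambda > 0) {
    tf <- get_transform(config$transform_name)
    all_targets <- compute_scheme2_targets(net1, head2, tf,
                                           data$train$images)
    target_fn <- function(rows) all_targets[rows, , drop = FALSE]
  }
  net2 <- train_loop(net2, data, config, target_fn = target_fn,
                     lambda = lambda)
  euclid <- vapply(net2$log, function(r) r$mean_euclid, numeric(1))
  new_pair_result(net1, net2, scheme = 2L,
                  extra = list(euclid_by_epoch = euclid,
                               head2_frozen = head2))
}
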