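#' Numerically stabilized softmax
#'
#' `softmax(v)[i] = exp(v[i]) / sum(exp(v))`, computed after subtracting
#' `max(v)` so arbitrarily large logits stay finite. Invariant to adding a
#' constant to every logit.
#'
#' @param v Numeric vector of logits (finite).
#' @return Probability vector: positive entries summing to 1.
#' @export
softmax <- function(v) {
  if (!all(is.finite(v))) stop("softmax requires finite logits")
  e <- exp(v - max(v))
  e / sum(e)
}

#' Row-wise softmax of a logit matrix
#' @param m n x N matrix of logits.
#' @return n x N matrix of probability rows.
#' @export
softmax_rows <- function(m) {
  if (!all(is.finite(m))) stop("softmax requires finite logits")
  e <- exp(m - apply(m, 1, max))
  e / rowSums(e)
}

#' Register a scalar monotone transform
#'
#' A transform is admissible for the categorization-invariance results only
#' if it is strictly increasing; this is verified empirically on a dense grid
#' (10,001 points) over `domain`, and registration fails otherwise.
#'
#' @param name Short name for reports.
#' @param f Scalar function, applied elementwise.
#' @param domain Length-2 numeric range on which monotonicity is checked
#'   (extended 20 percent beyond each end).
#' @return A `monotone_transform`.
#' @export
monotone_transform <- function(name, f, domain = c(-50, 50)) {
  stopifnot(is.function(f), length(domain) == 2, domain[1] < domain[2])
  pad <- 0.2 * diff(domain)
  grid <- seq(domain[1] - pad, domain[2] + pad, length.out = 10001)
  vals <- f(grid)
  if (!all(is.finite(vals)))
    stop(sprintf("transform '%s' is not finite on the checked range", name))
  if (any(diff(vals) <= 0))
    stop(sprintf("transform '%s' is not strictly increasing", name))
  structure(list(name = name, f = f, domain = domain),
            class = "monotone_transform")
}

#' Built-in monotone transforms
#'
#' Provides the transforms used throughout the analyses: `"abs_x_x"`
#' (`f(x) = |x| * x`, the signed square used by the second training scheme),
#' `"cube"`, `"exp"` (checked on a bounded domain to stay finite),
#' `"affine_2x_plus_1"`, and `"identity"`.
#'
#' @param name One of the names above.
#' @return A `monotone_transform`.
#' @export
get_transform <- function(name) {
  switch(name,
    abs_x_x = monotone_transform("abs_x_x", function(x) abs(x) * x),
    cube = monotone_transform("cube", function(x) x^3),
    exp = monotone_transform("exp", exp, domain = c(-50, 50)),
    affine_2x_plus_1 = monotone_transform("affine_2x_plus_1",
                                          function(x) 2 * x + 1),
    identity = monotone_transform("identity", function(x) x),
    stop(sprintf("unknown transform '%s'", name))
  )
}

#' Apply a registered monotone transform elementwise
#'
#' @param tf A [monotone_transform()].
#' @param v Numeric vector or matrix of logits.
#' @return Object of the same shape with `tf$f` applied elementwise; the
#'   rank order of entries is preserved.
#' @export
apply_transform <- function(tf, v) {
  if (!inherits(tf, "monotone_transform"))
    stop("tf must be a registered monotone_transform")
  out <- tf$f(v)
  if (is.matrix(v)) dim(out) <- dim(v)
  out
}

top_k_set <- function(v, K) {
  sort(order(v, decreasing = TRUE)[seq_len(K)])
}

#' Do two logit vectors give the same categorization?
#'
#' True iff the index sets of the K largest softmax probabilities coincide
#' (equivalently, of the K largest logits, softmax being order-preserving).
#' For K = 1 this is argmax equality with ties broken toward the lowest
#' index.
#'
#' @param x,y Logit vectors of equal length N.
#' @param K Top-K level, `1 <= K < N`.
#' @return Logical scalar.
#' @export
categorization_agreement <- function(x, y, K = 1L) {
  if (length(x) != length(y)) stop("logit vectors differ in length")
  if (K < 1 || K >= length(x)) stop("K must satisfy 1 <= K < N")
  if (K == 1)
    return(which.max(x) == which.max(y))
  identical(top_k_set(x, K), top_k_set(y, K))
}

# SVD pseudo-inverse with relative cutoff; returns M x N map pinv(W)
svd_pinv <- function(W, rtol = 1e-10) {
  sv <- svd(W)
  keep <- sv$d > rtol * sv$d[1]
  dinv <- ifelse(keep, 1 / sv$d, 0)
  sv$v %*% (dinv * t(sv$u))
}

#' Minimum-norm preimage of target logits under a classifier head
#'
#' Solves `W v + b = target` by the pseudo-inverse:
#' `v = (W'W)^+ W' (target - b)`, computed through the SVD of `W` with a
#' relative singular-value cutoff of `1e-10` times the largest singular
#' value. Requires M > N (a wide head); whenever `W` has full row rank the
#' reconstruction `W v + b` recovers the target exactly, and the returned
#' residual certifies it.
#'
#' @param head A `classifier_head` (N x M, M > N).
#' @param target_logits Length-N vector, or n x N matrix of row targets.
#' @param rank_tol Threshold on the smallest singular value below which a
#'   rank-deficiency warning is raised.
#' @return List with `preimage` (length-M vector or n x M matrix),
#'   `residual` (max abs reconstruction error), and `rank_deficient` flag.
#' @export
pinv_preimage <- function(head, target_logits, rank_tol = 1e-8) {
  stopifnot(inherits(head, "classifier_head"))
  W <- head$W; b <- head$b
  N <- nrow(W); M <- ncol(W)
  if (M <= N) stop("pseudo-inverse construction requires M > N")
  sv_min <- min(svd(W, nu = 0, nv = 0)$d)
  rank_deficient <- sv_min < rank_tol
  if (rank_deficient)
    warning(sprintf("head is near rank-deficient (sigma_min = %.3g)", sv_min))
  P <- svd_pinv(W)                              # M x N
  if (is.matrix(target_logits)) {
    stopifnot(ncol(target_logits) == N)
    Tc <- target_logits - matrix(b, nrow(target_logits), N, byrow = TRUE)
    V <- Tc %*% t(P)                            # n x M
    recon <- V %*% t(W) + matrix(b, nrow(V), N, byrow = TRUE)
    res <- max(abs(recon - target_logits))
  } else {
    stopifnot(length(target_logits) == N)
    V <- drop(P %*% (target_logits - b))
    res <- max(abs(drop(W %*% V) + b - target_logits))
  }
  list(preimage = V, residual = res, rank_deficient = rank_deficient)
}

#' Draw a random full-row-rank classifier head
#'
#' Entries i.i.d. Gaussian with sd `1/sqrt(M)`, redrawn until the smallest
#' singular value exceeds `rank_tol` (immediate for generic draws).
#'
#' @param N,M Head dimensions, M > N.
#' @param seed Integer seed.
#' @param rank_tol Minimum acceptable smallest singular value.
#' @return A `classifier_head`.
#' @export
random_full_rank_head <- function(N, M, seed = 1L, rank_tol = 1e-6) {
  stopifnot(M > N)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  repeat {
    W <- matrix(stats::rnorm(N * M, sd = 1 / sqrt(M)), N, M)
    b <- stats::rnorm(N, sd = 1 / sqrt(M))
    if (min(svd(W, nu = 0, nv = 0)$d) > rank_tol)
      return(new_classifier_head(W, b))
  }
}

#' Construct the counterpart representation with identical categorization
#'
#' Given a trained network with logits `x' = W1 x + b1`, a monotone transform
#' `f`, and a second full-row-rank head `(W2, b2)`, builds for every stimulus
#' the representation
#' `y = (W2'W2)^+ W2' (f(x') - b2)`,
#' the minimum-norm preimage of the transformed logits. By construction
#' `W2 y + b2 = f(x')` exactly (full row rank), so the counterpart network
#' categorizes every stimulus identically to the original while `y` is not a
#' linear transform of `x` for non-linear `f`.
#'
#' @param net1 A `trained_network`.
#' @param transform A [monotone_transform()].
#' @param head2 A full-row-rank `classifier_head` with the same N and M > N.
#' @param data A `labeled_image_set`.
#' @return List with `rep` (n x M counterpart representation, stimulus ids
#'   attached), `logits` (`W2 y + b2`), `pred` (argmax labels),
#'   `target_logits` (`f(x')`), `residual` (max abs
#'   `|W2 y + b2 - f(x')|`), and `pred1` (the original network's labels).
#' @export
construct_counterpart_representation <- function(net1, transform, head2,
                                                 data) {
  stopifnot(inherits(net1, "trained_network"),
            inherits(head2, "classifier_head"))
  if (nrow(head2$W) != net1$arch$N)
    stop("head2 class count does not match the network")
  if (ncol(head2$W) <= nrow(head2$W))
    stop("pseudo-inverse construction requires M > N in head2")
  fw <- forward_collect(net1, data)
  target <- apply_transform(transform, fw$logits)     # f(x'), n x N
  pre <- pinv_preimage(head2, target)
  Y <- pre$preimage
  attr(Y, "stimulus_ids") <- data$ids
  logits_y <- Y %*% t(head2$W) +
    matrix(head2$b, nrow(Y), nrow(head2$W), byrow = TRUE)
  list(rep = Y, logits = logits_y,
       pred = max.col(logits_y, ties.method = "first") - 1L,
       target_logits = target, residual = pre$residual, pred1 = fw$pred)
}
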