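#' @name equivalence
#' @title Linear-equivalence analysis of representation matrices
#'
#' @description Two object representations are considered equivalent when one
#' is an affine transform of the other over the stimulus set. The degree of
#' equivalence is quantified by explained variance (EV): an affine map is fit
#' from source to target on a seeded half of the stimuli and scored per
#' target neuron on the held-out half as `1 - SS_res / SS_tot`; the headline
#' value symmetrizes the two directions. EV = 1 (to tolerance) iff the
#' relation is affine on the evaluated stimuli; independent representations
#' score near 0.
NULL

rep_ids <- function(m) {
  ids <- attr(m, "stimulus_ids")
  if (is.null(ids)) seq_len(nrow(m)) else ids
}

sub_rep_rows <- function(m, rows) {
  out <- m[rows, , drop = FALSE]
  attr(out, "stimulus_ids") <- rep_ids(m)[rows]
  out
}

sub_rep_cols <- function(m, cols) {
  out <- m[, cols, drop = FALSE]
  attr(out, "stimulus_ids") <- rep_ids(m)
  out
}

# order rows canonically by stimulus id so EV is invariant to row
# permutations (resampled subsets compare exactly against full-set runs)
canonical_order <- function(source, target) {
  ids_s <- rep_ids(source); ids_t <- rep_ids(target)
  if (length(ids_s) != length(ids_t) || !setequal(ids_s, ids_t))
    stop("source and target stimulus ids are misaligned")
  if (anyDuplicated(ids_s)) stop("duplicated stimulus ids")
  list(source = sub_rep_rows(source, order(ids_s)),
       target = sub_rep_rows(target, order(ids_t)),
       ids = sort(ids_s))
}

split_by_ids <- function(ids, fit_fraction, seed) {
  n <- length(ids)
  n_fit <- round(fit_fraction * n)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fit_ids <- sort(sample(ids, n_fit))
  list(fit = which(ids %in% fit_ids), eval = which(!ids %in% fit_ids))
}

# minimum-norm least squares through the SVD (relative cutoff)
lstsq_minnorm <- function(X, Y, rtol = 1e-12) {
  sv <- svd(X)
  keep <- sv$d > rtol * sv$d[1]
  dinv <- ifelse(keep, 1 / sv$d, 0)
  sv$v %*% (dinv * (t(sv$u) %*% Y))
}

#' Fit an affine map between two representation matrices
#'
#' Rows are aligned by stimulus id, split into a seeded fit/eval partition,
#' and an affine map (intercept column appended) is fit on the fit split by
#' least squares: the minimum-norm solution via SVD when `ridge = 0`, ridge
#' regression (intercept unpenalized) otherwise. A warning is raised when the
#' fit split has fewer rows than source dimensions + 1 (underdetermined; the
#' minimum-norm fit is still returned).
#'
#' @param source n x Ms matrix (stimulus ids in `attr(, "stimulus_ids")`,
#'   defaulting to row numbers).
#' @param target n x Mt matrix, same stimulus ids.
#' @param fit_fraction Fraction of stimuli used for fitting (default 0.5).
#' @param ridge Ridge penalty (>= 0, default 0).
#' @param seed Seed for the fit/eval split.
#' @return List with `B` ((Ms + 1) x Mt map, first row the intercept),
#'   `fit_rows`, `eval_rows` (row positions in canonical id order),
#'   `underdetermined` flag.
#' @export
fit_linear_map <- function(source, target, fit_fraction = 0.5, ridge = 0,
                           seed = 1L) {
  co <- canonical_order(source, target)
  sp <- split_by_ids(co$ids, fit_fraction, seed)
  S <- co$source[sp$fit, , drop = FALSE]
  T_ <- co$target[sp$fit, , drop = FALSE]
  X <- cbind(1, S)
  under <- nrow(X) < ncol(X)
  if (under)
    warning(sprintf(
      "underdetermined affine fit: %d stimuli for %d coefficients",
      nrow(X), ncol(X)))
  if (ridge > 0) {
    pen <- diag(c(0, rep(ridge, ncol(S))))
    B <- solve(crossprod(X) + pen, crossprod(X, T_))
  } else {
    B <- lstsq_minnorm(X, T_)
  }
  list(B = B, fit_rows = sp$fit, eval_rows = sp$eval,
       underdetermined = under,
       source = co$source, target = co$target)
}

ev_one_direction <- function(source, target, fit_rows, eval_rows, B) {
  Xe <- cbind(1, source[eval_rows, , drop = FALSE])
  Te <- target[eval_rows, , drop = FALSE]
  pred <- Xe %*% B
  mu <- colMeans(Te)
  ss_tot <- colSums((Te - matrix(mu, nrow(Te), ncol(Te), byrow = TRUE))^2)
  ss_res <- colSums((Te - pred)^2)
  # neurons (near-)constant on the eval split have no variance to explain;
  # the cutoff is relative so numerically-silent ReLU units are excluded too
  keep <- ss_tot > max(1e-12, 1e-9 * max(ss_tot))
  ev <- rep(NA_real_, ncol(Te))
  ev[keep] <- 1 - ss_res[keep] / ss_tot[keep]
  list(per_neuron = ev, mean = mean(ev[keep]),
       n_excluded = sum(!keep))
}

#' Explained variance between two representations
#'
#' Fits affine maps in both directions on the same seeded stimulus split and
#' scores each target neuron on the held-out stimuli as
#' `EV_j = 1 - SS_res,j / SS_tot,j` (total sum of squares about the eval-split
#' mean). Zero-variance eval neurons are excluded from the directional mean
#' (their count is reported); negative per-neuron values are retained. The
#' headline value is the average of the two directional means.
#'
#' @inheritParams fit_linear_map
#' @return An `ev_report`: `per_neuron_ev_fwd`, `per_neuron_ev_rev`,
#'   `mean_ev_src_to_tgt`, `mean_ev_tgt_to_src`, `headline_mean_ev`,
#'   `n_excluded_fwd`, `n_excluded_rev`, `fit_fraction`, `ridge`,
#'   `n_stimuli`, `seed`.
#' @export
explained_variance <- function(source, target, fit_fraction = 0.5,
                               ridge = 0, seed = 1L) {
  co <- canonical_order(source, target)
  n <- length(co$ids)
  sp <- split_by_ids(co$ids, fit_fraction, seed)
  if (length(sp$eval) < 3) stop("fewer than 3 eval stimuli")
  fit_dir <- function(S, T_) {
    X <- cbind(1, S[sp$fit, , drop = FALSE])
    if (nrow(X) < ncol(X))
      warning(sprintf(
        "underdetermined affine fit: %d stimuli for %d coefficients",
        nrow(X), ncol(X)))
    if (ridge > 0) {
      pen <- diag(c(0, rep(ridge, ncol(S))))
      solve(crossprod(X) + pen, crossprod(X, T_[sp$fit, , drop = FALSE]))
    } else {
      lstsq_minnorm(X, T_[sp$fit, , drop = FALSE])
    }
  }
  B_fwd <- fit_dir(co$source, co$target)
  B_rev <- fit_dir(co$target, co$source)
  fwd <- ev_one_direction(co$source, co$target, sp$fit, sp$eval, B_fwd)
  rev <- ev_one_direction(co$target, co$source, sp$fit, sp$eval, B_rev)
  structure(list(
    per_neuron_ev_fwd = fwd$per_neuron, per_neuron_ev_rev = rev$per_neuron,
    mean_ev_src_to_tgt = fwd$mean, mean_ev_tgt_to_src = rev$mean,
    headline_mean_ev = (fwd$mean + rev$mean) / 2,
    n_excluded_fwd = fwd$n_excluded, n_excluded_rev = rev$n_excluded,
    fit_fraction = fit_fraction, ridge = ridge, n_stimuli = n,
    seed = as.integer(seed)), class = "ev_report")
}

#' @export
print.ev_report <- function(x, ...) {
  cat(sprintf(
    paste0("<ev_report: headline %.4f (src->tgt %.4f, tgt->src %.4f), ",
           "n = %d>\n"),
    x$headline_mean_ev, x$mean_ev_src_to_tgt, x$mean_ev_tgt_to_src,
    x$n_stimuli))
  invisible(x)
}

#' Explained variance between neuron subsets
#'
#' Restricts each representation to the selected neuron columns and computes
#' [explained_variance()] between the restrictions; full-index subsets
#' reproduce the unrestricted analysis exactly.
#'
#' @inheritParams explained_variance
#' @param idx_s,idx_t Non-empty column index vectors for source and target.
#' @return An `ev_report`.
#' @export
ev_between_neuron_subsets <- function(source, target, idx_s, idx_t,
                                      fit_fraction = 0.5, ridge = 0,
                                      seed = 1L) {
  if (length(idx_s) == 0 || length(idx_t) == 0)
    stop("neuron subsets must be non-empty")
  explained_variance(sub_rep_cols(source, idx_s),
                     sub_rep_cols(target, idx_t),
                     fit_fraction = fit_fraction, ridge = ridge, seed = seed)
}

#' Per-neuron selectivity as response kurtosis
#'
#' Kurtosis of each neuron's response distribution over stimuli, in the
#' Pearson convention (`m4 / m2^2`; a Gaussian scores 3). High kurtosis means
#' sparse, highly selective responding. Neurons with zero response variance
#' have undefined kurtosis and are returned as `NA` (ranked last by
#' [selectivity_ranking()]).
#'
#' @param rep n x M representation matrix, n >= 4.
#' @param excess If TRUE, report excess kurtosis (`m4 / m2^2 - 3`). The
#'   selectivity ranking is identical under either convention.
#' @return Numeric vector of length M (NA where undefined).
#' @export
selectivity_profile <- function(rep, excess = FALSE) {
  n <- nrow(rep)
  if (n < 4) stop("kurtosis requires at least 4 stimuli")
  mu <- colMeans(rep)
  xc <- rep - matrix(mu, n, ncol(rep), byrow = TRUE)
  m2 <- colMeans(xc^2)
  m4 <- colMeans(xc^4)
  k <- ifelse(m2 > 0, m4 / m2^2, NA_real_)
  if (excess) k <- k - 3
  k
}

#' Rank neurons by selectivity, most selective first
#'
#' @param kurt Vector from [selectivity_profile()].
#' @return Integer vector of column indices ordered by decreasing kurtosis,
#'   undefined (NA) neurons last.
#' @export
selectivity_ranking <- function(kurt) {
  order(kurt, decreasing = TRUE, na.last = TRUE)
}
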