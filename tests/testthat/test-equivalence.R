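rand_rep <- function(n, m, seed) {
  set.seed(seed)
  matrix(stats::rnorm(n * m), n, m)
}

test_that("EV is exactly 1 for self- and affine-related representations", {
  X <- rand_rep(300, 12, 1)
  ev_self <- explained_variance(X, X, seed = 1)
  expect_equal(ev_self$headline_mean_ev, 1, tolerance = 1e-9)
  set.seed(2)
  A <- matrix(stats::rnorm(144), 12, 12)
  cvec <- stats::rnorm(12)
  Y <- X %*% A + matrix(cvec, 300, 12, byrow = TRUE)
  ev_aff <- explained_variance(X, Y, seed = 1)
  expect_equal(ev_aff$headline_mean_ev, 1, tolerance = 1e-6)
})

test_that("EV concentrates near zero for independent representations", {
  evs <- vapply(1:5, function(s) {
    X <- rand_rep(2000, 32, 100 + s)
    Z <- rand_rep(2000, 32, 900 + s)
    explained_variance(X, Z, seed = s)$headline_mean_ev
  }, numeric(1))
  expect_true(all(abs(evs) < 0.05))
  # null EV shrinks with sample size
  ev_small <- abs(explained_variance(rand_rep(300, 32, 51),
                                     rand_rep(300, 32, 52),
                                     seed = 1)$headline_mean_ev)
  expect_lt(mean(abs(evs)), ev_small + 0.05)
})

test_that("nonlinearly related representations score below 1", {
  X <- rand_rep(1000, 16, 3)
  set.seed(4)
  A <- matrix(stats::rnorm(16 * 16), 16, 16)
  Y <- tanh(X %*% A)
  ev <- explained_variance(X, Y, seed = 1)
  expect_lt(ev$headline_mean_ev, 0.99)
  expect_gt(ev$headline_mean_ev, 0)
})

test_that("source-side EV is invariant to affine reparameterization", {
  # an invertible remix of the SOURCE spans the same predictor space, so
  # the source-to-target directional mean is unchanged; remixing the target
  # redefines the per-neuron quantities being explained, so only this
  # direction carries the invariance
  X <- rand_rep(400, 10, 5)
  Y <- rand_rep(400, 10, 6)
  base <- explained_variance(X, Y, seed = 3)$mean_ev_src_to_tgt
  set.seed(7)
  B <- matrix(stats::rnorm(100), 10, 10)
  Xr <- X %*% B + matrix(stats::rnorm(10), 400, 10, byrow = TRUE)
  expect_equal(explained_variance(Xr, Y, seed = 3)$mean_ev_src_to_tgt, base,
               tolerance = 1e-6)
})

test_that("EV is invariant to row permutation given stimulus ids", {
  X <- rand_rep(200, 8, 8)
  Y <- rand_rep(200, 8, 9)
  attr(X, "stimulus_ids") <- 1:200
  attr(Y, "stimulus_ids") <- 1:200
  base <- explained_variance(X, Y, seed = 2)
  set.seed(10)
  perm <- sample(200)
  Xp <- X[perm, ]; attr(Xp, "stimulus_ids") <- (1:200)[perm]
  expect_identical(explained_variance(Xp, Y, seed = 2)$headline_mean_ev,
                   base$headline_mean_ev)
  # misaligned ids are refused
  attr(Xp, "stimulus_ids") <- 201:400
  expect_error(explained_variance(Xp, Y, seed = 2), "misaligned")
})

test_that("underdetermined fits warn and still return the min-norm map", {
  X <- rand_rep(20, 30, 11)
  Y <- rand_rep(20, 5, 12)
  expect_warning(fm <- fit_linear_map(X, Y, seed = 1), "underdetermined")
  expect_true(fm$underdetermined)
  # min-norm solution interpolates the fit split exactly
  pred <- cbind(1, fm$source[fm$fit_rows, ]) %*% fm$B
  expect_lt(max(abs(pred - fm$target[fm$fit_rows, ])), 1e-8)
})

test_that("fit_linear_map recovers an exact affine relation", {
  X <- rand_rep(200, 6, 13)
  set.seed(14)
  A <- matrix(stats::rnorm(36), 6, 6)
  Y <- X %*% A + 2
  fm <- fit_linear_map(X, Y, seed = 5)
  pred <- cbind(1, fm$source[fm$eval_rows, ]) %*% fm$B
  expect_lt(max(abs(pred - fm$target[fm$eval_rows, ])),
            1e-6 * max(abs(Y)))
  expect_equal(fm$B[-1, ], A, tolerance = 1e-6)
})

test_that("neuron-subset EV matches the full analysis at full subsets", {
  X <- rand_rep(300, 10, 15)
  Y <- rand_rep(300, 10, 16)
  full <- explained_variance(X, Y, seed = 4)
  sub <- ev_between_neuron_subsets(X, Y, 1:10, 1:10, seed = 4)
  expect_identical(sub$headline_mean_ev, full$headline_mean_ev)
  one <- ev_between_neuron_subsets(X, Y, 3, 7, seed = 4)
  expect_length(one$per_neuron_ev_fwd, 1)
  expect_length(one$per_neuron_ev_rev, 1)
  expect_error(ev_between_neuron_subsets(X, Y, integer(0), 1), "non-empty")
  # disjoint small subsets of independent matrices stay near zero
  XL <- rand_rep(3000, 40, 17)
  YL <- rand_rep(3000, 40, 18)
  ev <- ev_between_neuron_subsets(XL, YL, 1:4, 37:40, seed = 1)
  expect_lt(abs(ev$headline_mean_ev), 0.1)
})

test_that("kurtosis selectivity matches moment oracles", {
  set.seed(20)
  g <- matrix(stats::rnorm(1e5), ncol = 1)
  expect_lt(abs(selectivity_profile(g) - 3), 0.1)
  # sparse spike train against the independent e1071 implementation
  x <- c(rep(0, 99), 10)
  jit <- x + stats::rnorm(100, sd = 1e-3)
  m <- cbind(jit, stats::rnorm(100))
  ours <- selectivity_profile(m)
  oracle <- apply(m, 2, function(col) e1071::kurtosis(col, type = 1) + 3)
  expect_equal(ours, oracle, tolerance = 1e-10, ignore_attr = TRUE)
  # constant neurons are flagged undefined and ranked last
  mc <- cbind(a = jit, b = rep(2, 100))
  k <- selectivity_profile(mc)
  expect_true(is.na(k[2]))
  expect_equal(selectivity_ranking(k), c(1L, 2L))
  expect_error(selectivity_profile(m[1:3, , drop = FALSE]), "at least 4")
  # excess convention shifts by 3, ranking unchanged
  expect_equal(selectivity_profile(m, excess = TRUE), ours - 3,
               ignore_attr = TRUE)
})
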