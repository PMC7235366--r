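test_that("softmax matches closed forms and is shift invariant", {
  expect_equal(softmax(c(0, 0, 0, 0)), rep(0.25, 4))
  expect_equal(softmax(c(log(2), 0)), c(2 / 3, 1 / 3))
  v <- c(1.3, -0.2, 4, 0)
  expect_equal(softmax(v + 17.5), softmax(v), tolerance = 1e-12)
  expect_equal(sum(softmax(stats::rnorm(10) * 30)), 1, tolerance = 1e-12)
  expect_error(softmax(c(1, Inf)), "finite")
})

test_that("monotone transforms apply elementwise; decreasing maps rejected", {
  tf <- get_transform("abs_x_x")
  expect_equal(apply_transform(tf, c(2, -2, 0)), c(4, -4, 0))
  idt <- get_transform("identity")
  v <- stats::rnorm(6)
  expect_identical(apply_transform(idt, v), v)
  expect_error(monotone_transform("neg", function(x) -x),
               "not strictly increasing")
  expect_error(apply_transform(function(x) x, v), "registered")
})

test_that("monotone transforms preserve top-K categorization", {
  expect_true(categorization_agreement(c(3, 1, 2), c(27, 1, 8), K = 1))
  expect_false(categorization_agreement(c(3, 1, 2), c(-3, -1, -2), K = 1))
  expect_error(categorization_agreement(c(1, 2), c(1, 2, 3)), "length")
  # randomized sweep: agreement must be exact for every monotone transform
  tfs <- lapply(c("abs_x_x", "cube", "exp"), get_transform)
  set.seed(42)
  for (tf in tfs) {
    X <- matrix(stats::rnorm(500 * 10, sd = 3), 500, 10)
    Y <- apply_transform(tf, X)
    for (i in seq_len(nrow(X))) {
      expect_true(categorization_agreement(X[i, ], Y[i, ], K = 1))
      expect_true(categorization_agreement(X[i, ], Y[i, ], K = 3))
    }
  }
})

test_that("softmax order is preserved under monotone maps", {
  set.seed(7)
  v <- stats::rnorm(20, sd = 2)
  y <- apply_transform(get_transform("cube"), v)
  expect_equal(stats::cor(rank(softmax(v)), rank(softmax(y)),
                          method = "spearman"), 1)
})

test_that("pseudo-inverse preimage reconstructs targets exactly", {
  # closed form: minimum-norm preimage picks the zero free coordinate
  head <- new_classifier_head(matrix(c(1, 0), 1, 2), 0)
  out <- pinv_preimage(head, 5)
  expect_equal(out$preimage, c(5, 0))
  expect_equal(out$residual, 0)
  # generic full-row-rank heads against an independent pseudo-inverse oracle
  set.seed(11)
  for (r in 1:20) {
    h <- random_full_rank_head(4, 9, seed = r)
    tgt <- stats::rnorm(4, sd = 3)
    got <- pinv_preimage(h, tgt)
    expect_lt(got$residual, 1e-8)
    oracle <- drop(MASS::ginv(h$W) %*% (tgt - h$b))
    expect_equal(got$preimage, oracle, tolerance = 1e-8)
  }
  # a zero row makes one logit unreachable
  W <- rbind(c(1, 0, 0), c(0, 0, 0))
  hz <- new_classifier_head(W, c(0, 0))
  expect_warning(outz <- pinv_preimage(hz, c(1, 2)), "rank-deficient")
  expect_gt(outz$residual, 0.5)
  # M <= N violates the wide-head precondition
  expect_error(pinv_preimage(new_classifier_head(diag(3), numeric(3)), 1:3),
               "M > N")
})

test_that("counterpart construction realizes the mapping identity", {
  # small instance (N = 4, M = 8) with the cube transform
  ds <- tiny_dataset()
  cfg <- tiny_train_config(seed = 5, epochs = 2)
  net1 <- train_single(cfg, ds)
  h2 <- random_full_rank_head(4, 8, seed = 99)
  tf <- get_transform("cube")
  cp <- construct_counterpart_representation(net1, tf, h2, ds$test)
  fw1 <- forward_collect(net1, ds$test)
  # y' = f(x') elementwise, to strict tolerance
  expect_lt(max(abs(cp$logits - apply_transform(tf, fw1$logits))), 1e-9)
  # identical categorization on every stimulus
  expect_equal(mean(cp$pred == fw1$pred), 1.0)
  # independent oracle: row-by-row generic least-squares preimage
  i <- 7
  yi <- MASS::ginv(h2$W) %*% (cp$target_logits[i, ] - h2$b)
  expect_equal(cp$rep[i, ], drop(yi), tolerance = 1e-8)
})

test_that("identity transform with the network's own head projects x", {
  ds <- tiny_dataset()
  net1 <- train_single(tiny_train_config(seed = 6, epochs = 1), ds)
  h1 <- classifier_head(net1)
  cp <- construct_counterpart_representation(net1, get_transform("identity"),
                                             h1, ds$test)
  fw1 <- forward_collect(net1, ds$test)
  # y is the projection of x onto the row space of W1
  P <- t(h1$W) %*% solve(h1$W %*% t(h1$W)) %*% h1$W
  expect_equal(cp$rep, fw1$rep %*% P, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("nonlinear counterparts are not linearly related to the source", {
  ds <- tiny_dataset()
  net1 <- train_single(tiny_train_config(seed = 5, epochs = 2), ds)
  h2 <- random_full_rank_head(4, 8, seed = 99)
  cp <- construct_counterpart_representation(net1, get_transform("abs_x_x"),
                                             h2, ds$test)
  fw1 <- forward_collect(net1, ds$test)
  ev <- explained_variance(fw1$rep, cp$rep, seed = 1)
  expect_lt(ev$headline_mean_ev, 1 - 1e-4)
})
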