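test_that("untrained networks sit at chance on a balanced set", {
  ds <- tiny_dataset()
  cfg <- tiny_train_config(seed = 1, epochs = 0)
  net <- train_single(cfg, ds)
  n <- length(ds$test$labels)
  # binomial band around 1/K
  expect_lt(abs(net$test_accuracy - 0.25), 4 * sqrt(0.25 * 0.75 / n))
})

test_that("training is deterministic in the seed", {
  ds <- tiny_dataset()
  cfg <- tiny_train_config(seed = 31, epochs = 2)
  n1 <- train_single(cfg, ds)
  n2 <- train_single(cfg, ds)
  expect_identical(forward_collect(n1, ds$test)$pred,
                   forward_collect(n2, ds$test)$pred)
  expect_identical(n1$test_accuracy, n2$test_accuracy)
})

test_that("training reduces the loss on separable data", {
  ds <- tiny_dataset()
  net <- train_single(tiny_train_config(seed = 12, epochs = 3), ds)
  ce <- vapply(net$log, function(r) r$mean_ce, numeric(1))
  expect_lt(ce[3], ce[1])
  expect_gt(net$test_accuracy, 0.5)
})

test_that("paired training yields distinct parameters and logs both nets", {
  ds <- tiny_dataset()
  cfg <- tiny_train_config(epochs = 2)
  pair <- train_pair_scheme1(cfg, ds, 11, 22)
  expect_error(train_pair_scheme1(cfg, ds, 11, 11), "must differ")
  expect_s3_class(pair, "pair_result")
  w1 <- pair$net1$params[[1]]$W
  w2 <- pair$net2$params[[1]]$W
  expect_gt(max(abs(w1 - w2)), 0)
  expect_true(pair$acc1 >= 0 && pair$acc1 <= 1)
  # re-run reproduces the pair exactly
  pair2 <- train_pair_scheme1(cfg, ds, 11, 22)
  expect_identical(pair$net1$params, pair2$net1$params)
  expect_identical(pair$acc2, pair2$acc2)
})

test_that("scheme-2 targets share the counterpart exactness contract", {
  ds <- tiny_dataset()
  net1 <- train_single(tiny_train_config(seed = 5, epochs = 2), ds)
  h2 <- random_full_rank_head(4, 8, seed = 17)
  tf <- get_transform("abs_x_x")
  tgt <- compute_scheme2_targets(net1, h2, tf, ds$train$images)
  fw1 <- forward_collect(net1, ds$train)
  recon <- tgt %*% t(h2$W) + matrix(h2$b, nrow(tgt), 4, byrow = TRUE)
  expect_lt(max(abs(recon - apply_transform(tf, fw1$logits))), 1e-7)
  # identity transform with net1's own head: row-space projection
  h1 <- classifier_head(net1)
  tgt_id <- compute_scheme2_targets(net1, h1, get_transform("identity"),
                                    ds$train$images)
  P <- t(h1$W) %*% solve(h1$W %*% t(h1$W)) %*% h1$W
  expect_equal(tgt_id, fw1$rep %*% P, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("scheme 2 with lambda 0 reproduces scheme-1 batch losses", {
  ds <- tiny_dataset()
  cfg1 <- tiny_train_config(seed = 77, epochs = 2)
  net_a <- train_single(cfg1, ds)
  cfg2 <- tiny_train_config(seed = 77, epochs = 2, scheme = 2,
                            scheme2_lambda = 0)
  net1 <- train_single(tiny_train_config(seed = 5, epochs = 1), ds)
  pair <- train_scheme2(cfg2, ds, net1)
  for (ep in 1:2)
    expect_identical(pair$net2$log[[ep]]$batch_ce, net_a$log[[ep]]$batch_ce)
  expect_identical(forward_collect(pair$net2, ds$test)$pred,
                   forward_collect(net_a, ds$test)$pred)
})

test_that("the Euclidean pull decreases its own residual", {
  ds <- tiny_dataset()
  net1 <- train_single(tiny_train_config(seed = 5, epochs = 3), ds)
  cfg2 <- tiny_train_config(seed = 88, epochs = 4, scheme = 2,
                            scheme2_lambda = 1)
  pair <- train_scheme2(cfg2, ds, net1)
  eu <- pair$euclid_by_epoch
  expect_lt(eu[length(eu)], eu[1])
  # bounded above by perfection: representations pulled toward, but not
  # onto, the analytic counterpart
  reps1 <- forward_collect(pair$net1, ds$test)$rep
  reps2 <- forward_collect(pair$net2, ds$test)$rep
  ev <- explained_variance(reps1, reps2, seed = 1)
  expect_lt(ev$headline_mean_ev, 1)
  expect_error(tiny_train_config(scheme2_lambda = -1), "scheme2_lambda")
})
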