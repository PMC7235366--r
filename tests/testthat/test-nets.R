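table1_columns <- function() {
  list(
    D1 = c("Conv5-32", "Max-pool", "Conv5-32", "Max-pool", "Conv5-64",
           "Max-pool", "Fc-64", "Fc-10"),
    D2 = c("Conv3-bn-32", "Conv3-bn-32", "Max-pool", "Conv3-bn-64",
           "Conv3-bn-64", "Max-pool", "Conv3-bn-128", "Conv3-bn-128",
           "Max-pool", "Conv3-bn-256", "Max-pool", "Fc-10"),
    D3 = c("Conv3-bn-64", "Conv3-bn-64", "Max-pool", "Conv3-bn-128",
           "Conv3-bn-128", "Max-pool", "Conv3-bn-256", "Conv3-bn-256",
           "Max-pool", "Conv3-bn-512", "Max-pool", "Fc-10"),
    D4 = c("Conv3-bn-128", "Conv3-bn-128", "Max-pool", "Conv3-bn-256",
           "Conv3-bn-256", "Max-pool", "Conv3-bn-512", "Conv3-bn-512",
           "Max-pool", "Conv3-bn-1024", "Max-pool", "Fc-100"),
    D5 = c("Conv3-bn-32", "Conv3-bn-32", "Conv3-bn-32", "Conv3-bn-32",
           "Max-pool", "Conv3-bn-64", "Conv3-bn-64", "Conv3-bn-64",
           "Conv3-bn-64", "Max-pool", "Conv3-bn-128", "Conv3-bn-128",
           "Conv3-bn-128", "Conv3-bn-128", "Max-pool", "Conv3-bn-256",
           "Conv3-bn-256", "Max-pool", "Fc-10"),
    D6 = c("Conv3-bn-64", "Max-pool", "Conv3-bn-128", "Max-pool",
           "Conv3-bn-256", "Conv3-bn-256", "Max-pool", "Conv3-bn-512",
           "Conv3-bn-512", "Max-pool", "Conv3-bn-512", "Conv3-bn-512",
           "Max-pool", "Fc-10")
  )
}

test_that("the 5-layer column parses with the printed penultimate width", {
  arch <- parse_architecture(table1_columns()$D1, c(32, 32, 3), 10)
  expect_equal(arch$M, 64)
  expect_equal(arch$N, 10)
})

test_that("all six configuration columns parse with M > N", {
  cols <- table1_columns()
  for (nm in names(cols)) {
    N <- if (nm == "D4") 100 else 10
    arch <- parse_architecture(cols[[nm]], c(32, 32, 3), N)
    expect_equal(arch$N, N)
    # columns ending in conv features: M = spatial positions x channels
    last_fc <- arch$layers[[length(arch$layers)]]
    expect_equal(arch$M, last_fc$din)
    expect_gt(arch$M, arch$N)
  }
  # deepest column keeps a valid spatial chain: 32 -> 16 -> 8 -> 4 -> 2
  arch5 <- parse_architecture(cols$D5, c(32, 32, 3), 10)
  expect_equal(arch5$M, 2 * 2 * 256)
})

test_that("grammar violations are rejected with the offending token", {
  expect_error(parse_architecture(c("Conv9-32", "Fc-10"), c(16, 16, 3), 10),
               "Conv9-32")
  expect_error(parse_architecture(c("Conv3-8", "Blob", "Fc-10"),
                                  c(16, 16, 3), 10), "Blob")
  expect_error(parse_architecture(c("Fc-10", "Conv3-8"), c(16, 16, 3), 10),
               "after a fully connected")
  expect_error(parse_architecture(c("Conv3-8", "Fc-12"), c(16, 16, 3), 10),
               "num_classes")
  # pooling below 2 pixels underflows
  toks <- c("Max-pool", "Max-pool", "Max-pool", "Fc-10")
  expect_error(parse_architecture(toks, c(4, 4, 3), 10), "pooled")
})

test_that("a lone Fc head is a linear model on flattened pixels", {
  arch <- parse_architecture("Fc-10", c(16, 16, 3), 10)
  expect_equal(arch$M, 16 * 16 * 3)
  net <- init_network(arch, 1)
  cfg <- synth_config(per_class_count = 3, seed = 1)
  ds <- generate_dataset(cfg)
  fw <- forward_collect(net, ds$test)
  expect_equal(dim(fw$rep), c(30, 768))
})

test_that("logits equal head times representation plus bias everywhere", {
  set.seed(1)
  archs <- list(
    parse_architecture(c("Conv3-bn-6", "Max-pool", "Conv5-8", "Max-pool",
                         "Fc-12", "Fc-5"), c(12, 12, 3), 5),
    parse_architecture(c("Conv5-4", "Max-pool", "Fc-6"), c(8, 8, 2), 6),
    parse_architecture("Fc-4", c(6, 6, 1), 4)
  )
  for (arch in archs) {
    net <- init_network(arch, 3)
    sh <- arch$input_shape
    imgs <- array(stats::runif(7 * prod(sh)), c(7, sh[1], sh[2], sh[3]))
    data <- repnonuniq:::new_image_set(imgs, rep(0L, 7), "rand", 0L)
    fw <- forward_collect(net, data)
    head <- classifier_head(net)
    recon <- fw$rep %*% t(head$W) +
      matrix(head$b, nrow(fw$rep), length(head$b), byrow = TRUE)
    expect_lt(max(abs(fw$logits - recon)), 1e-5)
    expect_equal(dim(fw$rep), c(7, arch$M))
  }
})

test_that("forward pass is deterministic and ties break low", {
  arch <- parse_architecture(c("Conv3-4", "Max-pool", "Fc-6", "Fc-3"),
                             c(8, 8, 3), 3)
  net <- init_network(arch, 9)
  imgs <- array(stats::runif(4 * 8 * 8 * 3), c(4, 8, 8, 3))
  data <- repnonuniq:::new_image_set(imgs, rep(0L, 4), "rand", 0L)
  fw1 <- forward_collect(net, data)
  fw2 <- forward_collect(net, data)
  expect_identical(fw1$logits, fw2$logits)
  # zeroed head with constant bias predicts the argmax of the bias
  i <- length(net$params)
  net$params[[i]]$W[] <- 0
  net$params[[i]]$b <- c(1, 0, 0)
  fw <- forward_collect(net, data)
  expect_true(all(fw$pred == 0L))
})

test_that("shape mismatches are rejected", {
  arch <- parse_architecture(c("Fc-3"), c(8, 8, 3), 3)
  net <- init_network(arch, 1)
  imgs <- array(0, c(2, 6, 6, 3))
  data <- repnonuniq:::new_image_set(imgs, c(0L, 1L), "bad", 0L)
  expect_error(forward_collect(net, data), "shape")
})

test_that("accuracy is the exact-match fraction", {
  expect_equal(accuracy(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(accuracy(c(1, 2, 3), c(3, 1, 2)), 0.0)
  expect_equal(accuracy(c(1, 2, 3, 4), c(1, 2, 3, 0)), 0.75)
  expect_error(accuracy(1:3, 1:4), "length")
})
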