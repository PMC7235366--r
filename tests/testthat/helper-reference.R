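# Shared fixtures, built once per test run and cached. The reference
# configuration is the desk-scale study condition: 10 balanced classes of
# 16 x 16 RGB images (100 per class per split), the quartered 5-layer
# column, 10 epochs of SGD.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

ref_dataset <- function() {
  fixture("ref_dataset", function() generate_dataset(synth_config(seed = 42)))
}

ref_train_config <- function() train_config()

ref_net1 <- function() {
  fixture("ref_net1", function() {
    cfg <- ref_train_config()
    cfg$seed <- 101L
    train_single(cfg, ref_dataset())
  })
}

ref_pair <- function() {
  fixture("ref_pair", function() {
    cfg <- ref_train_config()
    cfg$seed <- 202L
    net2 <- train_single(cfg, ref_dataset())
    repnonuniq:::new_pair_result(ref_net1(), net2, scheme = 1L)
  })
}

ref_reps <- function() {
  fixture("ref_reps", function() {
    repnonuniq:::pair_test_representations(ref_pair(), ref_dataset())
  })
}

# small, fast configuration for training-mechanics tests
tiny_dataset <- function() {
  fixture("tiny_dataset", function() {
    generate_dataset(synth_config(image_side = 8, num_classes = 4,
                                  per_class_count = 25, jitter_pixels = 0,
                                  seed = 7))
  })
}

tiny_train_config <- function(epochs = 4L, learning_rate = 0.1, ...) {
  train_config(tokens = c("Conv3-8", "Max-pool", "Fc-8", "Fc-4"),
               input_shape = c(8, 8, 3), num_classes = 4, epochs = epochs,
               batch_size = 32L, learning_rate = learning_rate, ...)
}
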