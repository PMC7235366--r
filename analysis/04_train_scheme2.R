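#!/usr/bin/env Rscript
# Scheme 2: train the second network toward the pseudo-inverse counterpart
# of the first. Loss = cross-entropy + lambda * mean squared error between
# the penultimate activations and the f(x) = |x|x targets computed through
# the second network's own head frozen at initialization.

library(repnonuniq)

seed <- 42L
out_dir <- "results"
ck <- file.path(out_dir, "checkpoints", "net1.rds")

ds <- generate_dataset(synth_config(seed = seed))
net1 <- if (file.exists(ck)) load_network(ck) else {
  cat("no checkpoint found; training net1 first\n")
  cfg <- train_config(); cfg$seed <- seed + 101L
  train_single(cfg, ds)
}

cfg2 <- train_config(scheme = 2, seed = seed + 303L)
pair <- train_scheme2(cfg2, ds, net1)
reps <- list(fw1 = forward_collect(pair$net1, ds$test),
             fw2 = forward_collect(pair$net2, ds$test))
ev <- explained_variance(reps$fw1$rep, reps$fw2$rep, seed = seed)

cat(sprintf("accuracies: net1 %.3f, net2 %.3f (gate %s)\n",
            pair$acc1, pair$acc2, if (pair$gate) "passed" else "FAILED"))
cat("mean per-unit Euclidean residual by epoch:\n")
cat(sprintf("  %s\n", paste(sprintf("%.0f", pair$euclid_by_epoch),
                            collapse = " ")))
cat(sprintf("residual fell to %.1f%% of its first-epoch value\n",
            100 * pair$euclid_by_epoch[length(pair$euclid_by_epoch)] /
              pair$euclid_by_epoch[1]))
cat(sprintf("headline EV between the pair: %.3f\n", ev$headline_mean_ev))

save_network(pair$net2, file.path(out_dir, "checkpoints", "net2_scheme2.rds"))
jsonlite::write_json(
  list(seed = seed, lambda = cfg2$scheme2_lambda,
       transform = cfg2$transform_name,
       acc1 = pair$acc1, acc2 = pair$acc2, gate = pair$gate,
       euclid_by_epoch = pair$euclid_by_epoch,
       headline_ev = ev$headline_mean_ev),
  file.path(out_dir, "scheme2_summary.json"),
  auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("wrote", file.path(out_dir, "scheme2_summary.json"), "\n")
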