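#' @name experiments
#' @title Equivalence experiments over a similar-performing pair
#'
#' @description Drivers for the four analyses run on a similar-performing
#' pair of networks: (i) EV on the standard test set, including the subset
#' correctly categorized by both networks; (ii) EV under additive Gaussian
#' pixel noise over a sigma grid; (iii) EV as a function of stimulus-set
#' size by seeded resampling; (iv) EV between subsets of the most selective
#' (highest-kurtosis) neurons. Each driver returns an `experiment_report`:
#' a data frame of per-condition rows plus a provenance attribute holding
#' every seed and grid needed to reproduce it.
NULL

pair_test_representations <- function(pair, data) {
  fw1 <- forward_collect(pair$net1, data$test)
  fw2 <- forward_collect(pair$net2, data$test)
  list(fw1 = fw1, fw2 = fw2,
       correct_both = which(fw1$pred == data$test$labels &
                              fw2$pred == data$test$labels),
       correct_either = which(fw1$pred == data$test$labels |
                                fw2$pred == data$test$labels))
}

new_experiment_report <- function(rows, name, provenance) {
  structure(rows, class = c("experiment_report", class(rows)),
            report_name = name, provenance = provenance)
}

check_gate <- function(pair) {
  if (!pair$gate)
    warning(sprintf(
      "pair failed the similar-performance gate (|%.3f - %.3f| > %.2f)",
      pair$acc1, pair$acc2, pair$gate_threshold))
}

#' EV on the standard test set, all inputs and correct-only inputs
#'
#' Two rows: headline EV over every test stimulus, and over the stimuli
#' correctly categorized under `correct_rule` (default: by BOTH networks, so
#' the two representations are evaluated on a common stimulus set;
#' `"either"`, `"net1"`, `"net2"` are available readings). A correct subset
#' smaller than `min_correct` is flagged in its row, never dropped.
#'
#' @param pair A `pair_result` passing the similar-performance gate.
#' @param data Dataset whose `test` split provides the stimuli.
#' @param ev_seed Seed for the EV fit/eval split.
#' @param min_correct Minimum correct-subset size before flagging.
#' @param correct_rule One of "both", "either", "net1", "net2".
#' @param reps Optional precomputed [pair_test_representations()].
#' @return An `experiment_report` with columns condition, acc1, acc2,
#'   headline_ev, n_stimuli, flagged.
#' @export
run_standard_ev <- function(pair, data, ev_seed = 1L, min_correct = 50L,
                            correct_rule = c("both", "either", "net1",
                                             "net2"),
                            reps = NULL) {
  correct_rule <- match.arg(correct_rule)
  check_gate(pair)
  if (is.null(reps)) reps <- pair_test_representations(pair, data)
  labels <- data$test$labels
  correct <- switch(correct_rule,
    both = reps$correct_both,
    either = reps$correct_either,
    net1 = which(reps$fw1$pred == labels),
    net2 = which(reps$fw2$pred == labels))
  ev_all <- explained_variance(reps$fw1$rep, reps$fw2$rep, seed = ev_seed)
  ev_cor <- explained_variance(sub_rep_rows(reps$fw1$rep, correct),
                               sub_rep_rows(reps$fw2$rep, correct),
                               seed = ev_seed)
  rows <- data.frame(
    condition = c("all", paste0("correct_", correct_rule)),
    acc1 = pair$acc1, acc2 = pair$acc2,
    headline_ev = c(ev_all$headline_mean_ev, ev_cor$headline_mean_ev),
    n_stimuli = c(ev_all$n_stimuli, ev_cor$n_stimuli),
    flagged = c(FALSE, length(correct) < min_correct))
  new_experiment_report(rows, "standard_ev",
                        list(ev_seed = ev_seed, correct_rule = correct_rule,
                             min_correct = min_correct,
                             acc1 = pair$acc1, acc2 = pair$acc2))
}

#' Default noise grid
#' @return The sigma grid used throughout: 0.01-0.05, 0.07, 0.1.
#' @export
default_sigma_grid <- function() c(0.01, 0.02, 0.03, 0.04, 0.05, 0.07, 0.1)

#' EV and accuracy under additive Gaussian pixel noise
#'
#' One row per noise level (a sigma = 0 baseline is prepended): noise is
#' drawn once per sigma with a derived seed and the same noisy stimuli are
#' shown to both networks, so accuracy and EV are measured on identical
#' inputs. The sigma = 0 row reproduces the all-inputs standard row exactly.
#'
#' @inheritParams run_standard_ev
#' @param sigma_grid Noise standard deviations (on the `[0, 1]` pixel scale).
#' @param noise_seed Base seed; level i uses `noise_seed * 100 + i`.
#' @return An `experiment_report` with columns sigma, acc1, acc2,
#'   headline_ev, n_stimuli.
#' @export
run_noise_grid <- function(pair, data, sigma_grid = default_sigma_grid(),
                           noise_seed = 1L, ev_seed = 1L) {
  check_gate(pair)
  sigmas <- c(0, sigma_grid)
  rows <- vector("list", length(sigmas))
  for (i in seq_along(sigmas)) {
    s <- sigmas[i]
    noisy <- add_gaussian_noise(data$test, s,
                                seed = noise_seed * 100L + i)
    fw1 <- forward_collect(pair$net1, noisy)
    fw2 <- forward_collect(pair$net2, noisy)
    ev <- explained_variance(fw1$rep, fw2$rep, seed = ev_seed)
    rows[[i]] <- data.frame(
      sigma = s,
      acc1 = accuracy(fw1$pred, noisy$labels),
      acc2 = accuracy(fw2$pred, noisy$labels),
      headline_ev = ev$headline_mean_ev, n_stimuli = ev$n_stimuli)
  }
  new_experiment_report(do.call(rbind, rows), "noise_grid",
                        list(sigma_grid = sigma_grid,
                             noise_seed = noise_seed, ev_seed = ev_seed))
}

#' Default subset-size grid for a stimulus pool
#' @param pool_size Number of stimuli in the pool.
#' @return Ten evenly spaced sizes from `pool_size / 10` to `pool_size`.
#' @export
default_size_grid <- function(pool_size) {
  unique(round(seq(pool_size / 10, pool_size, length.out = 10)))
}

#' EV as a function of stimulus-set size by resampling
#'
#' For each subset size, draws `resamples` seeded subsets (without
#' replacement) from the pool — the full test set, or only the stimuli both
#' networks categorize correctly — and reports the mean and standard
#' deviation of the headline EV over the draws. Sizes exceeding the pool are
#' skipped with a warning. At the full pool size every draw is a permutation
#' of the same stimuli, so the sd is exactly 0 and the mean equals the
#' standard all-inputs EV.
#'
#' @inheritParams run_standard_ev
#' @param size_grid Subset sizes; defaults to [default_size_grid()] of the
#'   pool.
#' @param resamples Draws per size (default 10).
#' @param resample_seed Base seed; size i, draw r uses
#'   `resample_seed * 10000 + i * 100 + r`.
#' @param pool `"all"` or `"correct_both"`.
#' @return An `experiment_report` with columns size, mean_ev, sd_ev,
#'   n_resamples.
#' @export
run_size_resampling <- function(pair, data, size_grid = NULL,
                                resamples = 10L, resample_seed = 1L,
                                ev_seed = 1L,
                                pool = c("all", "correct_both"),
                                reps = NULL) {
  pool <- match.arg(pool)
  check_gate(pair)
  if (is.null(reps)) reps <- pair_test_representations(pair, data)
  pool_rows <- if (pool == "all") seq_len(nrow(reps$fw1$rep))
               else reps$correct_both
  if (is.null(size_grid)) size_grid <- default_size_grid(length(pool_rows))
  out <- list()
  for (i in seq_along(size_grid)) {
    sz <- size_grid[i]
    if (sz > length(pool_rows)) {
      warning(sprintf("size %d exceeds pool (%d); row skipped",
                      sz, length(pool_rows)))
      next
    }
    evs <- numeric(resamples)
    for (r in seq_len(resamples)) {
      dseed <- resample_seed * 10000L + i * 100L + r
      old <- .Random.seed_save()
      set.seed(dseed)
      rows_r <- sample(pool_rows, sz)
      .Random.seed_restore(old)
      ev <- explained_variance(sub_rep_rows(reps$fw1$rep, rows_r),
                               sub_rep_rows(reps$fw2$rep, rows_r),
                               seed = ev_seed)
      evs[r] <- ev$headline_mean_ev
    }
    out[[length(out) + 1]] <- data.frame(
      size = sz, mean_ev = mean(evs), sd_ev = stats::sd(evs),
      n_resamples = resamples)
  }
  new_experiment_report(do.call(rbind, out), paste0("size_resampling_", pool),
                        list(size_grid = size_grid, resamples = resamples,
                             resample_seed = resample_seed,
                             ev_seed = ev_seed, pool = pool))
}

#' EV between subsets of the most selective neurons
#'
#' Ranks each network's penultimate neurons by response kurtosis over the
#' same test stimuli, then for each percentage p selects the top-p% most
#' selective neurons independently per network and computes the subset EV.
#' Undefined-kurtosis (zero-variance) neurons rank last; if every neuron is
#' undefined the analysis errors. The p = 100% row reproduces the standard
#' all-inputs row exactly.
#'
#' @inheritParams run_standard_ev
#' @param percentages Fractions in (0, 1]; default 0.1 to 1 in steps of 0.1.
#' @return An `experiment_report` with columns percentage, n_neurons_1,
#'   n_neurons_2, headline_ev.
#' @export
run_selectivity_analysis <- function(pair, data,
                                     percentages = seq(0.1, 1, by = 0.1),
                                     ev_seed = 1L, reps = NULL) {
  check_gate(pair)
  if (is.null(reps)) reps <- pair_test_representations(pair, data)
  k1 <- selectivity_profile(reps$fw1$rep)
  k2 <- selectivity_profile(reps$fw2$rep)
  if (all(is.na(k1)) || all(is.na(k2)))
    stop("all neurons have undefined kurtosis")
  r1 <- selectivity_ranking(k1)
  r2 <- selectivity_ranking(k2)
  M1 <- length(r1); M2 <- length(r2)
  if (floor(min(percentages) * min(M1, M2)) < 1)
    stop("smallest percentage selects no neurons")
  rows <- vector("list", length(percentages))
  for (i in seq_along(percentages)) {
    p <- percentages[i]
    # top-p% SETS; sorted so the p = 100% run is column-identical to the
    # unrestricted analysis
    idx1 <- sort(r1[seq_len(max(1L, floor(p * M1)))])
    idx2 <- sort(r2[seq_len(max(1L, floor(p * M2)))])
    ev <- ev_between_neuron_subsets(reps$fw1$rep, reps$fw2$rep, idx1, idx2,
                                    seed = ev_seed)
    rows[[i]] <- data.frame(percentage = p, n_neurons_1 = length(idx1),
                            n_neurons_2 = length(idx2),
                            headline_ev = ev$headline_mean_ev)
  }
  new_experiment_report(do.call(rbind, rows), "selectivity",
                        list(percentages = percentages, ev_seed = ev_seed))
}

#' Write an experiment report to disk
#'
#' Emits `<name>.csv` (the rows) and `<name>_provenance.json` (seeds, grids
#' and settings). Re-running with identical inputs reproduces byte-identical
#' files.
#'
#' @param report An `experiment_report`.
#' @param out_dir Writable directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "experiment_report"))
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  name <- attr(report, "report_name")
  csv_path <- file.path(out_dir, paste0(name, ".csv"))
  json_path <- file.path(out_dir, paste0(name, "_provenance.json"))
  utils::write.csv(as.data.frame(report), csv_path, row.names = FALSE)
  jsonlite::write_json(attr(report, "provenance"), json_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(csv = csv_path, json = json_path))
}
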