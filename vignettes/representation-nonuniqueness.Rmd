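---
title: "Non-uniqueness of categorization-trained object representations: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-uniqueness of categorization-trained object representations: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question

Goal-driven models of the primate ventral stream train a deep convolutional
network (DCNN) on object categorization alone and read out the
penultimate-layer activations as the model of inferotemporal (IT) cortex
responses. That program implicitly assumes the categorization objective pins
down the representation — that two networks equally good at the task carry
essentially the same penultimate code, where "the same" is understood up to a
linear transformation (the convention under which model activations are
regressed onto neural recordings).

This package implements the counter-argument and its quantification:

1. **Argmax invariance.** A softmax classifier's decision depends only on
   the order of the logits. For any elementwise strictly increasing `f`,
   the logits `x'` and `f(x')` give identical top-1 (indeed top-K)
   categorization on every input. `categorization_agreement()` checks this
   exactly; `monotone_transform()` refuses non-increasing maps.
2. **Pseudo-inverse counterexample.** Write the classifier head as
   `x' = W x + b` with `W` an `N x M` matrix, `M > N`, full row rank. For
   any target logits `t` the minimum-norm preimage
   `v = (W'W)^+ W'(t - b)` satisfies `W v + b = t` *exactly*. Applying this
   to `t = f(x')` with a second head `(W2, b2)` yields, stimulus by
   stimulus, a representation `y` whose categorization is identical to the
   original network's, while `y` is a *non-linear* function of `x` — no
   linear map relates them. `construct_counterpart_representation()` builds
   `y` for a whole stimulus set and certifies `|W2 y + b2 - f(x')|` along
   the way.
3. **Explained variance (EV).** The degree of linear relatedness between
   two representation matrices is measured per target neuron as
   `1 - SS_res / SS_tot` under the best affine map, and summarized by a
   symmetrized mean (`explained_variance()`). EV is 1 (to tolerance) iff
   the relation is affine on the evaluated stimuli; independent
   representations score near 0.

The experiments then ask how far two *trained* networks — same architecture,
different random initializations, matched accuracy (a "similar performing
pair") — are from linear equivalence, and how that depends on input noise,
stimulus-set size, and neuron selectivity.

## The synthetic stimulus set

Everything runs at desk scale on generated stimuli rather than a downloaded
benchmark. `generate_dataset()` emulates the *structure* of small
natural-image classification sets: `K = 10` balanced classes of
`16 x 16 x 3` images with pixel values in `[0, 1]`, disjoint train/test
splits of 100 images per class each. Each class is a smooth deterministic
template (a seeded four-term random Fourier series per channel, contrast
0.9 of the intensity range), and each stimulus adds a circular translation
jitter of up to 1 pixel per axis and i.i.d. Gaussian pixel noise
(sd 0.05), clipped to `[0, 1]`. The class-conditional structure is strong
enough that small CNNs reach high test accuracy within minutes on one CPU —
the property the analyses need.

What the generator does *not* emulate: natural image statistics, object
pose/scale/clutter variation, and within-class appearance diversity beyond
jitter and noise. Passing results therefore demonstrate the constructions
and the behavior of the EV methodology, not performance claims about
full-scale benchmarks; full-size inputs (e.g. `32 x 32` with the unshrunk
channel widths) remain available through the same configuration surface.

Two stimulus manipulations follow the experimental grids exactly:
`add_gaussian_noise()` adds mean-0 Gaussian noise with sd
`{0.01, 0.02, 0.03, 0.04, 0.05, 0.07, 0.1}` *without* re-clipping to
`[0, 1]` — clipping would truncate the stated noise distribution — and
`subsample_stimuli()` draws seeded subsets without replacement. "Standard
variance" in the source grid is read as standard deviation: values of
0.01–0.1 on a unit intensity scale are only sensible as sd.

## The network engine

No deep-learning framework is involved: the package contains a compact,
fully deterministic CNN engine (vectorized im2col convolutions, 2 x 2
max-pooling, optional batch normalization, fully connected layers, softmax
cross-entropy, SGD with momentum and backpropagation) sufficient for the
small configuration grammar. `parse_architecture()` accepts column-style
token lists — `Conv<k>-<c>`, `Conv<k>-bn-<c>` (k in {3, 5}), `Max-pool`,
`Fc-<u>` — and resolves shapes, the penultimate width `M`, and the class
count `N`. Unstated architectural details are fixed as the conventional
choices: ReLU after every convolution and hidden fully connected layer,
2 x 2 stride-2 pooling, "same" convolution padding (depth, not convolution,
controls spatial shrinkage), fan-in-scaled Gaussian initialization, and
argmax ties broken toward the lowest index so agreement checks are exact.
The *object representation* is the post-ReLU activation vector of the layer
feeding the head; batch-norm layers use frozen running statistics whenever
representations are extracted, so EV inputs are deterministic.

The reference profile is the 5-layer column shrunk for 16 x 16 inputs with
channel widths quartered (`Conv5-8, Max-pool, Conv5-8, Max-pool, Conv5-16,
Max-pool, Fc-16, Fc-10`), giving `M = 16 > N = 10` as the pseudo-inverse
construction requires. A pair trains in about a minute on one CPU.

## Training

Defaults (`train_config()`): 10 epochs, batch 64, SGD momentum 0.9, initial
learning rate 0.02 with cosine decay, global gradient-norm clipping at 5.
The learning rate was chosen so the reference profile converges to its
contract (>= 90% test accuracy, in practice ~100%) across arbitrary
initialization seeds; at 0.01 occasional seeds stall just below it.
Clipping is effectively inert for cross-entropy training and exists for the
second scheme (below). Training is reproducible end to end from
`(config, seed)`: the seed controls initialization and batch shuffling, and
re-running reproduces predictions exactly.

**Scheme 1** (`train_pair_scheme1()`) trains the same architecture twice
from different seeds, cross-entropy only. A pair enters the analyses only
if it passes the similar-performance gate `|acc1 - acc2| <= 0.05`.

**Scheme 2** (`train_scheme2()`) trains the second network with
`CE + lambda * mean((penult - target)^2)`, where the targets are the
pseudo-inverse counterparts of the first network's transformed logits
(`f(x) = |x| x`). The procedure this reconstructs leaves two things open,
resolved as follows:

* *Which head defines the targets?* The second network's own head, frozen
  at initialization. A concurrently trained head would chase its own
  targets; freezing makes the Euclidean objective well-posed. The trainable
  head receives gradients only from the cross-entropy term.
* *The weight `lambda`.* The Euclidean loss is averaged over units and
  batch, so `lambda` carries the scale. At desk scale a fully trained first
  network has logits of order tens; `|x| x` squares them and the targets
  reach magnitudes of order 10^2, so the initial Euclidean loss is ~10^5
  per unit while cross-entropy is ~2. `lambda = 1` lets the Euclidean
  gradient destroy the network in the first batches (dead ReLUs, chance
  accuracy) — this is also why gradient clipping is on by default — and
  `lambda = 0.01` still leaves accuracy seed-dependent. The default
  `lambda = 0.001` produces gate-passing pairs (acc within 5 points)
  with a decreasing residual across all probed seeds. `lambda = 0`
  reduces the loop to scheme 1 exactly, batch by batch.

## Explained variance methodology

The measure itself leaves the map direction, the evaluation split and the
formula unstated; the package fixes them as:

* **Affine map, ordinary least squares.** An intercept column is appended;
  with fewer fit stimuli than coefficients the minimum-norm SVD solution is
  returned with a warning. An optional ridge penalty (default 0, recorded
  in every report) is available for near-singular fits.
* **Held-out evaluation.** Stimuli are split 50/50 into fit and eval sets.
  Without a held-out split, EV tends to 1 mechanically as the neuron count
  approaches the stimulus count. The split is drawn by seed *on sorted
  stimulus ids*, so any row permutation of the same stimuli — e.g. a
  full-size resample — reproduces the identical report, which the
  cross-experiment consistency identities rely on.
* **Per-neuron EV on the eval split**, `1 - SS_res/SS_tot` with `SS_tot`
  about the eval mean. Negative values are retained (not clipped): a
  neuron predicted worse than its mean is evidence of non-linearity, and
  clipping would bias the mean upward. Neurons with (near-)zero eval
  variance are excluded from the directional mean with a logged count; the
  threshold is relative (`SS_tot > max(1e-12, 1e-9 * max SS_tot)`) so
  numerically-silent ReLU units are treated like exactly dead ones.
* **Symmetrized headline.** Both directions are fit on the same split and
  averaged. One caveat follows from the definition: EV is invariant to an
  invertible affine remix of the *source* (same predictor span), but
  remixing the *target* redefines the per-neuron quantities, so only the
  source-direction mean carries that invariance exactly.

On small stimulus subsets the per-neuron EV distribution is heavy-tailed:
an almost-silent neuron that survives the variance threshold can score a
very large negative EV, which inflates the across-resample sd at the
smallest subset sizes. This is visible in the size-resampling analysis and
is precisely why EV needs a modestly large stimulus set to stabilize — the
sd of the headline EV across 10 seeded resamples falls by orders of
magnitude from the smallest subset (a tenth of the pool) to the full pool
(where every draw is a permutation and the sd is exactly 0). Because each
sd is estimated from 10 draws (~24% relative error), the stabilization
check compares levels against the smallest size and the overall trend,
rather than demanding consecutive monotonicity between adjacent plateau
sizes.

**Selectivity** is the Pearson kurtosis `m4 / m2^2` of a neuron's response
distribution over stimuli (Gaussian = 3), the convention of the sparseness
literature; excess kurtosis is a flag away and yields the identical
ranking. Zero-variance neurons have undefined kurtosis and rank last.

## Experiment drivers

All four analyses run over one gate-passing pair and emit CSV tables plus a
JSON provenance block (seeds, grids, settings) from which every row is
reproducible:

* `run_standard_ev()` — EV over all test stimuli and over the subset
  *correctly categorized by both* networks (so both representations are
  evaluated on a common stimulus set; "either"/"net1"/"net2" readings are
  available behind a flag). Undersized correct subsets are flagged, never
  dropped.
* `run_noise_grid()` — a sigma = 0 baseline plus the seven-level noise
  grid; one noise draw per sigma is shared by both networks so accuracy
  and EV are measured on identical stimuli.
* `run_size_resampling()` — ten subset sizes scaled to the pool (a tenth
  of the pool up to the full pool, preserving the ten-point grid shape),
  ten seeded resamples per size, mean and sd of headline EV per size; run
  for the unrestricted and the correct-by-both pool.
* `run_selectivity_analysis()` — kurtosis profiles per network on the same
  stimuli; for each percentage 10%..100% the top-p% most selective neurons
  are chosen independently per network and the subset EV computed. Index
  sets are sorted so the 100% row is column-identical to the standard
  analysis.

Three identities tie the drivers together exactly (same seeds, same split):
the sigma = 0 row, the 100%-selectivity row, and the full-size resampling
row all equal the standard all-inputs EV.

## Problem sizes and runtime

The reference analyses use 1,000 train and 1,000 test stimuli, M = 16
penultimate neurons, and 10 training epochs; a full pipeline run (pair,
counterpart, all four analyses, scheme 2) completes in a few minutes on a
single CPU. These sizes are the package's reference study conditions;
everything scales up by configuration (32 x 32 inputs, the unshrunk
columns, more stimuli) at proportional cost.

## Known limitations

* The analytic constructions are exact at any scale, but the *trained*
  results (EV magnitudes, noise and selectivity trends) are demonstrated on
  synthetic desk-scale stimuli; absolute EV values on natural-image
  benchmarks will differ.
* A single global monotone `f` per construction is implemented; the theory
  also admits per-input transforms, which the experiments do not use.
* Scheme 2's published training procedure is not fully specified by its
  source; the frozen-head target definition and `lambda` are documented
  reconstructions (see above), not reproductions.
* No hypothesis testing across conditions is performed; the analyses are
  descriptive, mirroring the bar/line summaries they emulate.
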