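# repnonuniq

Is the object representation a deep convolutional network learns pinned down
by its categorization objective? Goal-driven models of primate
inferotemporal (IT) cortex assume so: train a DCNN on categorization only,
read out the penultimate layer, regress it onto neural data. `repnonuniq`
implements the counter-argument — categorization-optimal representations are
**non-unique** — and the analyses that quantify it, as an R package plus a
set of numbered analysis scripts.

## The core constructions

Let a network compute logits `x' = W₁x + b₁` from its penultimate
representation `x` (`W₁` is `N × M`, `M > N`), classified by softmax argmax.

* **Argmax invariance.** For any elementwise strictly increasing `f`, the
  logits `x'` and `f(x')` have the same top-K order, hence identical
  categorization on every input — yet for non-linear `f` they are not
  linearly related.
* **Pseudo-inverse counterexample.** For a second full-row-rank head
  `(W₂, b₂)`, the minimum-norm preimage

  `y = (W₂ᵀW₂)⁺ W₂ᵀ (f(x') − b₂)`

  satisfies `W₂y + b₂ = f(x')` *exactly*. So `y` is a representation with
  categorization identical to the original network's on every stimulus,
  while `y` is a non-linear function of `x`: two representations, same
  behavior, no linear map between them.
* **Explained variance (EV).** Linear relatedness of two representation
  matrices is scored per target neuron as `1 − SS_res/SS_tot` under the
  best affine map, fit on a seeded half of the stimuli and evaluated on the
  held-out half, symmetrized over the two directions. EV = 1 iff the
  relation is affine on those stimuli; independent representations score
  near 0.

Around these sit a synthetic stimulus generator (balanced 10-class sets of
16×16 RGB images in `[0,1]` with controllable Gaussian noise), a small
deterministic CNN engine for the column-style architecture grammar
(`Conv5-32 … Max-pool … Fc-64, Fc-10` and friends), two training schemes for
"similar performing pairs" (same architecture, different seeds, matched
accuracy), and experiment drivers for EV under noise, stimulus-set size and
kurtosis-based neuron selectivity. See the methods vignette
(`vignettes/representation-nonuniqueness.Rmd`) for every methodological
choice and its rationale.

## Worked example

The numbered scripts under `analysis/` run the whole study; each prints its
findings and writes tables under `results/`:

```sh
Rscript analysis/01_generate_data.R   # reference stimulus set
Rscript analysis/02_train_pair.R      # similar-performing pair (scheme 1)
Rscript analysis/03_counterexample.R  # analytic counterpart construction
Rscript analysis/04_train_scheme2.R   # pull a second net toward the counterpart
Rscript analysis/05_experiments.R     # the four EV analyses
```

Output of a full run (seed 42, one CPU, a few minutes total):

```
net1 test accuracy: 1.000
net2 test accuracy: 1.000
similar-performance gate (|diff| <= 0.05): passed

label agreement with the original network: 100.0%
max |y' - f(x')| over all stimuli: 1.59e-12
accuracy original 1.000 vs counterpart 1.000 (identical: TRUE)
headline EV between x and y: 0.859 (< 1: no linear relation)

accuracies: net1 1.000, net2 0.953 (gate passed)
residual fell to 96.3% of its first-epoch value
headline EV between the pair: 0.788

(i)   EV all inputs 0.752 | correct-by-both 0.752 (n = 1000)
(ii)  sigma 0 -> 0.1: EV 0.752 -> 0.691, mean accuracy 1.000 -> 1.000
(iii) sd(EV) 55.8548 at size 100 -> 0.0000 at size 1000 (all pool)
(iv)  EV top-10% selective -0.001 -> all neurons 0.752
```

Reading the numbers: the two independently initialized networks are
behaviorally interchangeable (both 100% test accuracy) yet their
representations share only ~75% explained variance — similar performance
does not mean the same representation. The analytic counterpart makes the
point exactly: categorization agrees on all 1,000 test stimuli to
reconstruction error 1.6e-12, while EV stays strictly below 1. EV barely
moves under pixel noise up to sd 0.1, stabilizes once the stimulus set
reaches a few hundred images (the sd at the smallest size is dominated by
occasional extreme negative per-neuron values — see the vignette), and
grows as less-selective (lower-kurtosis) neurons are added.

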