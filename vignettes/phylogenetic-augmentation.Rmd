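---
title: "Phylogenetic augmentation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic augmentation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloaug)
```

## The method

Supervised sequence-to-function models — convolutional networks mapping a
fixed-length one-hot DNA sequence to a measured regulatory activity — are
limited by how much sequence variation the training genome contains.
Phylogenetic augmentation enlarges that variation with evolution itself: at
batch generation, each training sequence is replaced, with probability
`phylo_rate`, by a homolog of that sequence from another species, while the
label stays the one measured for the reference sequence. The premise is
that homologs of a regulatory element are plausible sequence variants under
similar functional constraint, so they are label-preserving transformations
in the same sense as an image crop — approximately, because regulatory
elements also turn over in evolution, which is why the method ends with a
short fine-tuning phase on the original sequences and why the choice of
species matters.

The workflow has three phases:

1. **Preprocessing.** Homologs for every training sequence are extracted
   upstream from a multi-species whole-genome alignment (or, for genic
   sequences, from orthologous gene annotations) and flattened into a
   homolog archive: at most one sequence per (reference id, species),
   resized about its midpoint to the model's input length. The archive is
   the only alignment artefact this package consumes; it can also be
   produced entirely synthetically (see "The simulator" below).
2. **Augmented training.** Batches are drawn per epoch; per item, an
   independent coin with probability `phylo_rate` decides whether the
   reference sequence or a homolog (uniform over the species available for
   that item) is encoded, and an independent coin with probability
   `rc_rate` (default 0.5) applies a reverse complement. Labels are never
   altered. Items with no homolog in the active species set fall back to
   the reference sequence, so batch composition is independent of archive
   coverage. Validation and test data are never augmented.
3. **Fine-tuning.** A short, low-learning-rate phase (default 5 epochs at
   `1e-4`) on original sequences only, which reduces bias from homologs
   whose function has diverged. Reverse complements stay on during
   fine-tuning (a flag can disable them); only the phylogenetic coin is
   frozen.

Two experiment axes probe the method: the **species sweep** augments with
the closest species, then the two closest, and so on in ascending
evolutionary distance from the reference species, reporting each subset's
total evolutionary distance (the branch-length sum of the species tree
pruned to the subset with branch lengths preserved); the **rate sweep**
varies `phylo_rate` on the full species set. **Down-sampling** trains on
random fractions of the training set, baseline and augmented conditions
paired on identical samples, to measure data-efficiency gains.

## Model architectures

Four convolutional families are provided, all ending in one linear layer
per task (sigmoid-transformed at prediction time for binary tasks):

* `deepstarr`: four convolutions (256/60/60/120 filters, kernels 7/3/5/3,
  max-pool 2 after each) and two fully connected layers of 256. At input
  length 200 and one task this is ~4.4 x 10^5 parameters.
* `motif_deepstarr`: one wide convolution (256 filters, kernel 19 — wide
  enough to learn a full transcription-factor motif per filter), global
  max pooling, and two fully connected layers of 256.
* `explainn`: an additive model — 256 single-filter units (kernel 19),
  each globally pooled to a scalar that passes through its own small
  two-layer MLP (1 -> 8 -> 1, a width we fixed as a design default), with
  the prediction an exact linear combination of unit outputs. Additivity
  holds by construction and is asserted in the tests.
* `basset`: three convolutions (300/200/200 filters, kernels 19/11/7,
  pools 3/4/4) and two fully connected layers of 1000, for multi-task
  binary accessibility-style problems.

Every width, kernel, pool and dropout value is overridable in
`architecture_spec()`, so a scaled-down member of a family (fewer filters,
narrower dense layers) can be trained on a laptop-sized problem without
leaving the family. The networks run on a compact engine written against
base R matrix algebra: convolution is evaluated as a sum over kernel
offsets of dense matrix products (so the inner loop is BLAS), with ReLU
activations, max pooling, inverted dropout on the dense layers, Adam, and
analytic backpropagation that the test suite checks against central finite
differences. Convolution layers use bias + ReLU without batch
normalization: at the scales this package targets, normalization layers
add state and nondeterminism without changing any contract we test, and
the engine stays exactly seed-reproducible.

## Randomness and reproducibility

Every stochastic component is seeded, and augmentation randomness is
counter-based: each per-item decision is keyed by (policy seed, epoch,
item index), so the realised batch stream is independent of batch size,
identical across reruns, and resampled across epochs — one sequence can be
represented by a different species every epoch, which is the source of the
method's effective dataset expansion. Identical seeds give bit-identical
loss curves. Weight initialisation is seeded separately per replicate.
None of the package's functions perturb the caller's RNG state.

## Training defaults

Adam with learning rate `2e-3`, squared-error loss for regression or
cross-entropy for binary tasks, up to 100 epochs with early stopping after
10 epochs without validation-loss improvement (best-epoch weights are
restored — the stopping rule only names a patience, and restoring is the
dominant convention), then 5 fine-tuning epochs at `1e-4`. Batch size
defaults to 128 and is logged with results; for the small synthetic
problems in this package's tests we use batch sizes of 8–32 so that an
epoch contains enough optimisation steps to learn from a few hundred
sequences. Accessibility-style setups use 20 epochs and cross-entropy; the
small-dataset binary setup uses 50 epochs, no validation set, no early
stopping, no reverse complements (single-stranded RNA), and a
scrambled-label negative control (`scramble_labels()`).

Early stopping monitors validation loss (not the test metric) — the metric
is computed exactly once, on the held-out split, from the final weights.

## Metrics

`pcc()` is the Pearson correlation (undefined, and rejected, for constant
vectors). `auprc()` integrates the precision–recall curve step-wise with
tied scores collapsed to a single operating point; implementations differ
at ties, so ours is pinned by an independent enumeration oracle in the
tests. `avg_auprc()` is the unweighted mean over tasks, appropriate for
heavily imbalanced multi-task classification.

## The simulator

`generate_dataset()` + `evolve_homologs()` produce a fully synthetic
benchmark in which every claim about the method can be exercised without
external data:

* Reference sequences are i.i.d. draws from a base composition, with
  `k ~ Poisson(lambda)` planted consensus-motif instances at
  non-overlapping uniform positions. Labels follow either a linear rule
  (sum of instance effects + Gaussian noise) or a Bernoulli rule with a
  logistic link on the same sum — abstract stand-ins for enhancer-activity
  regression and RNA-binding classification.
* Homologs are evolved independently along each path from the reference
  leaf of a user-supplied species tree under Jukes–Cantor substitution:
  a neutral site differs from the reference with probability
  `0.75 * (1 - exp(-4 * mu * d / 3))` at tree distance `d` (the closed form
  the tests check), and sites inside motif instances evolve at
  `conservation * mu` — elevated conservation at functional positions.
* Element turnover is modelled by a per-branch "kill" probability: with
  probability `kill_rate` per edge on the path, a motif instance loses its
  constraint, after which its sites drift neutrally over the whole path
  (a deliberate simplification of drift-from-the-kill-point; it preserves
  the property that matters, namely that loss accumulates with tree
  depth). A killed homolog keeps its reference label — exactly the
  label-noise hazard that motivates conservative species choice and
  fine-tuning.
* Indels are off by default so all homologs share the reference length;
  enabling them routes homologs through midpoint resizing.

What the simulator does **not** emulate: assay count noise, chromatin
context, motif syntax/spacing grammars, GC isochores, alignment errors,
and correlated turnover across sister species (kills are independent per
species). Passing the directional tests below therefore demonstrates that
the machinery behaves as designed under the stated evolutionary model, not
that equally sized gains will appear on any particular real assay.

## Study conditions used by the tests and the acceptance script

These sizes were chosen once as desk-scale conditions (single CPU, minutes
per experiment) and are stated here so results are interpretable:

* Regression benchmark: 1000 sequences of 200 bp (500 train / 250 val /
  250 test by chromosome), one planted 8-bp motif, `lambda = 1`, label
  noise sd 0.2; caterpillar tree of 10 species at distances 0.05–0.5
  substitutions/site from the reference; `mu = 0.4`,
  `conservation = 0.05`, no turnover. Model: `motif_deepstarr` scaled to
  32 filters and 32/32 dense units; 15 epochs + 5 fine-tuning epochs.
  Down-sampled runs (10% of the training set) use batch size 8 and
  25 + 5 epochs so that 50 sequences still yield enough gradient steps.
* Binary (RNA-binding-style) benchmark: 500 sequences of 200 bp, motif
  `TGTAAATA` with effect 4 on a logistic link (intercept -2), no reverse
  complements, cross-entropy loss; global importance analysis with 1000
  backgrounds of 200 bp.
* Species sweep: 600 sequences; deeper divergence (`mu = 1`) with
  turnover `kill_rate = 0.4` against a no-turnover control.

## Numerical and design choices

* **Midpoint resizing tie-breaks**: an odd trim drops the extra base on
  the right; an odd pad adds the extra `N` on the right. Fixed and tested.
* **Encoding**: channels A,C,G,T; `N` is an all-zero row. Coordinates are
  0-based half-open internally (BED convention).
* **First-match rule**: when an alignment yields several homologs for one
  (reference, species) pair, the first in input order is kept, making
  archive construction deterministic given input order.
* **Uniform species sampling**: a homolog is drawn uniformly over the
  species available for that item; the species-subset mechanism, not the
  sampling weights, controls divergence exposure.
* **Empty homolog sets** fall back to the reference sequence, which makes
  the `phylo_rate = 0` pipeline exactly equivalent to a plain loader (an
  equivalence asserted bit-for-bit in the tests).
* **Tree handling**: equal distances are broken lexicographically by
  species name; unrooted trees are accepted (path distances are
  rooting-invariant); edges must carry finite non-negative branch lengths
  or parsing is rejected, since distances would be undefined.
* **Sweep budgets** include the reference leaf in every pruned subset, so
  a one-species subset has the budget of the reference-to-species path.
* **Degenerate inputs**: all-`N` sequences encode to zero matrices and
  must produce finite predictions; constant prediction vectors make the
  Pearson correlation undefined and are rejected rather than silently
  returned as `NA`; a non-finite training loss aborts the run with a
  diagnostic rather than continuing on `NaN` weights.

## Known limitations

* The built-in engine is CPU-bound and meant for scaled-down experiments
  and method development; reproducing published-scale accessibility runs
  (millions of 600-bp peaks) is out of its scope.
* `N`-containing homologs are kept by default (`drop_n = FALSE` exposes
  the filter); masking information in lowercase FASTA is discarded.
* The homolog archive is one-sequence-per-species; alignment-graph
  traversal, liftover and ortholog retrieval are upstream concerns.
* GIA here is the paired-insertion design only; attribution methods
  (saliency, in-silico mutagenesis scans) are deliberately not included.
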