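---
title: "Imputing single-cell RNA-seq dropouts with sparsity-penalized stacked denoising autoencoders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imputing single-cell RNA-seq dropouts with sparsity-penalized stacked denoising autoencoders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scsdae)
```

## The problem

Single-cell RNA-seq expression matrices are dominated by zeros. Some are
biological — the gene is simply not expressed in that cell — but many are
technical: the transcript was present and missed because of inefficient
mRNA capture or shallow sequencing. Downstream analyses (correlation
structure, differential expression, clustering) are distorted by these
false zeros, and imputation methods that refuse to distinguish the two
kinds of zero either leave the damage in place or, worse, overwrite true
zeros and invent biology that is not there.

The model implemented here threads that needle with a single scalar knob.
An autoencoder is fit to the normalized expression matrix under a mixture
loss: mean squared reconstruction error over the *observed* (non-zero)
entries of each cell, plus an L1 penalty, weighted by `alpha`, on the
network's output at that cell's *zero* entries,

$$
L(x, x') \;=\; \frac{1}{\#\{j: x_j>0\}}\sum_{j:\,x_j>0}(x_j-x_j')^2
\;+\; \alpha\,\frac{1}{\#\{j: x_j=0\}}\sum_{j:\,x_j=0}\lvert x_j'\rvert .
$$

The MSE term anchors the reconstruction to what was measured. The L1 term
uses the information in the zeros without trusting them as measurements: it
shrinks the output at zero positions, so the network only leaves a zero
entry substantially non-zero when the observed entries of similar cells
give it a strong reason to. Two ablations bracket this choice and are
implemented as variants: `sdae` (plain MSE over all entries — treats zeros
as trustworthy measurements) and `sdae0` (MSE over observed entries only,
`alpha = 0` — ignores zeros entirely and therefore happily fills all of
them). Observed values are never altered: the final matrix is
`x_imputed = x_out * (1 - m) + x * m` with `m = I(x > 0)`, so imputation
touches only zeros.

## Preprocessing

Cells expressing no genes and genes expressed in no cells are removed
(cells first, then genes; repeated to a fixed point, though one pass
suffices for non-negative data). Each cell is then scaled to counts per
million and log-transformed with pseudocount 1,
`x = log(count / libsize * 1e6 + 1)`, which maps zero counts to exactly
zero — a property the mask and the loss both rely on. The log base is a
convention, not a measurement; we use the natural log, as the field's
standard toolkits do, and expose `log_base` for users who prefer log2.
Non-integer inputs (microarray-style intensities) pass through the same
formula unchanged.

## Architecture and training

The network is a symmetric fully connected autoencoder. The reference
architecture is `n`-500-500-2000-10: encoder widths `dims = c(500, 500,
2000, 10)` with the 10-unit bottleneck last, mirrored by the decoder. All
hidden layers use ReLU except the bottleneck and the final output, which
are linear — the output must be free to match the full dynamic range of
log-expression. For the small matrices used in examples and tests we use
proportionally smaller stacks (e.g. `c(128, 32)` or `c(64, 16)`); the
architecture is a capacity knob, not part of the loss.

Deep unsupervised networks are hard to fit on small datasets, so training
is greedy and layer-wise, in the classic denoising-autoencoder tradition:

1. **Pretraining.** Layer 1 is trained as a one-hidden-layer denoising
   autoencoder: the input is corrupted by independently zero-masking each
   entry with probability `corruption_rate = 0.2`, and the network must
   reconstruct the *uncorrupted* input under the variant loss. The trained
   encoder is then applied to the uncorrupted data to produce the hidden
   representation, and each deeper layer repeats the procedure on the
   previous representation, using plain MSE (the mixture loss is only
   meaningful at the data layer, where zeros have a meaning).
2. **Stacking and fine-tuning.** The pretrained encoders and decoders are
   assembled into the full symmetric network and fine-tuned end to end
   *without* corruption under the variant loss. With zero fine-tuning
   steps the stacked forward pass is exactly the composition of the
   pretrained layers — a useful identity that the test suite checks.

"Iterations" are minibatch gradient steps, not epochs: minibatches of
`batch_size = 256` cells are drawn by seeded shuffling with cycling (for
datasets smaller than the batch size, the whole dataset is one batch). The
defaults are 1000 pretraining steps per layer and 2000 fine-tuning steps,
optimized with Adam (learning rate 1e-3, beta1 0.9, beta2 0.999, epsilon
1e-7). Weights are initialized Glorot-uniform from the fit's seed; the
entire fit is a deterministic function of the input and the seed. Training
aborts with a diagnostic if the loss becomes non-finite.

Two conventions deserve a note because the underlying choices were
genuinely open:

- **What gets corrupted.** Corruption indicators are drawn for every
  entry; zero entries are unaffected by construction, so this is
  distributionally identical to corrupting only observed entries. A
  `corrupt_nonzero_only` switch changes the random-number accounting for
  users who want the restricted reading.
- **Per-cell degenerate index sets.** A cell with no zeros contributes no
  sparsity term; a cell with no observed entries (impossible after
  filtering) would contribute no MSE term. The minibatch loss is the mean
  of per-cell losses.
- **Clipping.** The linear output layer can produce small negative values;
  imputed entries are clamped at zero by default (`clip = TRUE`), since
  log-expression is non-negative. The raw output is kept in the fit object.

Choosing `alpha`: `1.0` is a good default for single-cell data, and values
in `(0.1, 1)` are the recommended range. When the zeros are known to be
almost entirely technical — e.g. bulk profiles artificially downsampled,
where a zero carries no evidence of true absence — the penalty should be
nearly off (`alpha = 0.001`). Larger `alpha` monotonically shrinks the
output at zero positions (the suite verifies this on a fixed dataset over
`alpha` in {0.01, 0.1, 1, 10}); smaller `alpha` imputes more aggressively
and admits more false positive signals.

## The simulators: what they emulate, and what they do not

Because truth is unknowable in real single-cell data, the package ships
three synthetic designs with full ground truth.

**Smooth bulk-like profiles + logistic capture dropout**
(`make_bulklike_profiles()`, `logistic_downsample()`). Emulates a dense
developmental time course: each gene's log-expression follows a
Gaussian-kernel-smoothed random trajectory (length-scale
`trajectory_smoothness = 0.15` of the series, 206 samples by 2000 genes by
default), so the sample–sample correlation matrix is banded around the
diagonal. Dropout follows a logistic capture model — the logit of the
probability that a value is captured is linear in its log magnitude — with
the intercept solved numerically so the expected zero fraction hits the
requested target (0.5–0.9 in the benchmark design); the slope is a free
parameter, default 1. This captures the two properties the recovery
benchmark needs (ordered correlation structure; value-dependent missing
not-at-random dropout) and nothing else: there is no batch structure, no
count noise, and the trajectory is stationary, so good recovery here does
not promise good recovery on rhythmic or switch-like real programs.

**Negative-binomial two-group counts** (`simulate_nb_two_group()`). 1000
cells in two balanced groups, 500 genes with log-uniform base means in
[1e3, 1e4], half differentially expressed; fold change 3 with alternating
direction (so library sizes stay comparable) and NB size 0.5. Fold change
and dispersion are not dictated by the design it mirrors and are exposed
as parameters; the defaults are one-time choices in the realistic range
for highly overdispersed single-cell counts. Zeros here arise from NB
sampling itself, not from a separate dropout channel, so the false-signal
analysis asks exactly the right question: does imputing sampling zeros
manufacture gene–gene correlations that were never there? Detection uses
Spearman correlation with Bonferroni control at family-wise 0.05, scored
against DE–DE pairs (the pairs genuinely correlated through the shared
group structure).

**Spiked artificial genes** (`spike_artificial_genes()`). Five artificial
genes are appended to a normalized two-group matrix: `N(0, 0.1)` in group
A (clamped at zero, so roughly half the group-A values are true zeros)
and `N(2, 0.1)` in group B, then positive spiked values are dropped to
bring the spiked columns to 50% zeros overall. Group-A zeros must stay
zero; group-B zeros must be filled toward 2. The per-group MAE split makes
over- and under-imputation separately visible: the observed-only `sdae0`
loss fills group-A zeros (false positives), while the mixture loss holds
them near zero at a modest cost in group-B aggressiveness — the
qualitative signature the method is designed for. The *base* matrix for
this experiment is an NB two-group simulation with low means
(`mean_low = 0.05`, `mean_high = 10`, ~60% zeros): the experiment emulates
spiking genes into a real sparse UMI matrix, and the sparsity matters
mechanically, because the per-cell L1 weight is `alpha / n_zeros` — on an
unrealistically dense base the penalty on each individual zero would be
tens of times stronger than it ever is on real data.

## Problem sizes and numerical checks

The test suite runs every design at desk scale: the recovery benchmark at
206 x 2000 with an `c(128, 32)` stack, 200 pretraining steps per layer and
400 fine-tuning steps; the false-signal and spiked-gene experiments at
their design sizes (1000 x 500 and 740 x 505) with `c(64, 16)` stacks.
These sizes were chosen so a full run completes in minutes on one core
while leaving each experiment's qualitative contrast (imputed vs dropout
vs ablation) clearly resolved; the package itself has no size-dependent
logic, and the reference architecture is the default for real data.
Stochastic claims are asserted over five seeds with an explicit majority
threshold rather than on a single lucky draw. The loss implementations are
checked against scalar per-element oracles to 1e-10, and all network
gradients against central finite differences.

## Known limitations

- The method imputes on the logCPM scale and returns that scale; it does
  not model counts, so no statistical uncertainty accompanies the imputed
  values (in contrast to probabilistic ZINB approaches).
- A cell's observed entries drive its reconstruction; cell types absent
  from training data, or represented by a handful of cells, may be
  reconstructed toward better-represented neighbours.
- `alpha` trades false positives (too small) against under-imputation (too
  large) and the right value depends on the true technical-zero fraction,
  which is unknowable; the default is a compromise, not an estimate.
- Determinism holds for fixed seed, BLAS, and platform; different linear
  algebra backends can differ in the last bits.
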