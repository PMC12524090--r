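---
title: "Confidence-guided pseudo-labelling with dual-branch fusion: methods and design"
author: "pseudofuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confidence-guided pseudo-labelling with dual-branch fusion: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudofuse)
```

## The problem

Supervised image classifiers degrade sharply when only a small fraction of
the training images carry labels — the common situation in medical imaging,
where expert annotation of MRI scans is the bottleneck while unlabelled
scans are plentiful. Semi-supervised *self-training* addresses this by
letting a model trained on the labelled subset annotate the unlabelled pool
itself: predictions whose softmax confidence clears a threshold are
promoted to *pseudo-labels*, merged into the training set, and the model is
retrained. `pseudofuse` implements this loop for multi-class grayscale
image classification, together with the dual-branch, feature-fusion
variant and the statistical machinery needed to decide whether the
semi-supervised gain is real.

## The model

Let $D_l = \{(x_i, y_i)\}_{i=1}^{N_l}$ be the labelled set with
$y_i \in \{1, \dots, C\}$ and $D_u = \{x_j\}_{j=1}^{N_u}$ the unlabelled
pool, and $f_\theta$ a network emitting softmax class probabilities.
Training minimises

$$L_{total} = L_{sup} + \lambda\, L_{unsup},$$

where $L_{sup}$ is the mean categorical cross-entropy over the genuine
labels and $L_{unsup}$ the mean cross-entropy over the pseudo-labelled set

$$\tilde D_u = \{(x_j, \hat y_j) : \max f_\theta(x_j) \ge \tau\},
\qquad \hat y_j = \arg\max f_\theta(x_j),$$

with the threshold boundary *inclusive* ($\ge \tau$, tested at the
boundary). $\lambda$ defaults to 1 and may ramp linearly over the first
`rampEpochs` epochs (`lossConfig()`); the weighting is applied per
mini-batch as `mean CE(labelled) + λ · mean CE(pseudo)`, the batch-level
analogue of the two-term objective.

**Iterative rejection.** Pseudo-labelling runs for up to $T$ iterations
under a non-increasing threshold schedule (default $0.98, 0.95, 0.90$):
iteration $t$ scores the *currently remaining* pool at $\tau_t$, merges
the accepted samples, retrains, and passes the rejects to iteration
$t+1$. Samples still rejected after the last iteration are permanently
excluded. A constant schedule (e.g. $0.98, 0.98, 0.98$) is equally
supported: it re-scores the rejects of earlier rounds after retraining at
a fixed bar. Every run records a ledger of
`(iteration, threshold, accepted, rejected)` whose invariant —
`accepted + rejected` equals the pool size of that iteration — is asserted
in the tests.

**Consensus voting.** In the dual-branch mode two independently trained
networks score the pool. With two voters, "majority voting" is agreement:
a pseudo-label is accepted only when both argmax classes coincide and the
combined confidence (the maximum of the two, by default; the mean is
available) clears the threshold. Disagreement rejects the sample by
default — the conservative reading, protecting label purity; a
`max_confidence` policy that trusts the more confident voter is available
as a config option. The agreed-confidence and disagreement conventions are
deliberate design choices: with two voters there is no majority to fall
back on, and the defaults favour precision of the accepted set over its
size.

**Dual-branch fusion.** The two branches see two renderings of the same
image: a grayscale view (168×168×1 at full scale) into a compact
texture-oriented CNN — four convolutions (64 filters of 5×5 twice, then
128 filters of 4×4 twice), max-pooling after each (3×3 first, 2×2
thereafter), a flatten and a 512-unit ReLU layer — and an RGB
(channel-replicated) view (224×224×3) into a pluggable feature extractor
whose head is global average pooling → Dropout(0.5) → 128-unit ReLU →
Dropout(0.5) → softmax. The 512- and 128-dimensional penultimate
activations are concatenated into a 640-dimensional fused vector,
classified by Dropout(0.5) → 256-unit ReLU → Dropout(0.3) → softmax. The
fusion head trains on the merged (labelled + accepted pseudo-labelled)
set; by default the branches also get a refresh pass on the merged set
after each iteration.

No pretrained weights are required anywhere: the transfer branch accepts
any function mapping an image batch to a 4-d feature map (a pretrained
residual network can be plugged in where one is available offline), and
its built-in default is a small randomly initialised convolutional stack
trained end-to-end.

## Optimisation

The custom CNN trains with Adam at learning rate $10^{-3}$,
$\beta_1 = 0.85$, $\beta_2 = 0.9925$; the transfer head with Adamax at
$10^{-4}$; the fusion head with Adam at $10^{-4}$. A
"reduce-LR-on-multiple-accuracies" callback multiplies the learning rate
by 0.75 whenever validation accuracy surpasses one of the thresholds
$0.96, 0.99, 0.9935$ (each fires once, floor $10^{-4}$). A best-checkpoint
rule restores the weights of the epoch with the highest validation
accuracy; when no validation set is supplied, 10% of the training split is
carved out.

Two degenerate-input rules matter at desk scale. First, when the carved
validation set has fewer than 8 images, both the checkpoint rule and the
LR callback are disabled: a 2-image validation accuracy is noise, and
acting on it demonstrably froze models at early epochs. Second, the tiny
profiles (below) carry desk-appropriate learning rates — Adamax $10^{-3}$
for the tiny transfer branch and Adam $10^{-3}$ for a narrow fusion head —
because the full-scale rates assume thousands of images and dozens of
epochs per unit of progress.

All computation runs on a base-R network engine (im2col convolution with
precomputed gather indices, non-overlapping max pooling with first-index
tie-breaking, dense layers, inverted dropout, Adam/Adamax). Backward
passes are verified against central-difference numerical gradients to
about $10^{-7}$ relative error in the test suite, and all randomness —
initialisation, shuffling, dropout, splits, augmentation draws,
bootstrap — derives from one root seed via a deterministic fan-out
(`fanSeed()`), so identical configurations reproduce identical runs.

## Preprocessing and augmentation

Training images are augmented *then* normalised to $[0,1]$ by division by
255; evaluation data are normalised only. The augmentation draw per image:
horizontal flip with probability 0.5, rotation uniform within ±2% of a
full turn (±7.2°; rotation magnitude is expressed as a fraction of a turn,
matching common augmentation-layer semantics), contrast scaling uniform in
$1 \pm 0.10$ about the image mean, and zoom and translation within ±5%
each (a conservative, configurable default). Geometry is
resampled bilinearly with reflection at the borders, so rotations leave no
dark corners. Pseudo-label *scoring* always happens on clean,
normalisation-only images; augmented views feed only gradient steps. The
normalisation step refuses input that already looks normalised
(maximum ≤ 1), a guard against silent double division; an all-black 8-bit
image trips the same guard, a documented trade-off.

## The phantom generator

Because the real MRI cohort is external and large, the package ships a
seeded generator of four visually separable grayscale classes over a
smooth elliptical "brain" background: an eccentric bright ellipse with a
ragged edge, a bright ring, a small high-intensity disc in the lower half,
and a lesion-free background. Per-sample pose jitter (±10% rotation and
translation) is part of generation — distinct from training-time
augmentation — plus Gaussian pixel noise (default SD 10 grey levels) and a
`difficulty` parameter in $[0,1]$ that linearly interpolates the lesion
peak toward the background intensity; inter-class centroid distance is
monotonically non-increasing in it (tested on a three-point grid). The
ragged-ellipse vs ring pair is designed to be the hardest, a qualitative
analogue of the hardest tumor class in real cohorts. The generator
emulates class geometry, class balance and noise; it does *not* emulate
scanner intensity nonuniformity, anatomical variability, or 3-D structure
— so passing phantom benchmarks demonstrates that the pipeline's machinery
works, not that real-MRI accuracies transfer.

## The standing benchmark

`phantomBenchmark()` is the package's reference experiment: 50 training
and 25 test images per class at 32×32 (the tiny profile's native size),
noise SD 10, difficulty 0.3; 10% of the training images labelled; the tiny
custom CNN (two conv blocks of 8 and 16 filters, 32-unit dense) trained
50 epochs, then up to three pseudo-label iterations at thresholds
0.98/0.95/0.90 with 10 retraining epochs each; ten seeded replicates.
These sizes keep a full paired run around a minute on one CPU while
leaving the supervised baseline measurably below ceiling, so the
semi-supervised recovery is visible. The acceptance checks assert that the
mean paired improvement (semi-supervised minus supervised) is positive and
that accepted pseudo-labels are overwhelmingly correct (precision is
computable on phantoms because the split retains the hidden truth of the
pool — accessible to evaluation code only, never to training).

## Statistics suite

The comparison machinery mirrors standard practice for paired classifier
evaluation, all on the percent scale the tables use:

* paired one-tailed t-test on per-split accuracies,
  $t = \bar d / (s_d / \sqrt n)$ with the sample SD ($n-1$) of the
  differences; descriptive Mean ± SD summaries use the population
  convention (÷ n), which is what reproduces the printed column summaries;
* binomial proportion interval $p \pm z\sqrt{p(1-p)/n}$, bounds not
  clipped to $[0, 100]$ so the printed arithmetic is preserved;
* Cohen's $d$ with the pooled SD (reducing to
  $\sqrt{(s_1^2 + s_2^2)/2}$ at equal group sizes);
* McNemar's test with Yates continuity correction, clamped at zero —
  $\chi^2 = \max(|b - c| - 1, 0)^2 / (b + c)$ — so equal discordant counts
  give 0 rather than a spurious positive statistic; two-sided p from
  $\chi^2_1$;
* Cohen's $\kappa$ from the 2×2 marginals;
* percentile bootstrap of accuracy (1000 resamples, 2.5/97.5 percentiles,
  SE with the $1/(B-1)$ convention), deterministic per seed.

Worked examples from the published comparison tables are frozen into the
acceptance tests, where the arithmetic recomputes exactly at printed
precision. Three published summary numbers do *not* recompute from their
own tables — the paired t statistics (5.66/3.14, where the per-split
columns give 4.72/2.25), the κ of 0.89 (the published 2×2 table yields
≈ 0.027 under the standard formula), and one effect-size row (1.42 printed
where the row's own summaries give ≈ 1.70). The suite asserts the
recomputed values and flags the discrepancies rather than reproducing
inconsistent numbers.

## Numerical and design choices

* Class indices are 1-based internally (R convention); class *names*
  define the order and appear at all I/O boundaries. When reading an
  image folder the ordering is the spec's explicit class-name order;
  alphabetical when inferred.
* Stratified splits use largest-remainder apportionment: total labelled
  count `round(fraction · n)`, per-class floors, leftovers by largest
  fractional remainder (ties by class order), so totals are conserved and
  every class is within one sample of its exact quota.
* Argmax ties break toward the lowest class index; max-pooling ties keep
  the first (lowest-index) cell — both deterministic.
* Cross-entropy clamps the predicted probability of the true class at
  $10^{-12}$.
* An empty pseudo-label set contributes an unsupervised loss of 0 by
  convention.
* Retraining between iterations continues from the current weights (warm
  start) by default; `retrainFromScratch` restarts the optimiser state.
  Whether branch models are refreshed on the merged set before fusion is
  a flag (`refreshBranches`, default on).
* Image I/O is 8-bit PNG; images live on the $[0,255]$ scale in memory
  until normalisation. JPEG decoding is out of scope (a clear error
  names the file).
* The resampling engine is a single bilinear sampler with reflect
  padding used for rotation, zoom, translation *and* resizing; it is
  cross-checked against an established bilinear resize implementation in
  the tests.

## Limitations

The phantom task is far easier than real MRI: tiny networks approach
ceiling with dozens of labels, so the benchmark measures the *machinery*
(acceptance bookkeeping, threshold behaviour, paired improvement at 10%
labels) rather than clinically meaningful accuracy. The engine is
CPU-bound base R — appropriate for the desk-scale profiles, but training
the full 168×168/224×224 branches on thousands of images is out of its
intended range. Dropout regularisation at desk scale interacts strongly
with sample count; the tiny profiles' adjusted rates are documented
above. Soft pseudo-labels, temperature scaling, consistency-based
augmentation pairing and entropy regularisers are deliberately out of
scope.
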