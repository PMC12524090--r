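# pseudofuse

Semi-supervised self-training for multi-class grayscale image
classification, built for the low-annotation regimes typical of medical
imaging: a labelled subset trains a classifier, the classifier's
high-confidence predictions on the unlabelled pool are promoted to
*pseudo-labels* over an iterative rejection loop, and the merged set
retrains the model. The package also implements the dual-branch variant —
a compact texture-oriented CNN on grayscale input and a pluggable
feature-extractor branch on RGB input, whose penultimate feature vectors
(512 + 128 = 640 dimensions at full scale) are concatenated under a shared
dense classification head — plus the statistics suite used to compare
semi-supervised against supervised baselines.

## The method in brief

With labelled data $D_l$ and unlabelled pool $D_u$, training minimises
$L_{sup} + \lambda L_{unsup}$, where $L_{unsup}$ is cross-entropy against
the pseudo-labels

$$\hat y_j = \arg\max f_\theta(x_j) \quad \text{accepted iff} \quad \max f_\theta(x_j) \ge \tau .$$

The threshold relaxes across iterations (default τ = 0.98 → 0.95 → 0.90);
each iteration re-scores only the samples rejected so far, and the
per-iteration `(threshold, accepted, rejected)` bookkeeping is returned as
a ledger. In the dual-branch mode a pseudo-label additionally requires the
*consensus* of the two independently trained branches. Paired comparisons
are evaluated with a paired one-tailed t-test, binomial proportion
intervals, Cohen's *d*, McNemar's test with Yates continuity correction,
Cohen's κ and a percentile bootstrap.

Everything runs on a deterministic, single-CPU, base-R network engine;
no pretrained weights or GPU frameworks are needed. A seeded four-class
phantom generator (lesion-like shapes over an elliptical background)
provides a desk-scale stand-in for an MRI tumor-classification task.

## Worked example

```r
library(pseudofuse)

data  <- generatePhantoms(phantomConfig(perClassCount = 50, imageSize = 32, seed = 101))
test  <- generatePhantoms(phantomConfig(perClassCount = 25, imageSize = 32, seed = 202))
test@sampleIds <- paste0("test_", sampleIds(test))

split <- stratifiedSplit(data, labelledFraction = 0.1, seed = 7)
split
#> SplitResult (fraction 0.1, seed 7): 20 labelled / 180 unlabelled

cfg <- runConfig(mode = "ssl_single", seed = 7)
runSupervisedBaseline(split, test, cfg)
#> supervised_only run: test accuracy 0.9000
runSSL(split, test, cfg)
#> ssl_single run: test accuracy 0.9900, pseudo-label precision 1.0000
#>   iteration threshold accepted rejected
#> 1         1      0.98        0      180
#> 2         2      0.95       36      144
#> 3         3      0.90       94       50
```

With only 20 of 200 training images labelled, the supervised baseline
reaches 90% on the held-out phantoms. The pseudo-labelling loop accepts
nothing at τ = 0.98, then 36 samples at 0.95 and 94 more at 0.90 after
retraining — 130 of 180 pool images, every accepted label correct
(precision 1.0, measurable because the split retains the pool's hidden
truth for evaluation only) — and the retrained model reaches 99%.

The statistics suite reproduces published worked examples by plain
arithmetic:

```r
mcnemarTest(b = 30, c = 15)
#> McNemar chi2 = 4.356 (b = 30, c = 15), p = 0.03689
binomialCI(0.9839, 1311)
#> 98.39% [97.71, 99.07]  (SE 0.00348, n = 1311, z = 1.96)
cohensD(86.04, 1.58, 9, 84.74, 1.42, 9)
#> Cohen's d = 0.865  (pooled SD 1.502)
```

A command-line surface (`gen-data`, `split`, `train-supervised`,
`ssl-run`, `evaluate`, `stats`) is installed at `inst/cli/pseudofuse`;
every stage records a seed and a run manifest.

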