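---
title: "Shallow-autoencoder seizure detection: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shallow-autoencoder seizure detection: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SeizureAE)
```

## The detection problem

SeizureAE classifies 1-second single-channel EEG epochs as **ictal**
(seizure) or **interictal** (background). Working at the single-channel,
single-second level keeps detection latency at one second, localizes the
evidence to a channel, and keeps the arithmetic budget small enough for
wearable, few-channel recorders. The method is a two-stage hybrid:

1. **Feature learning.** A shallow autoencoder — one hidden layer of
   $m < n$ units — is trained to reconstruct raw epochs $x \in
   \mathbb{R}^n$ (for 256 Hz data, $n = 256$). The encoder
   $y = \mathrm{satlin}(W_E^\top x + b_E)$ compresses each epoch to an
   $m$-dimensional latent code; the decoder
   $\hat x = W_D^\top y + b_D$ reconstructs it. Training minimizes the mean
   squared reconstruction error plus an L2 weight penalty. No class labels
   enter this stage, and no preprocessing (filtering, normalization,
   artifact removal) is applied: the weights learn the scale of the data.
2. **Classification.** After training, the decoder is discarded. The
   latent code is the feature vector for a conventional two-class
   classifier. Six families are supported: weighted k-nearest neighbors,
   Gaussian-kernel SVM, quadratic discriminant analysis, kernel naive
   Bayes, a Gini decision tree, and a softmax (logistic) unit.

The deployed pipeline therefore costs one encoder pass plus one decision
evaluation per second of signal. The `complexity` functions make that
budget explicit (see below).

## The autoencoder

**Activations.** The encoder uses the symmetric saturating linear transfer
function, identity on $[-1, 1]$ and clipped to $\pm 1$ outside; the decoder
output is purely linear (identity). Saturating-linear rather than sigmoid
keeps the deployed encoder multiply-add only, with saturation as a
comparison. Every latent feature is guaranteed to lie in $[-1, 1]$
regardless of weights or input — a property the test suite asserts. A
literal reading of some printed statements of this activation would map the
whole interval $[-1,1]$ to 0, which would make the latent code constant and
useless; the package implements the standard saturating-linear form (the
breakpoints at $\pm 1$ and the function's name both imply it).

**Decoder bias.** The decoder bias $b_D$ is part of the model by default
(`decoderBias = TRUE` in `trainAE()`); it can be disabled for a purely
linear-map decoder. The bias is excluded from the L2 penalty, as is $b_E$
(penalizing biases would shrink the reconstruction offset for no
regularization benefit).

**Loss.** For a batch of $N$ epochs,
$$L = \frac{1}{nN}\sum_{i=1}^N \lVert x_i - \hat x_i \rVert^2
      + \lambda\,(\lVert W_E\rVert_F^2 + \lVert W_D\rVert_F^2),$$
with $\lambda$ = `l2` defaulting to $10^{-4}$ — small enough not to bias
reconstruction visibly, large enough to keep weights bounded when epochs
are nearly collinear.

**Optimizer.** Training uses scaled conjugate gradient (SCG): conjugate
search directions, a second-order curvature estimate from one extra
gradient evaluation along the direction (finite difference with constant
$\sigma_0 = 10^{-4}$), and Levenberg-style damping starting at
$\lambda_0 = 10^{-6}$, raised when a step fails and lowered when the
quadratic model is trustworthy. There is no line search. A step is accepted
only when the comparison ratio indicates an actual decrease, so the
sequence of accepted losses is non-increasing by construction — this is
asserted on every tracked run in the tests. Training stops when the
relative loss change stays below `tol` ($10^{-8}$) for 5 consecutive
accepted iterations, at `maxIter` (1000), or on gradient underflow.
The same optimizer trains the softmax classifier on binary cross-entropy.

**Initialization and determinism.** Weights start uniform in
$\pm\sqrt{6/(n+m)}$ under a user seed; biases start at zero. Identical
seeds give bitwise-identical models. All derived randomness (folds,
splits, per-epoch simulation) flows from explicit integer seeds through
one deterministic seed-derivation function, so end-to-end runs are
reproducible.

**Cross-validation.** `fitFeatureExtractor()` estimates the held-out
reconstruction error by k-fold cross-validation (default 5 folds) and then
refits on all training epochs. The decoder is evaluated only inside this
estimate; the classification path never reconstructs. `decodeCallCount()`
exposes a decoder call counter so this encoder-only contract is auditable.

**Gradient correctness.** The analytic gradient (with the satlin derivative
taken as 1 on the open interval and 0 in saturation) matches central finite
differences to relative error below $10^{-5}$ on random small models; this
is a standing test.

## Classifiers and their settings

* **kNN** (`knnConfig`): $k = 10$ Euclidean neighbors with
  squared-inverse-distance vote weights $1/d^2$. Two rules make the vote
  total: a query at zero distance from a stored point takes that point's
  label (the weight diverges; with several exact matches the first in
  stored order wins), and an exact weight tie predicts interictal — the
  deterministic choice that favors specificity. Predictions are verified
  against an independently coded brute-force vote in the tests.
* **SVM** (`svmConfig`): Gaussian kernel of scale 2 with an additive
  kernel offset of 0.1 and box constraint 1. The offset is implemented on
  each kernel evaluation (Gram-matrix offset convention). Because the dual
  coefficients sum to zero, a uniform Gram offset is absorbed by the bias
  and cannot change the decision — a property the tests check on fitted
  models. Fitting delegates to kernlab's SMO solver with this custom
  kernel; the decision function $\sum_i \alpha_i y_i K(x, s_i) + b$ is
  evaluated natively, since the operation accounting depends on its exact
  form.
* **QDA**: per-class maximum-likelihood covariance with a ridge of
  $10^{-6}\,\mathrm{tr}(S)/m$ on the diagonal for invertibility.
* **Naive Bayes**: per-feature Gaussian kernel densities with
  normal-reference (Silverman) bandwidths, floored for degenerate
  (constant) features.
* **Decision tree**: rpart with Gini impurity and exhaustive split
  search, post-pruned to at most 159 nodes. The cap is treated as a
  ceiling, not a target size.
* **Softmax**: a single logistic unit on the latent code, trained by the
  same SCG optimizer on binary cross-entropy (numerically stabilized via
  the log-sum-exp form). The problem is convex; the tests compare the
  fitted decision values against a converged gradient-descent reference.
  That comparison uses overlapping classes — on separable data the
  cross-entropy has no finite minimizer and any two optimizers drift apart
  along the same separating direction.

Single-class training input is rejected for SVM, QDA and softmax; kNN
accepts it and predicts the sole class.

## Operation accounting

`aeOpCount()`, `svmOpCount()`, `pipelineOpCount()` and `decisionOps()`
count multiplications and additions (subtractions count as additions) for
one test-time evaluation.

* **Encoder**: each hidden unit costs $n$ multiplications and $n-1$
  accumulation additions; the default convention excludes bias additions,
  giving the total $m(2n-1)$ — e.g. 32,704 operations at $n=256, m=64$ and
  4,088 at $m=8$. A flag (`includeBiasAdd`) adds the $m$ bias additions
  for alternative accounting.
* **SVM decision**: the default convention is affine in the feature
  dimension, $15d + 97$ total operations (1,057 at $d = 64$, 577 at
  $d = 32$). A mechanistic decomposition — per support vector a squared
  distance, a scaled exponential via a 10-term Taylor series, the kernel
  offset, and a weighted accumulation — is available
  (`mechanistic = TRUE`) but depends on the realized support-vector count,
  so the affine convention is the default. The multiplication/addition
  split of the affine total ($8d+49$ vs $7d+48$) is a documented package
  convention; only the total is externally meaningful.
* **Data reduction**: $(1 - m/n)\cdot 100\%$ at compression ratio $n/m$;
  75% (ratio 4) for $m = 64$ down to ~96.9% (ratio 32) for $m = 8$ at
  $n = 256$.
* **kNN**: $Nm$ subtraction-additions, $Nm$ multiplications and $N(m-1)$
  additions over $N$ stored training points — the memory- and
  compute-heavy option, which is why the SVM variant is the
  hardware-friendly configuration despite kNN's better sensitivity.
* **Softmax**: an $m$-term dot product plus bias ($m$ multiplications,
  $m$ additions); the monotone sigmoid needs no evaluation for a
  thresholded decision. Tree decisions are comparisons only.

## The synthetic generator

Real benchmark corpora cannot ship with a package, so `generateDataset()`
produces labeled epochs with known, controllable structure:

* **Interictal background**: an order-2 autoregressive process, poles at
  radius 0.95 placing the spectral peak near 10 Hz — an alpha-like,
  bandwidth-controlled background — scaled to unit standard deviation
  using the analytic stationary variance. A $1/f$ "pink" background is
  available as an alternative (`background_model = "pink"`).
* **Ictal activity**: the background plus a 3 Hz spike-wave train — the
  fundamental with second and third harmonics at weights 0.5 and 0.25, one
  narrow Gaussian transient per cycle (the "spike", sd = 1% of the cycle),
  gently amplitude-modulated at 1 Hz — scaled to `ictal_amp` (default 5)
  times the background standard deviation, over a configurable fraction of
  the epoch (`ictal_duty`, default the whole epoch).
* Amplitudes are unitless; no microvolt calibration is attempted, matching
  a pipeline that applies no amplitude normalization. Signals are O(1) so
  encoder saturation is exercised without being degenerate.

Defaults were fixed once, before the pipeline was evaluated, from
Monte-Carlo checks of class separability: at the defaults the line-length
statistic separates the classes with a standardized effect size above 2
and a single energy threshold exceeds 90% balanced accuracy, so the
classes are learnable by construction. Setting `ictal_amp = 0` makes the
two class distributions identical — the null configuration used for
chance-level testing. The chance-level check uses balanced class counts,
because 50% is the chance rate only for balanced data; with imbalanced
training a no-signal classifier legitimately drifts toward the majority
class.

**What passing on synthetic data does not show.** The generator has no eye
blink or muscle artifacts, no inter-channel correlation, no non-stationary
background drift, and its ictal morphology is far more stereotyped than
real seizures. Synthetic results validate the machinery (training
converges, features separate what is separable, metrics are computed
correctly) — they say nothing about clinical performance, which requires
real annotated EEG through the EDF/ASCII readers.

## Protocol utilities

Epochs are cut non-overlapping (stride = epoch length) with the trailing
partial window dropped — the autoencoder needs a fixed $n$. An epoch is
labeled ictal when it overlaps a seizure annotation by at least half the
epoch duration (a symmetric, deterministic rule for boundary epochs);
intervals are half-open $[t, t+1\,\mathrm{s})$ with 0-based sample
indexing. `makeSplit()` draws seeded train/validation/test partitions and
can subsample the training set to a target class ratio (e.g. 40% ictal /
60% interictal) while validation and test keep their natural ratios;
infeasible ratios fail with explicit counts. For 173-sample records the
epoch length is fixed at exactly 173 samples rather than a nominal 1-s
equivalent. EDF channels with duplicated labels keep their acquisition
index (e.g. `T8P8#2`) as identity.

## Report shapes

`evaluateChannel()` emits accuracy, sensitivity and specificity (ictal
positive) per channel, hidden size and family; `sweepGrid()` runs the full
hidden-size-by-classifier grid (the canonical grid is
$m \in \{64, 32, 20, 16, 8\}$), averages cells over channels, and reports
per channel the hidden size with the best value of each metric, breaking
ties toward the larger hidden size (the richer representation). Tables
render at two decimals with half-even rounding; undefined metrics (an
empty class) print as `NA`, never 0. The identity
$\mathrm{acc} = (\mathrm{sen}\cdot P + \mathrm{sp}\cdot N)/(P+N)$ holds
exactly for every emitted row and is enforced by a property test.

## Problem sizes in the test suite

The shipped tests run the full method at reduced scale so the suite stays
fast on one CPU: gradient checks on models up to $n = 8, m = 3$;
convergence checks at $n = 16$–$32$; the end-to-end recovery check at 400
training and 1000 test epochs of 256 samples with $m = 16$ and kNN (which
reaches 100% test accuracy on the default generator); the chance-level
check on 1000 balanced null epochs against a 99% binomial interval around
50%. Channel sweeps in tests use 64-sample epochs and small grids. These
sizes are the package's own choice of desk-scale experiment; the
machinery is identical at full scale.

## Known limitations

* Per-channel training is the default; one model can be shared across
  channels by passing pooled epochs, but no cross-channel ensembling is
  provided.
* The SVM hyperparameters are fixed defaults; no random-search tuning is
  included.
* Event-level (as opposed to epoch-level) seizure detection, probability
  calibration, multiclass problems and online/streaming operation are out
  of scope.
* The EDF reader targets the 16-bit, uniform-rate dialect used by common
  scalp-EEG corpora; EDF+ annotations embedded in the file are not parsed
  (seizure intervals come from a companion table), and EDF writing is not
  supported.
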