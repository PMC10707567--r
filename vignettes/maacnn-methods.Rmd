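---
title: "Multi-atlas attention CNNs for functional connectivity: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-atlas attention CNNs for functional connectivity: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the model implemented by `maacnn`, the choices
made where the design was genuinely open, the numerical conventions, and
what the synthetic cohorts do and do not establish about real data.

## From time series to features

Each subject contributes one ROI time-series matrix per atlas. The
feature map is fixed and estimator-free: all pairwise Pearson
correlations, then the strict lower triangle vectorized **row-major**
over pairs (i, j), i > j — (2,1), (3,1), (3,2), (4,1), … The set of
retained entries is forced by symmetry; their order is a convention, and
any fixed order works as long as it is stable. `feature_count(n)`
= n(n−1)/2 is enforced exactly in integer arithmetic.

Two degenerate-input policies matter downstream:

* **Zero-variance ROIs.** A constant time course makes the correlation
  undefined. Every affected entry (including the diagonal one) is set
  to 0 and a warning names the ROI indices. Propagating `NaN` instead
  would poison the autoencoder's loss irrecoverably.
* **Short series.** Fewer than two time points is a hard error; the
  correlation is not defined and no imputation is attempted. Subjects
  with incomplete series are expected to be excluded upstream.

Correlations enter the model as raw r values in [−1, 1]; no Fisher
z-transform is applied. The later per-feature standardization absorbs
scale, and keeping r bounded simplifies the convexity reasoning in the
fusion stage.

## Per-view feature learning: stacked denoising autoencoders

Each view's features are standardized (mean/variance fit on the
training fold only, the same affine transform applied to test folds)
and passed through two chained denoising autoencoders trained greedily:
DAE-1 on the standardized features, DAE-2 on DAE-1's bottleneck codes.
Each DAE corrupts its input with **masking noise** — every coordinate
independently zeroed with probability 0.30 (stage 1) or 0.10 (stage 2),
a fresh mask per sample per epoch — and reconstructs the *clean* input.

Open choices, and how they were settled:

* **Activations and loss.** Rectified bottleneck, linear decoder,
  mean-squared error. A linear output suits unbounded z-scored inputs;
  a squashing output would have to fight the standardization.
* **Optimizer.** Minibatch SGD, momentum 0.9, learning rate 1e-4,
  200 epochs, batch size 32 at full scale. Batch size and weight
  initialization (Glorot-uniform) are conventional choices; nothing in
  the model depends on them beyond convergence speed.
* **Frozen encoders.** After pretraining, encoders only feed the
  classifier; no joint fine-tuning of the autoencoders with the CNN.
  This keeps the unsupervised stage honestly unsupervised and makes the
  leakage analysis simple: encoder weights depend only on training-fold
  rows.
* **Widths.** The five named atlases use the published stage-1
  bottleneck widths (AAL 3330, CC200 9950, HO 3050, Dosenbach160 6440,
  EZ 3380); any other atlas takes half its input width, rounded up.
  Stage 2 always outputs the common width F. Note the input widths are
  always derived from the ROI count as n(n−1)/2, which for
  Dosenbach160 gives 12720 — published tabulations of that atlas's
  width differ internally, and the arithmetic identity wins here.
  F defaults to 2000; every configuration requires F strictly below the
  stage-1 bottleneck so the stack stays compressive.

At inference the corruption and decoders are gone: `sda_transform()` is
two deterministic affine-plus-rectifier maps, so repeated calls are
bit-identical and encoding is row-wise independent (up to floating-point
reassociation inside the BLAS).

## Multi-view attention fusion

Encoded views x′₁…x′ₙ (each N×F) are fused per subject as
X̂ = Σᵢ cᵢ x′ᵢ. The weights come from global average pooling — each
subject's view vector collapsed to its mean — followed by a one-hidden-
layer MLP (width max(4, 2n)) and a softmax over views. The block is
trained jointly with the CNN by backpropagation; gradients reach the
weights both through the MLP and through the fused features, but never
into the frozen encoders.

Two readings of the summary dimensionality were possible: a single
global weight vector per batch, or per-subject weights. The per-subject
reading (the squeeze-and-excitation convention) is the default because
fusion happens per subject; `global_weights = TRUE` restores the
literal batch-global reading. Softmax normalization is likewise a
choice: it makes the weights a probability vector, which turns the
fusion into a convex combination with a testable elementwise bound
(fused values never leave the per-coordinate min/max envelope across
views); `normalize = "none"` disables it for experimentation. With one
view the block reduces exactly to the identity.

## The 1D CNN classifier

The fused N×F matrix is treated as N single-channel length-F sequences.
Each conv block applies, in order: same-padded 1D convolution, ReLU,
batch normalization, max pooling (length floor-divided by the pool
factor), dropout. The published architecture fixes this order but not
depth or widths; the defaults are 3 blocks, channels (16, 32, 64),
kernel 5, pool 2, dropout 0.3, dense width 128, weight decay 1e-4, one
skip connection spanning blocks 1–2 — all overridable in
`cnn_config()`.

The skip connection implements Output = Conv(x) + G(x): a 1×1
convolution projects the shortcut's channels to match the main path
(identity when they already match), and the shortcut is max-pooled by
the span's total pool factor so lengths align — the channel fix is
prescribed, the spatial fix is the natural completion since integer
floor-division composes. Placement is configurable because "between two
convolutional layers" admits several readings; one spanning connection
is the default.

The head is flatten → dense ReLU → softmax over (HC, ASD), with ASD in
column 2 as the positive class. Predictions threshold the ASD
probability at 0.5 with ties broken toward HC. The L2 penalty
λ·Σw² covers convolution and dense weights only — biases and batch-norm
parameters are exempt, following standard weight-decay practice.

All forward/backward passes are plain matrix algebra written in base R
(im2col convolutions, hand-derived batch-norm and pooling gradients).
The test suite verifies every gradient path against central finite
differences at relative tolerance 1e-5.

## Cross-validation, metrics, leakage

* **Stratified k-fold** (default 10): each class shuffled and dealt
  round-robin, so per-fold class counts deviate from proportionality by
  at most one subject and sensitivity/specificity are defined in every
  fold. Site-blocked splitting is not implemented; stratification is
  the default reading.
* **Aggregation.** k-fold metrics are averaged over folds; LOOCV pools
  confusion counts over the N singleton folds (per-fold rates would be
  degenerate). Reports label which mode produced them and never mix
  the two.
* **Metrics.** ACC, SEN, SPEC from the confusion counts with ASD
  positive; undefined denominators yield `NA` with a warning and are
  skipped in fold averaging. AUC is the Mann–Whitney rank statistic
  with ties counted one half, using the ASD probability as the score.
* **Leakage instrumentation.** Every fit routine (standardization, DAE
  training, RFE, joint training) reports the row ids it receives; while
  a fold's guard is active, any intersection with that fold's test ids
  is recorded. A clean run reports zero violations — this is asserted
  in the acceptance tests rather than assumed.
* **Seeding.** One master seed fans out deterministically to the
  split, per-view SDA, and joint-training streams; identical seeds give
  identical reports.

The RFE baseline used by the ablation arms ranks features by the
absolute coefficients of a ridge-regularized linear classifier
(closed-form, deterministic), removing 10% of the remaining features
per round without overshooting the target dimension.

## The synthetic cohort generator

`make_cohort()` draws each subject's time series from a zero-mean
multivariate normal whose correlation matrix is a shared per-view base
(random 3-factor structure), plus a class shift of magnitude δ on a
planted edge set (informative views only), plus a symmetric per-site
perturbation; matrices are repaired to positive definiteness by
eigenvalue clipping (floor 1e-4) and renormalized to unit diagonal,
with repairs counted in the cohort object. Affected edges get head-room
capping so the ASD value never exceeds 0.98 in magnitude; a δ outside
[0, 1.9] is rejected outright.

What it emulates: multiple atlas views, class-dependent covariance
differences, site batch effects, views of differing informativeness.
What it deliberately does not: temporal autocorrelation and hemodynamics
(the pipeline consumes only pairwise correlations), realistic site
demographics, class imbalance, motion artifacts. Consequently, passing
tests demonstrate that the machinery recovers planted covariance
structure under leakage-free evaluation — they say nothing about effect
sizes in real clinical cohorts.

One subtlety worth knowing: the positive-definiteness repair slightly
perturbs *all* entries, so a strong planted shift bleeds a weak echo
into unaffected edges. The null preset (δ = 0) is therefore the one
that certifies false-positive behavior, and the verification report
pools its false-positive rate over views.

### Preset study conditions

* `separable` — three views of 10/12/14 ROIs, T = 120, 40+40 subjects,
  δ = 0.6 on 20 edges per view, 2 sites: strongly recoverable signal.
* `null` — identical geometry, δ = 0: exchangeable classes.
* `noise-view` — one informative view (δ = 0.6, 20 edges), one
  pure-noise view: the attention weights should favor the former.
* `complementary-views` — two views of unequal informativeness
  (δ = 0.3 on 3 edges vs δ = 0.55 on 12 edges, T = 100), calibrated
  with a ridge-classifier oracle so a single-view model trails the
  fused model: the regime where multi-view fusion demonstrably pays.

## Desk-scale configuration

The full-scale settings (F = 2000, 200 epochs, learning rate 1e-4)
target cohorts of hundreds of subjects with thousands of features. The
bundled tests and the acceptance script run the same code on the preset
cohorts above with `maacnn_desk_config()`: F = 16, two conv blocks of
8/16 channels with kernel 3, dropout 0.1, dense width 32, SDA for 40
epochs at learning rate 0.02, joint training for 80 epochs at 0.01.
These are convergence-scale choices for small matrices, not model
changes: the architecture, corruption rates, loss, and evaluation
protocol are identical. A full cross-validated run on a preset cohort
completes in well under a minute on one CPU core.

## Known limitations

* No GPU path and no convolutional/variational autoencoder variants;
  the networks are desk-scale by construction in R.
* Multi-site structure is simulated and stratified over, not modeled;
  no harmonization (e.g. empirical-Bayes batch correction) is applied.
* Attention is single-head over view summaries; it cannot express
  feature-level cross-view interactions.
* The classifier is binary with a fixed 0.5 threshold; calibration of
  the softmax probabilities is not assessed.
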