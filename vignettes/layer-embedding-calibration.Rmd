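---
title: "Layer-embedding analysis and probability calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Layer-embedding analysis and probability calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Voxel-wise classifiers for lesion segmentation are routinely overconfident:
the softmax score they attach to "anomaly" is far larger than the empirical
frequency with which such voxels actually are anomalous. For clinical
decision support the score matters as a probability, not only through its
ranking, so this miscalibration is a real defect even when AUC is high.

`layercal` implements a calibration strategy built on *layer embedding
analysis*: instead of post-processing the output score alone (as Platt
scaling does), it asks every hidden layer of the network what it believes
about each voxel, and uses an early layer's belief to temper the final
output.

## Model and notation

The segmentation model is a 3D fully convolutional network (FCN) of ten
blocks, each `ReLU(BN(conv))` with 3x3x3 kernels, channel widths
16,16,32,32,64,64,32,32,16,16 and dilations 1,1,2,2,4,4,2,2,1,1, followed by
a 1x1x1 convolution to 4 tissue classes (background, parenchyma, viable
tumor, necrosis) and a softmax. Zero padding equal to the dilation keeps the
spatial grid unchanged in every layer, which is what makes *per-voxel*
representations comparable across layers. The closed-form trainable
parameter count of this baseline is 320,276 (`param_count(fcn_spec())`).
The binary anomaly score of a voxel is
`sigma = P(viable) + P(necrosis)`.

Each hidden layer is decomposed into two sub-steps:

* **Spatial information aggregation** — for layer dilation `d`, each voxel's
  feature vector is replaced by the concatenation of the 27 neighbor vectors
  at offsets `{-d, 0, +d}^3` (zero-padded at boundaries). This is the
  *pre-convolution representation*: everything the next convolution could
  use, before any weighting. Width: `27 * N`.
* **Information synthesis** — `ReLU(BN(W h + b))`: what the layer actually
  keeps. This is the *post-convolution representation*.

For a 10-layer network this yields 20 representation slots per voxel
(`l1_pre`, `l1_post`, ..., `l10_post`).

## Embedding outputs and calibration

For each slot, a probability classifier (a 20-tree random forest by
default; an exact k-nearest-neighbor estimator is available as
`kind = "knn"`) is fitted on a seeded voxel subsample of the training-set
representations against the binarized labels (anomaly = viable or
necrosis). Applied to an unseen volume, the slot's classifier produces a
per-voxel anomaly probability `sigma_l` — the *embedding output* of that
layer: what the layer already knows about the voxel.

Calibration is the voxel-wise product

```
sigma' = a * sigma_l * sigma + b,    a = 1, b = 0
```

so the embedding output acts as a reliability weight: a score survives only
where the probed layer supports it, and with the default constants a
calibrated score can never exceed the raw one (pure down-weighting of
overconfidence; false positives are de-emphasized). The only tuned
hyper-parameter is *which* slot to use. It is selected on the validation
split by minimum calibrated average calibration error (ACE), with ties
broken by higher AUC, then earlier layer, then pre- before post-stage; the
test split plays no part in the choice, and the run manifest records the
full validation ranking for audit.

Three standard baselines are included for comparison: Platt scaling of the
binary anomaly logit (fitted by deterministic IRLS; strictly increasing, so
it preserves AUC exactly), Monte Carlo dropout (mean of `T` stochastic
passes with channel-wise 3D dropout active at inference), and deep
ensembles (mean softmax of seed-varied members).

## Metrics

Reliability diagrams use the equal-width half-open bins
`B_m = ((m-1)/M, m/M]` (a score exactly at a bin edge falls in the lower
bin; zeros fall in bin 1; `M = 10` by default). ACE is the unweighted mean
of `|accuracy - confidence|` over nonempty bins; a strict mode dividing by
all `M` bins is available. Two accuracy conventions are provided and always
named in the report: `argmax_accuracy` (fraction of voxels whose
thresholded prediction matches the label — the literal formula) and
`positive_frequency` (fraction of positive labels in the bin — the
diagonal-over-[0,1] reading of a binary reliability diagram). The shipped
experiment pipeline uses `positive_frequency`, because for a binary score
the diagonal reading is the convention under which "bar height tracks the
diagonal" means calibrated across the whole [0,1] range; under the argmax
convention an accurate model shows |acc - conf| near 1 in the low bins by
construction, which measures sharpness, not calibration. AUC uses the
Mann-Whitney midrank form (ties count one half), making it exactly
invariant under strictly increasing transforms; DSC is
`2|A n B| / (|A| + |B|)` at threshold 0.5, defined as 1 when both masks are
empty.

## The synthetic phantom

Real multi-phase MR data cannot ship with a package, so experiments run on
a synthetic liver phantom: an ellipsoidal parenchyma on dark background
with 1–3 spherical viable lesions, optional concentric necrotic cores, and
three intensity channels emulating pre-contrast / arterial / venous
enhancement (viable tumor is arterial-bright, necrosis hypointense), plus
i.i.d. Gaussian noise. The phantom emulates the *class structure and
contrast ordering* of dynamic contrast imaging — enough to exercise
training, probing, and calibration end-to-end. It does not emulate organ
texture, partial-volume effects, bias fields, or registration error, and
no anatomical realism is claimed. Augmentation (monotone gamma contrast,
smooth free-form deformation, additive noise) is available but off by
default.

The noise level is a study condition, not a tuning knob: at low noise the
classes are separable from a single voxel's intensities and even layer 1
probes at ceiling; at high noise (for example `noise_sd = 40` against a
viable-parenchyma arterial contrast of 35) voxel-wise separation is poor
and performance must come from spatial context, which is the regime in
which layer-wise probing is informative.

## Numerical choices

* Convolutions are gathered by a C++ `im2col` for dilated 3x3x3
  neighborhoods and multiplied as one BLAS GEMM per layer; the breakdown
  functions (`spatial_aggregate`, `information_synthesize`) are a second,
  independent pure-R implementation, so their agreement with the network
  forward pass (within 1e-5, tested) checks both.
* Batch normalization uses per-patch batch statistics during training
  (running statistics updated with momentum 0.1) and frozen running
  statistics at inference; `eps = 1e-5`.
* Weights are He-initialized; optimization is Adam on class-weighted voxel
  cross-entropy, weights defaulting to inverse class frequency (normalized
  to mean 1) to counter the extreme lesion/background imbalance.
* All randomness flows through seeded scopes that never touch the caller's
  RNG state; derived stages use deterministic child seeds. Two runs with
  the same config are bit-identical, including the 20-tree forests
  (`ranger` with a fixed seed, single-threaded prediction).
* Volumes are written as uncompressed NIfTI (gzip embeds timestamps, which
  would break byte-identical manifests), images as float64 so round trips
  are exact.

## Desk-scale experiment

`experiment_config()` defines the package's canonical study: 10 synthetic
subjects on a 24^3 grid, a narrow 10-layer ladder (channels
8,8,12,12,16,16,12,12,8,8, dropout 0.1), 16^3 patches, 12 epochs, one fold
of a subject-level 5-fold 60/20/20 split, 20-tree forests on 400 voxels per
volume. These sizes are this package's own choice so that the full pipeline
runs in minutes on one CPU; the architecture defaults in `fcn_spec()` remain
the full-width baseline. On this study the qualitative pattern of the
method appears clearly: the raw FCN is heavily overconfident (test ACE
around 0.4–0.5), embedding calibration at the validation-selected slot cuts
ACE by a factor of 2–3 while AUC does not degrade, the selected slot sits in
the early layers, and the last layer's embedding output converges to the
raw FCN output.

## Interpretation choices on under-specified points

Decisions the method description leaves open, and what this package does:

* **Reliability accuracy convention** — both modes implemented; pipeline
  default `positive_frequency` (rationale above).
* **Forest training-class balance** — probe subsamples are drawn at the
  natural class prevalence with a small guaranteed minimum per class
  (default 25), not rebalanced 50/50: the embedding output is used as a
  probability, and training a forest on artificially balanced data would
  inflate its positive-class probabilities, re-introducing the very
  overconfidence being removed.
* **MC-dropout baseline weights** — shares the single dropout-trained
  network with the raw output rather than training a separate model, so the
  comparison isolates the effect of inference-time averaging.
* **DkNN details** — Euclidean distance, ties broken by lower training
  index, exact (no approximate search) at desk scale.
* **Empty reliability bins** — excluded from the ACE mean by default
  (accuracy is undefined on them); strict mode divides by all bins.
* **Calibrated scores out of range** — only possible for non-default
  `a, b`; clipped to [0,1] and flagged in provenance.

## Limitations

The engine is a compact CPU implementation for desk-scale studies, not a
training framework: single-patch batches with gradient accumulation, no
learning-rate schedules, no checkpointing mid-run. Phantom realism is
deliberately minimal (see above). Embedding probes are fitted per fold and
never shared; fitting the calibration constants `a, b` by optimization, and
conformal or credibility-style uncertainty for the DkNN estimator, are out
of scope.
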