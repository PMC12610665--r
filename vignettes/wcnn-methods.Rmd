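---
title: "Methods: a weighted CNN workflow for heart-valve-disease detection in PCG audio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a weighted CNN workflow for heart-valve-disease detection in PCG audio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcgwcnn)
```

## The problem and the model

A phonocardiogram (PCG) records the amplitude of heart sounds over time. In
a healthy cycle the first and second heart sounds (S1, S2) appear as
periodic transient bursts; valve pathology (aortic stenosis AS, mitral
regurgitation MR, mitral stenosis MS, mitral valve prolapse MVP) adds
murmurs — band-limited turbulent noise between or around them, typically in
the 100–700 Hz range. `pcgwcnn` implements a complete detection workflow:

1. **Standardization** — every recording is truncated or zero-padded to
   1.4 s, so each file is exactly one fixed-size segment and splits can be
   strictly file-level.
2. **Features** — a static MFCC map: 0.2 s Hamming frames with 50% overlap
   (1600 samples at 8000 Hz, 400 at 2000 Hz), 2048-point FFT, 32 triangular
   mel filters, log, orthonormal DCT-II, keeping 17 coefficients
   (coefficient 0 doubling as the energy term). A 1.4 s signal yields
   `floor((fs*1.4 - winlength)/winstep) + 1 = 13` frames, so the model input
   is a 17 x 13 matrix.
3. **Classifier** — a lightweight weighted CNN: three valid 2 x 2
   convolutions (32, 64, 64 filters; strides 1, 1, 2) with ReLU and batch
   normalization, a parameter-free *key weighting calculation* (KWC) layer,
   flatten (2240 units), a 128-unit dense layer, and a softmax head.
4. **Explanation** — Grad-CAM heatmaps over the MFCC plane.
5. **Quality** — the band energy ratio (BER): spectral energy in 20–700 Hz
   over the energy outside it, after resampling to 2000 Hz.

The KWC layer computes, per channel $c$ of a feature tensor $F \in
\mathbb{R}^{C \times H \times W}$,

$$w_c = \frac{1}{HW}\sum_{i,j} F_c(i,j), \qquad F'_c = w_c \cdot F_c,$$

i.e. each channel is rescaled by its own global average. Channels that
respond consistently (high mean activation) are amplified; channels
dominated by incoherent noise are attenuated. The layer holds no
parameters, so it changes neither the parameter count nor (by the usual
conv/dense-only convention) the FLOP count, and gradients flow through both
factors of the product. A useful structural consequence, asserted in the
tests, is positive homogeneity of degree two: $\mathrm{KWC}(aF) = a^2\,
\mathrm{KWC}(F)$.

Parameter and FLOP accounting is purely analytic: convolutions contribute
$(K_h K_w C_{in} + 1)\,C_{out}$ parameters and $2 K_h K_w C_{in} H_{out}
W_{out} C_{out}$ FLOPs, dense layers $(in+1)\,out$ and $2\,in\,out$;
normalization, dropout, flatten, and KWC contribute zero. The default
17 x 13 network has 312,357 parameters (160 / 8,256 / 16,448 / 286,848 /
645 per learnable layer) and 4,474,112 FLOPs. Because the stride-2
convolution floors its output size, an odd input height and the next even
one can yield identical counts — `count_parameters()` reproduces that
parity pattern.

## The training engine

No deep-learning framework is declared as a dependency: the network is
implemented on base-R arrays with im2col convolutions (BLAS matrix
products), hand-written backpropagation, Adam, and a staircase exponential
learning-rate schedule (`0.001 * 0.95^floor(iter/10000)`). That keeps the
package self-contained and makes the gradient path available to Grad-CAM
directly. Backpropagation is verified against central finite differences in
the test suite (worst relative error below `1e-5` across conv, batch-norm,
KWC, and dense parameters, in both train and eval modes).

Defaults follow the study configuration: 100 epochs, batch size 16,
categorical cross-entropy, Adam with the framework-conventional
$\beta_1 = 0.9$, $\beta_2 = 0.999$. Batch normalization is applied after
the activation (Conv → ReLU → BN), configurable via
`build_model(bn_after_activation =)`, since the two published descriptions
of the block order disagree; the accounting is unaffected either way.
Dropout rates are not stated in the source material; 0.3 is used at both
marked sites (after the third conv block and after the hidden dense
layer), configurable in `wcnn_architecture()`.

## Evaluation

`classification_metrics()` derives accuracy, precision, recall, F1, and
Cohen's kappa ($\kappa = (p_o - p_e)/(1 - p_e)$) from a confusion matrix;
multiclass metrics are one-vs-rest and macro-averaged by default — macro is
the default because it exactly reproduces the published per-fold recall and
F1 values recomputed from the bundled reference fold matrices
(`reference_fold_matrices()`). Those matrices also expose one known
inconsistency: the published fold-1 precision (98.05) differs slightly from
the macro precision recomputed from the same matrix (98.10); the averaging
used there is unclear, so precision is not asserted exactly.

`roc_auc()` sweeps TPR/FPR over all distinct score thresholds (ties
grouped) and integrates with the trapezoidal rule; on tie-free data this
equals the Mann–Whitney concordant-pair fraction, which the tests assert
exhaustively on small instances and cross-check against pROC.
`average_precision()` sums precision at each recall increment;
`map_multiclass()` averages per-class APs one-vs-rest.

Dataset splitting is strictly at the file level. Balanced k-fold draws an
equal per-class test count per fold (20 per class with 200-file classes and
k = 10); random k-fold draws n/k per fold regardless of class. Folds are
pairwise disjoint and cover the manifest — a property test, not an
assumption. All splits are seeded; no class rebalancing is ever applied.

## The synthetic generator

`synth_recording()` emulates exactly the structural properties the
pipeline depends on, and nothing more:

* quasi-periodic S1/S2 Gaussian-windowed tone bursts (30–150 Hz) at a
  heart rate drawn from 60–100 bpm, the resting adult range;
* a class-conditional murmur: band-limited noise under a class-distinct
  envelope — mid-systolic diamond (AS, 200–600 Hz), holosystolic (MR,
  150–400 Hz), diastolic rumble (MS, 100–300 Hz), mid-systolic click plus
  late systolic murmur (MVP, 250–500 Hz), none for N;
* optional noise injection: low-frequency drift (0.5–15 Hz) and
  high-frequency hiss (720–990 Hz) scaled in closed form to hit a requested
  band energy ratio. The noise bands are disjoint from the signal band in
  the spectrum, so the scaling is exact and `compute_ber()` recovers the
  target within a few percent (the tests require 10%).

Recording lengths are drawn from 1.2–4 s and datasets mirror the study
layouts: five balanced classes (200 per class at full size, 8000 Hz) or a
binary normal:abnormal set with 4:1 imbalance (2000 Hz). Everything is
seeded file-by-file.

What the generator deliberately does **not** model: real stethoscope
transfer functions, respiration and friction artifacts, inter-patient
variability, ECG timing, or physiologically faithful murmur spectra.
Passing tests on generator data therefore demonstrate that the pipeline's
machinery is correct and that the model can learn band/timing structure —
they do not certify clinical performance. The published full-dataset
accuracies require the two public PCG databases, which are deliberately
outside the automated surface.

## Numerical choices and degenerate inputs

* Mel filterbank: unit-peak triangles, centers equally spaced on the mel
  scale over [0, fs/2]; filterbank energies floored at `1e-10` before the
  natural log, so silent frames produce finite, constant columns rather
  than `-Inf`.
* DCT-II with orthonormal scaling, fixed for reproducibility.
* Pre-emphasis coefficient 0.97 (speech-processing convention),
  configurable.
* Resampling is zero-phase FFT spectrum truncation — exact for band-limited
  content, which is all this pipeline produces or analyzes.
* BER: single full-length periodogram; band edges inclusive on [20, 700];
  the DC bin is excluded from the denominator (a constant offset is neither
  heart sound nor meaningful noise). Zero out-of-band energy returns an
  `Inf` sentinel with a flag instead of an error; an all-zero signal is an
  error.
* Truncation keeps the *beginning* of long recordings (the fixed-length
  standardization must be deterministic; which portion to keep is otherwise
  unspecified), configurable by standardizing a manually windowed
  recording.
* Zero-denominator per-class ratios are reported as 0 with a warning so a
  degenerate fold cannot abort a cross-validation run.
* Grad-CAM upsamples the conv-grid map (7 x 5 by default) to the input
  grid (17 x 13) bilinearly, applies ReLU before min–max normalization, and
  flags identically-zero maps as degenerate instead of dividing by zero.

## Problem sizes used by the test suite

The stochastic end-to-end checks run at sizes chosen to exercise the full
study configuration where it matters and generator-scale elsewhere: the
separability check trains the default 17 x 13 network on the full 200
recordings per class (8000 Hz) with a 90/10 holdout and 15 epochs — the
loss curve plateaus near zero well before that, consistent with the rapid
convergence the study design anticipates; the KWC-ablation comparison uses
60 recordings per class at 2000 Hz under heavy injected noise (target
BER 0.5) for 5 seeded repetitions of 10 epochs each. Unit tests use toy
feature sets and small architectures throughout.

## Known limitations

* Pure-R training is adequate at this input size (seconds per epoch at
  n = 1000) but would not scale to spectrogram-sized inputs.
* The binary (normal/abnormal) path shares the softmax machinery with the
  five-class path; binary cross-entropy is its two-class special case
  rather than a separate sigmoid head.
* The generator's murmur envelopes are stylized; class separability is by
  construction, so accuracy on synthetic data is an upper bound, not an
  estimate, of real-data performance.
* Grad-CAM explanations are taken from the last convolutional layer by
  default; the 7 x 5 grid bounds how sharply attention can localize after
  upsampling.
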