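---
title: "Methods: wind-driven-optimized stacked sparse autoencoders for histology patches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wind-driven-optimized stacked sparse autoencoders for histology patches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Osteosarcoma histology slides are screened as small image patches, each
assigned to one of three classes: viable tumor (VT), non-viable/necrotic
tumor (NVT), and non-tumor (NT). `osteoDSSAE` implements a complete patch
classification pipeline for this setting: edge-preserving pre-filtering,
lightweight convolutional feature extraction, a deep stacked sparse
autoencoder (DSSAE) classifier, and population-based hyperparameter search
with Wind Driven Optimization (WDO). Every stage is testable offline through
a seeded synthetic data generator.

## Pre-processing

Smoothing uses a weighted average $f(p) = \sum_q K_{p,q} P_q$ over a
truncated window. The bilateral kernel is the product of a spatial and a
range factor,

$$K_{p,q} \propto
  \exp\!\left(-\frac{\lVert p-q\rVert^2}{\sigma_s^2}\right)
  \exp\!\left(-\frac{(Q_p - P_q)^2}{\sigma_r^2}\right),$$

normalized to sum to one over the in-bounds window. Two conventions matter
and are deliberate:

* **No factor 2 in the denominators.** The kernels use
  $\exp(-d^2/\sigma^2)$, not the textbook $\exp(-d^2/2\sigma^2)$; `sigma_s`
  and `sigma_r` are therefore scales in that convention (pixels and
  intensity units on the $[0,1]$ scale respectively).
* **Per-pixel renormalization, no padding.** Near borders the kernel is
  renormalized over the pixels that exist. Every output pixel is then a
  convex combination of input pixels, so filter outputs are always bounded
  by the input range — a property the test suite asserts.

With no guide image the filter is self-guided (the classic bilateral form);
a same-shape guide gives the joint/cross form. Pure Gaussian smoothing
(range factor dropped) is selectable; the pipeline default is the
self-guided bilateral filter, which preserves nuclear boundaries that
grading depends on. Defaults $\sigma_s = 1.5$ px (radius 3) and
$\sigma_r = 0.1$ smooth stain noise without erasing texture at the
128-px patch scale.

Contrast enhancement follows: CLAHE by default (clip limit 0.01 as a
fraction of tile pixels per histogram bin, 256 bins, 8×8 tiles — the common
choice for stain-variable histology), with global histogram equalization and
min–max stretching selectable. Constant images pass through every method
unchanged; there is no division by zero anywhere in the degenerate cases.

## Feature extraction

Features come from a SqueezeNet-v1.1-style network: a 3×3 stride-2 stem,
eight *fire modules* (a 1×1 "squeeze" convolution feeding concatenated 1×1
and 3×3 "expand" branches), interleaved max pooling, and global average
pooling (GAP). Replacing 3×3 kernels by 1×1 divides the per-layer parameter
count by 9; the default network has ~0.7 M parameters, some 80× fewer than
a classic 60 M-parameter AlexNet-scale model, which keeps a pure-R forward
pass practical.

The network is used **frozen**: weights are drawn once from a seeded
He-normal initialization and never trained. Random convolutional features
followed by GAP summarize local texture energy and intensity statistics,
which is sufficient for the texture-scale class differences this pipeline
targets, and it keeps the whole artifact free of external weight files. The
`import_weights()` adapter accepts externally trained weights matching the
spec shapes, with per-layer shape validation, for users who have them. The
feature vector is the GAP output (512 dimensions at width 1); any named
layer can be tapped instead. Input patches are resized bilinearly to the
network input size (default 128×128; 227×227 is selectable for compatibility
with externally trained weights).

## The DSSAE classifier

The building block is a sparse autoencoder (SAE) with log-sigmoid coding:
$C = g(W_Y Y + B_Y)$, $Z = g(W_Z C + B_Z)$, $g(x) = 1/(1+e^{-x})$. Its loss
over $N$ samples is

$$\ell = \frac{1}{N}\sum_n \lVert Z_n - Y_n\rVert^2
  + c_s \sum_j \mathrm{KL}(\rho \,\|\, \hat\rho_j)
  + \frac{c_w}{2}\left(\lVert W_Y\rVert_F^2 + \lVert W_Z\rVert_F^2\right),$$

where $\hat\rho_j$ is hidden unit $j$'s mean activation over the batch and
$\mathrm{KL}$ is the Bernoulli Kullback–Leibler divergence pulling mean
activations toward the sparsity proportion $\rho$. Defaults are
$\rho = 0.05$, $c_s = 1$, $c_w = 10^{-4}$. The weight penalty is applied to
both weight matrices (penalizing only their product would leave each matrix
individually unregularized). $\hat\rho_j$ is clipped to
$[10^{-8}, 1-10^{-8}]$ so dead or saturated units cannot make the penalty
infinite. The analytic gradient of all three terms is verified against
central finite differences at relative error $<10^{-5}$ — the central
correctness gate of the training code.

Four SAEs (default hidden sizes 256, 128, 64, 32) are trained greedily:
each on the codes of its predecessor, then a softmax output layer on the
deepest codes. Two scaling rules keep the stack healthy:

* input features are min–max scaled to $[0,1]$ (scaler fitted on the
  training split only), because the log-sigmoid decoder can only produce
  values in $(0,1)$;
* the codes passed between layers are likewise rescaled to $[0,1]$.
  Sparse codes concentrate in a narrow band near $\rho$; without the
  rescale, a deeper layer can meet its objective with a *constant* code and
  the class signal dies inside the stack. The per-layer scalers are part of
  the model and are replayed at prediction time.

All stages are trained with Møller's scaled conjugate gradient
($\sigma_0 = 10^{-5}$, $\lambda_0 = 10^{-7}$), full batch by default; the
`epochs` hyperparameter caps conjugate-gradient iterations per layer, and a
`batch_size` below the sample count switches to seeded-shuffled mini-batch
cycling with one conjugate step per batch. An optional end-to-end
fine-tuning pass (plain gradient descent through the encoder stack and
softmax head at `learning_rate`, off by default) measurably sharpens
decision boundaries; it is the one place `learning_rate` acts. Prediction
ties in the argmax are broken toward the lowest class index, for
determinism.

## Wind Driven Optimization

Hyperparameters are searched by WDO, a population method whose candidates —
*air parcels* — carry a position $x \in [-1,1]^D$ and velocity $u$. Parcels
are ranked by *pressure* (here: classification error, lower is better;
rank $k=1$ is the incumbent), and each dimension updates as

$$u_{\text{new}} = -g\,x + (1-\alpha)\,u
  + \left|1 - \tfrac{1}{k}\right| RT\,(x_{\max} - x)
  - \frac{c\,u_{d'}}{k}, \qquad x_{\text{new}} = x + u_{\text{new}},$$

with $u_{d'}$ the current velocity of one uniformly chosen *other*
dimension (the Coriolis surrogate; $d'=d$ in one dimension). The rank-1
parcel feels no pressure-gradient pull ($|1-1/1| = 0$). Velocities are
clamped elementwise (default 0.3); positions that leave the box are clipped
with the violating velocity component zeroed (reflection is selectable).
Defaults $\alpha = 0.4$, $g = 0.2$, $RT = 3$, $c = 0.4$, 20 parcels follow
the established WDO literature and are all exposed in `wdo_config()`.

The search space maps $[-1,1]^D$ to native units per dimension: linear or
log-scaled continuous intervals, or finite value grids with nearest-point
decoding (`decode(encode(v)) = v` on grid values). The default DSSAE space
tunes `epochs` (log-spaced integers 20–200), `batch_size`
({8, 16, 32, 64, full}) and `learning_rate` (log-uniform
$[10^{-4}, 10^{-1}]$); $c_s$, $\rho$ and the hidden sizes can be added.
Fitness is the error rate on an internal stratified 75/25 validation split
of the training data; the winning configuration is retrained on the full
training split. The incumbent's fitness is non-increasing by construction
and is asserted every iteration.

On the 5-D sphere benchmark (20 parcels, 200 iterations) the optimizer
reaches $<10^{-2}$ and beats equal-budget uniform random search in median
over 10 seeds; an ablation shows that removing the pressure-gradient term
degrades convergence on a *shifted* sphere — the shift matters, because
with the optimum at the origin the gravitation term $-g\,x$ alone already
solves the problem.

## Evaluation metrics

A $C\times C$ confusion matrix (rows = truth) is reduced one-vs-rest per
class to (TP, FP, FN, TN), from which per-class accuracy
$(TP{+}TN)/\text{total}$, precision, recall, F-score $2PR/(P{+}R)$, the
Matthews correlation coefficient, and the geometric mean
$\sqrt{\text{sensitivity}\times\text{specificity}}$ are computed, all as
percentages, plus an unweighted macro-average row. The G-mean is defined on
sensitivity/specificity (not precision/recall): only that reading is
arithmetically consistent with the published per-class tables this layout
mirrors, a consistency the test suite checks cell by cell. Per-class
accuracy is the one-vs-rest accuracy — the reading under which each class
can carry a distinct accuracy value. Zero-denominator cases (F, MCC,
G-mean) return 0 by explicit convention. Tables are rendered at two
decimals for presentation; all computation and the CSV outputs keep full
precision.

## Synthetic data

`generate_images()` draws three textured classes built from random ellipse
fields plus Gaussian blur and pixel noise: VT as a dense field of small
dark ellipses on a bright background (nuclei-rich viable tissue), NVT as
sparse, larger, low-contrast blobs (necrotic fragmentation), NT as smooth
low-frequency background (stroma). A `separability` knob in $[0,1]$
linearly interpolates each class's texture parameters between one common
average set (0: the three classes are identically distributed, so any
classifier sits at chance) and fully distinct sets (1). Default class
counts 345/263/536 mirror a realistic VT/NVT/NT imbalance so the
imbalance-sensitive metrics (G-mean, MCC) are exercised; default patch size
is 128 px. `generate_features()` provides a feature-level stand-in: a
three-component Gaussian mixture with class-mean separation given in units
of the within-class standard deviation.

What the generator does **not** emulate: H&E stain distributions, optical
blur/artifacts, annotation noise, or real osteosarcoma morphology. Passing
the synthetic suites therefore demonstrates that the machinery — filtering,
feature extraction, sparse stacking, tuning, evaluation — recovers signal
that is present by construction; it says nothing about accuracy on real
slides, which requires the user's own data via `read_patches()`.

`split_dataset()` performs stratified splitting (80/20 and 70/30 presets;
both are first-class because per-phase reports at both ratios are the
conventional presentation), with per-class sizes within one sample of the
exact products.

## Reproducibility and numerical choices

One global seed fans out deterministically to per-stage seeds
(`stage_seed()`), so a stage can be rerun in isolation; two runs with the
same configuration produce byte-identical summaries and model files. Model
serialization is JSON with 17-significant-digit doubles, which round-trips
IEEE doubles exactly. Further conventions: cross-entropy predictions are
clipped at $10^{-12}$; the log-sigmoid saturates cleanly to 0/1 for
$|x|\ge 10^3$ rather than overflowing; non-finite parcel pressures are
ranked worst with a warning; a failing tuning objective scores the worst
fitness (100) instead of aborting the search.

## Problem sizes in the shipped tests

The test and acceptance suites run at desk scale by choice: gradient checks
on 6-input/4-hidden fixtures; oracle equivalence on images up to 8×8;
sphere benchmarks at 20×200 evaluations; the tuned-classifier check on 150
samples/class with a 4-dimensional search space, 5 parcels × 4 iterations,
and 100 fine-tuning steps; the image pipeline on 60 patches/class at 128 px
(and 48-px, width-0.25 networks for the smoke/determinism runs). Larger
runs only change the configuration, not the code paths.

## Known limitations

* The frozen-random feature extractor is a deliberate floor: with
  externally trained weights imported, features would be stronger on real
  tissue; nothing in the pipeline changes.
* Mini-batch conjugate-gradient training takes one conjugate step per batch
  and is markedly slower per epoch in R than the full-batch path; prefer
  full batch below a few thousand samples.
* The classifier stack is fixed to feed-forward sigmoid SAEs; denoising or
  variational variants, dropout, and convolutional autoencoders are out of
  scope.
* WDO is run synchronously; objective evaluations are not parallelized.
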