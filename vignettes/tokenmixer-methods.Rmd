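---
title: "Token-based hybrid models for histopathology classification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Token-based hybrid models for histopathology classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Breast-tumor histopathology slides are photographed at four microscope
magnifications (40x, 100x, 200x, 400x) and labeled twice: coarsely as benign
or malignant, and finely as one of eight tumor subtypes (benign: adenosis
AD, fibroadenoma FI, phyllodes tumor PH, tubular adenoma TU; malignant:
ductal DU, lobular LO, mucinous MU, papillary PA carcinoma). The package
implements four image classifiers for this task and the full protocol
around them — reading magnification-stratified collections, stratified
splitting, augmentation, training, and a metric suite — with a seeded
synthetic-image generator standing in for the real archive so that every
stage is testable end to end on a laptop-scale CPU budget.

## The four architectures

All models consume `224 x 224 x 3` RGB tensors in `[0, 1]`.

**Compact ViT.** The image is cut into non-overlapping `14 x 14` patches
(`N = HW / P^2 = 256` of them), each flattened (588 values) and linearly
projected to a `D = 64`-dimensional token. A learned positional embedding is
added, and eight pre-norm transformer encoder blocks follow: layer norm,
multi-head self-attention (`softmax(QK'/sqrt(d_K)) V`, 4 heads of per-head
dimension 64), a residual add, layer norm, a two-layer GELU MLP of widths
(128, 64), and a second residual add. The final representation is
layer-normalized, flattened (`256 x 64`), and classified through a
(2048, 1024) GELU MLP head.

**TokenLearner.** Same patch embedding at `D = 128` (no positional
embedding) and four encoder blocks of the same shape (4 heads, per-head
dimension 128, MLP (256, 128)). After the third block the token sequence is
reshaped to its `16 x 16` spatial grid and an adaptive tokenizer replaces
the 256 tokens with `S = 4`: a layer norm followed by four bias-free `3 x 3`
convolutions (GELU, GELU, GELU, sigmoid) produces `S` spatial attention
maps `alpha_i` with values in `[0, 1]`; each token is the spatial global
average of the grid multiplied elementwise by one map,
`z_i = GAP(X (*) broadcast(alpha_i))`. The remaining block runs on the 4
tokens; the head is a final layer norm, global average pooling, and a dense
classifier.

**ConvMixer.** A convolutional stem with kernel = stride = `p = 8` embeds
the image into a `28 x 28 x 256` map (`Z0 = BN(GELU(Conv(X)))`), followed by
six mixer blocks: a `9 x 9` depthwise convolution (spatial mixing) whose
GELU output is added to its input *before* batch normalization,
`Z' = BN(GELU(DW(Z)) + Z)`, then a `1 x 1` pointwise convolution (channel
mixing), `BN(GELU(PW(Z')))`. Global average pooling and a dense layer close
the model. The residual placement inside the first batch normalization is
deliberate: it reflects the printed composition of the reference design,
and the package implements it exactly as stated rather than the more common
post-normalization residual.

**TokenMixer.** The hybrid is the TokenLearner backbone whose tokenizer
additionally mixes the normalized token grid with a `5 x 5` depthwise
convolution plus batch normalization before the map-generating
convolutions. The depthwise stage acts on a 64-channel subset of the
128-channel grid (a partial depthwise convolution; the remaining channels
pass through untouched), adding exactly
`64 x (5*5) + 64 + 2 x 64 = 1,792` trainable parameters over TokenLearner.

## How the free hyperparameters were fixed

The reference design prints only four architecture totals — 36,376,521
(ViT), 577,282 (ConvMixer), 1,402,169 (TokenLearner), 1,403,961 (TokenMixer)
— together with the input geometry (224/14), the ViT depth (8) and head
count (4). Everything else (latent widths, MLP widths, token count, the
ConvMixer geometry) is under-determined, so the package fixes it by an
exhaustive integer constraint search (`search_architecture_configs()`)
whose closed-form counts must match all four totals exactly. Findings worth
recording:

- The ConvMixer solution is unique in the searched grid: width 256, stem
  patch 8, kernel 9, depth 6, 2-unit head.
- The ViT and TokenLearner totals are only reachable with a 2-unit softmax
  binary head (not a 1-unit sigmoid) and with a 7-parameter input
  standardization layer (per-channel shift and scale plus a global gain,
  initialized to the identity). Both are therefore part of the frozen
  configurations; builders still accept `n_classes = 1` for a sigmoid head,
  which the learnability tests use.
- The TokenMixer-minus-TokenLearner difference of exactly 1,792 parameters
  pins the depthwise stage to 64 channels with bias plus one batch
  normalization; inside a 128-channel backbone that is realizable only as a
  partial (channel-subset) depthwise convolution, which is how it is built.
- The tokenizer's four map convolutions are bias-free `3 x 3` filters with
  `S = 4` maps, matching the count decomposition and the published
  TokenLearner lineage; the map activation is a sigmoid (bounded maps), a
  choice the reference text does not state explicitly.

A consequence worth stating plainly: the binary and multi-class variants
cannot share these exact totals (an 8-way head adds parameters), so the
frozen totals are tied to the binary configurations.

## Training protocol

- Optimizer Adam, batch size 32, 100 epochs by default; learning rate 1e-3
  (the optimizer's conventional default — only the optimizer itself is
  prescribed). No early stopping and no schedules.
- Losses: binary cross-entropy for sigmoid heads, categorical cross-entropy
  for softmax heads.
- Splitting: per magnification stratum, 20% of each class is held out as
  the test set, then 20% of the remainder as validation — 64/16/20 overall.
  Within each class the order is shuffled by the seed, test is sliced
  first, and flooring remainders are assigned to training so the training
  partition is never starved.
- Augmentation (training partition only, applied on the fly each epoch):
  rotation within ±5°, width/height shifts within ±10%, zoom within ±0.1%,
  nearest-edge fill. The reference table lists `0.001` for the fill mode,
  which is not a valid fill policy; it is read as a typographical artifact
  and the fill defaults to nearest-edge replication.
- Multi-class runs use stratified threefold cross-validation on the
  train+validation pool, keeping the 20% test holdout untouched (the
  reference protocol does not state the cross-validation pool; this choice
  preserves the holdout).
- Class imbalance is addressed by augmentation only — no class weights.

## The autodiff engine

The models run on a compact reverse-mode automatic differentiation engine
written as part of the package, keeping the whole stack self-contained and
auditable in R: define-by-run nodes over plain R arrays,
BLAS-backed matrix products, im2col convolutions, shift-and-accumulate
depthwise convolutions, exact (Phi-based) GELU, row-wise softmax, layer and
batch normalization, and composite ops for batched multi-head attention and
map-pooled tokenization. Every primitive's analytic gradient is tested
against central finite differences; attention and the metric suite are
additionally tested against independent brute-force oracles. Batch-norm
running statistics are state, not parameters, and are excluded from the
trainable-parameter inventory; functional (single-frame) forms of the
ConvMixer stages evaluate batch normalization in inference mode with
identity statistics so that scalar oracles are well defined.

## The synthetic generator

`synthetic_spec()` / `generate_dataset()` emulate the archive's *structure*,
not its histology: a BreakHis-style directory tree over 4 magnifications
and 8 subtypes, with default counts equal to the reference per-cell counts
divided by 10 (rounded up), preserving the benign:malignant imbalance
direction (about 2.2:1 malignant). Each image is a Gaussian background
texture around a subtype-specific hue with Poisson-many soft elliptical
"nuclei" blobs (subtype-specific density and radius); magnification scales
blob radii proportionally and adds Gaussian blur at 40x/100x. Images are
rendered at 460 x 700 before the standard resize, exercising the resize
path with a realistic aspect ratio. Generation is a pure function of
`(spec, seed)` down to file bytes.

What this does and does not show: subtypes are separable mainly by color
and blob statistics, so passing tests demonstrate that the pipeline,
gradients and optimization are correct and that the models can fit a
learnable signal — they say nothing about stain physics, tissue morphology,
scanner variation, or the real archive's difficulty. Real-data accuracies
require the external archive and GPU-scale training and are out of scope.

## Numerical choices and degenerate inputs

- Softmax rows are max-shifted before exponentiation; layer norm uses
  epsilon 1e-6, batch norm 1e-5 and momentum 0.1.
- Undefined metric ratios (zero denominators) return 0 with a flag rather
  than raising, keeping batch evaluation total while preserving
  auditability; kappa with chance agreement 1 is flagged 0.
- The headline AUC is the trapezoidal ROC area (equal to the Mann-Whitney
  pair-counting statistic with ties as 1/2); the sensitivity/specificity
  *ratio* at the 0.5 threshold is also reported as a secondary diagnostic
  because the reference text prints that ratio under the AUC heading, yet
  its published AUC values are only consistent with the conventional ROC
  area. Similarly both G-mean variants are reported: the printed
  `sqrt(precision*recall/(precision+recall))` (maximum `sqrt(1/2)`) and the
  conventional `sqrt(sensitivity*specificity)`.
- Classification ties break deterministically toward the lower class index.
- `kappa_stat()` carries the `_stat` suffix to avoid masking `base::kappa`.
- Seeded streams (`seed_rng()`) are isolated from R's global RNG so
  generation, splitting, shuffling and augmentation compose reproducibly.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run the full-size builders for
parameter auditing only; training-based checks use a width-reduced
TokenMixer (latent 16, one encoder block, two heads, sigmoid head) on a
two-subtype synthetic set of 100 images per class at 200x, reaching >= 95%
training accuracy within a handful of epochs. Oracle checks use 100 random
attention instances, 1,000 random confusion matrices, and 40 random score
sets. These sizes were chosen so the whole suite runs in minutes on one CPU
while still exercising every stage at full fidelity.

## Known limitations

- Full-scale training of the frozen (unreduced) configurations is CPU-days
  in this engine; the package is built for correctness and desk-scale
  experiments, not throughput.
- Dropout appears in the reference ViT lineage but carries no parameters
  and is omitted here (regularization is of no consequence at desk scale);
  if added later it would not change any audited count.
- The multi-class (8-way) heads necessarily differ in parameter count from
  the audited binary totals.
- Whole-slide (pyramidal) inputs and stain normalization are out of scope;
  images are plain PNG/JPEG files.
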