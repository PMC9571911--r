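---
title: "Joint-point detection with a truncated high-resolution network and shifted-window attention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint-point detection with a truncated high-resolution network and shifted-window attention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrst)
```

## The problem and the approach

Body-size estimation of pigs from overhead footage needs the image
coordinates of anatomical landmarks. This package implements a top-down
pipeline for that task: an object detector (consumed as a JSON contract,
never computed here) supplies per-animal boxes with a posture class, and a
heatmap-regression network predicts ten joints — left/right neck, shoulder,
abdomen, hip, tail — inside each *standing* box. Lying animals are kept in
the output but not decoded: their dorsal landmarks are occluded from an
overhead view, so posture gating is part of the method, not a shortcut.

The network trades the fourth, parameter-heavy stage of an HRNet-w48
backbone for a small stack of shifted-window transformer blocks:

- **Backbone (stages 1–3).** Stride-4 stem (two 3×3/stride-2 convolutions to
  64 channels), four bottleneck blocks to 256 channels, then parallel
  branches at 1/4, 1/8, 1/16 resolution with widths 48/96/192. Stage 2 runs
  one fusion module, stage 3 runs four; each module applies four residual
  basic blocks per branch and then resamples and sums every branch into
  every output (strided 3×3 convolutions downward; 1×1 convolution, batch
  norm and nearest-neighbour upsampling upward). The final stage-3 module
  fuses only into the highest-resolution branch, which is the only branch
  consumed downstream; the other branches pass through un-fused. This
  terminal-module convention matches the reference implementation of the
  pose backbone (its last stage does the same) and is what yields the
  17.3 M total; fusing all three outputs in the last module would add
  ~0.33 M parameters that the model never uses.
- **Attention layer.** The 1/4-resolution map is patch-embedded by a
  convolution with kernel = stride = 4 to 96 dimensions and
  layer-normalized: a 384×288 input gives a 24×18 token grid (432 tokens).
  Four transformer blocks follow in regular/shifted pairs with window 6,
  48 heads, MLP ratio 4, learned relative-position bias and qkv bias.
  Shifted blocks roll the grid by ⌊6/2⌋ = 3 and add a per-window mask that
  zeroes attention between tokens that were not contiguous before the roll.
- **Head.** A single transposed convolution (kernel 4, stride 4, 96→10,
  with bias, no trailing normalization or activation) produces per-joint
  heatmaps at 1/4 input resolution.

### Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| input size | 384 × 288 | px (W × H) | working resolution; divisible by 32 and by 16·window |
| branch widths | 48/96/192 | channels | reference w48 widths, pinned by the 17.3 M / 63.6 M totals |
| embed dim / depth | 96 / 4 | — | attention layer capacity |
| window / shift | 6 / 3 | tokens | 6 divides both grid sides (24, 18); shift = ⌊window/2⌋ |
| num. heads | 48 | — | as specified for the model; head dimension 96/48 = 2 is unusually narrow, and the parameter count is almost insensitive to it (only the bias-table width changes), so it is exposed in the configuration |
| target σ | 2 | heatmap px | Gaussian target width, standard for 96×72 maps |
| box padding | 1.25 | — | context margin around detections before cropping |
| lr schedule | 1e−3, ×0.1 at 600/800, 1000 epochs | — | published schedule; Adam |
| augmentation | rotation ±45°, scale 0.65–1.35, flip 0.5 | — | published ranges |

Open points resolved as package conventions: training starts from random
initialization (no classification pretraining); batch size defaults to 16
with no weight decay; heatmap targets use peak amplitude 1.0 rather than a
normalized density; decoding uses quarter-pixel refinement and no flip
test; ground-truth boxes are used for training crops, detector JSON for
inference.

## Coordinate and encoding conventions

All coordinates are 0-based pixel-centre; boxes are `(x, y, w, h)` with
top-left origin. Crops expand the box to the 4:3 output aspect, scale by
the padding factor, optionally rotate about the box centre and flip; the
same 2×3 affine maps the joints, and flipped crops swap left/right labels
through the pair table (indices 1–2, 3–4, 5–6, 7–8, 9–10). Affine
round-trips invert to below 1e−3 px; joints leaving a crop are demoted to
invisible and carry zero loss weight (COCO visibility semantics: only
`v = 0` is excluded). Decoding adds 0.25 px toward the larger neighbour on
each axis before scaling by the stride, bounding the encode→decode
round-trip error by one heatmap stride (4 input px); the property suite
asserts this bound for arbitrary joint positions.

## Evaluation

OKS between a prediction and a ground-truth instance is

$$\mathrm{OKS} = \frac{\sum_i \exp(-d_i^2 / (2 s^2 k_i^2))\,[v_i>0]}{\sum_i [v_i>0]},
\qquad k_i = 2\sigma_i,\quad s = \sqrt{wh},$$

with the per-joint σ the packaged double-annotation estimates
(`pig_sigmas()`; shoulders and hips, the least repeatable joints, have the
largest values). "Object scale" is read as the square root of the box area,
the COCO convention. AP/AR average over OKS thresholds 0.50:0.05:0.95 with
greedy per-image matching in descending score order and 101-point
interpolated precision; a second, independently coded brute-force evaluator
(exhaustive best-match search, literal max-precision-at-recall
interpolation) pins this behaviour in the tests.

`estimate_sigmas()` returns, per joint, the per-axis maximum-likelihood
standard deviation of an isotropic Gaussian annotation-error model,
$\hat\sigma_i = \sqrt{\tfrac{1}{2}\,\overline{d_i^2/s^2}}$. A scalar
standard deviation of the raw distances would estimate the Rayleigh spread
instead and systematically miss a planted per-axis noise (by the factor
$\sqrt{2-\pi/2}$); the per-axis form recovers the generator's noise exactly
in expectation, which the round-trip test checks at ~1200 doubly-labeled
joints.

## The profiler and its conventions

Parameters are counted exactly from the graph structure — convolution and
linear weights, biases, batch/layer-norm affine pairs, relative-position
bias tables — and the count is asserted equal to a brute-force enumeration
of materialized tensors. FLOPs are multiply-accumulates (1 MAC = 1 FLOP)
for one forward pass: `k²·C_in·C_out` per output position for convolutions
(per *input* position for the stride-equal transposed convolution),
`d_in·d_out` per token for linear layers, and `T²·d` per window each for
attention logits and the weighted sum; normalizations, activations,
sampling and softmax are excluded. Absolute GFLOPs depend on this
convention; the reduction percentages barely do, because the convention
cancels in the ratio — which is why the comparison table, not the absolute
numbers, is the primary surface. At 384×288 the analytic counts come to
20.6 GMACs for the truncated model versus 35.3 for the four-stage baseline
with a 10-channel 1×1 prediction head.

## The synthetic generator

`generate_synthetic_pigs()` draws each animal as an oriented ellipse on a
dark background; standing animals carry one high-contrast colour marker per
joint at fixed positions in the body frame (neck pair at 0.62 of the
semi-major axis, shoulders at 0.35, abdomen at mid-flank, hips at −0.35,
tail at −0.68), lying animals are flatter, unmarked and unlabeled. Boxes
are tight around the ellipse; a parallel detection table carries the
posture class with score 1.0. Everything is seeded: the same spec and seed
produce byte-identical annotation files.

What the generator emulates: exact landmark geometry under the full crop /
augmentation / encoding pipeline, multi-animal scenes, posture gating, and
a controllable double-annotation noise (`perturb_annotations()`, per-axis
std in units of object scale). What it does not emulate: realistic pig
appearance, occlusion, lighting, motion blur, or annotation ambiguity.
Passing the overfit and property tests therefore demonstrates that the
implementation is correct and trainable end to end — not that the model
reaches any particular accuracy on real footage, which requires GPU-scale
training on real data and is out of scope here.

The overfit check trains the reduced preset (widths 8/16/32, one stage-3
module, two blocks per branch, embedding 32 with 4 heads, one transformer
pair, 96×96 input — a 6×6 token grid, one window) for 150 full-batch Adam
steps on 8 scenes and requires a ≥10× loss reduction and AP = 1.0 at OKS
0.5 on the training set. Its evaluation uses a uniform σ = 0.05: the
packaged real-footage sigmas (~0.005) describe annotation noise on
2560×1440 frames, where the OKS decay length s·k spans several pixels; on a
96×96 crop that length would shrink below one pixel — under the intrinsic
4 px quantization bound of stride-4 heatmap decoding — so no heatmap method
could register a match at any threshold. σ = 0.05 is the magnitude of
published animal-keypoint constants and keeps the check meaningful:
decoded joints must land within ~7 px of ground truth on the original
frames to count.

## Numerical choices and degenerate inputs

- Batch norm uses minibatch statistics in training and running averages
  (momentum 0.1, ε 1e−5) at inference; layer norm uses ε 1e−5.
- The −∞ surrogate in attention masks is −1e9, which drives masked softmax
  weights below 1e−6 while keeping arithmetic finite.
- Window partitioning refuses grids not divisible by the window (no padding
  dialect); the model constructor rejects such configurations before any
  training starts. Inputs not divisible by 32 are rejected by the stem.
- Degenerate boxes (non-positive width/height) error at crop time;
  annotations with the wrong joint count error at read time naming the
  image; ground truth without labeled joints is skipped with a warning.
- Training aborts with a diagnostic on non-finite loss rather than
  continuing silently.
- Initialization: He-normal for convolutions, N(0, 0.02) for linear weights
  and bias tables, N(0, 0.001) for the head deconvolution, unit/zero norm
  affines; all driven by the R RNG so a single seed reproduces loss curves
  bit-for-bit on one device.

## Problem sizes used by the test suite

Gradient checks run on single-digit tensor shapes against central finite
differences. Attention oracles use grids up to 12×12. Sigma recovery uses
~120 instances (≈1200 doubly-labeled joints). The overfit run is 150 steps
of batch 8 at 96×96 (about a minute on one CPU core). Architecture
profiling builds the canonical graphs structurally — parameters are
materialized only where a test enumerates them — so the full suite stays
within a few minutes.

## Known limitations

- The canonical-width model is far too slow to train in R; the package
  trains reduced presets only. The canonical graph exists for profiling,
  structural checks and (slow) single forwards.
- The attention head count of 48 on a 96-dimensional embedding (head
  dimension 2) is implemented as specified; if it is a misprint for 4
  heads, the configuration key `model.attention.num_heads` changes it, and
  the parameter totals move by under 0.02 M.
- The evaluator reproduces the COCO matching and interpolation semantics as
  documented and is pinned by an independent oracle, but bit-for-bit
  agreement with any particular external evaluator binary is not asserted.
- Posture detection itself (the first pipeline stage) is consumed as a
  detection JSON and never computed.
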