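---
title: "Lightweight detection transformers for weed detection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lightweight detection transformers for weed detection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phrfdetr)
```

## The problem and the model family

Weed detection for upland rice asks for a detector that is accurate enough
to drive a weeding robot and light enough to run on its hardware. The
package implements a family of real-time detection transformers built for
that trade-off: a convolutional backbone feeds a hybrid encoder (one
attention block on the deepest pyramid level plus a CNN cross-scale fusion
path), and a transformer decoder predicts up to 300 `(class, confidence,
box)` triples directly, with no non-maximum suppression.

Four components can be toggled against an r18-scale baseline, giving the
eight ablation variants of `variant_table()`:

* **PGRNet** replaces the ResNet18 feature extractor;
* **AIFI-HiLo** replaces full multi-head attention in the encoder's
  intra-scale block;
* **RetC3** replaces the RepC3 fusion blocks in the cross-scale path;
* **Focaler-WIoUv3** replaces GIoU in the decoder's box objective.

All layers run on a compact array-based neural core with reverse-mode
automatic differentiation that is part of the package, so every forward
path here is executable and trainable, and every complexity number is
recomputed from the actual module tree rather than quoted.

## PGRBlock and PGRNet

`pgr_block(C)` combines three lightweight-convolution ideas. A 3x3
convolution runs over all `C` channels. The *first half* of its output
(the partial-convolution principle: a contiguous channel slice is
convolved, the rest passes through untouched) enters a 5x5 convolution;
the first quarter of that result enters a 7x7 convolution. The three
contributions — `C/4` channels from the 7x7 path, `C/4` untouched
channels of the 5x5 stage, `C/2` untouched channels of the 3x3 stage —
are concatenated back to `C` channels and a residual add closes the
block. `C` must be divisible by 4 so the slices are integral. With zero
weights and normalization disabled the block is exactly the identity,
which the tests assert.

`build_pgrnet()` stacks five 3x3 convolutions (each stride 2, so the
stride product over the network is 32) and four PGRBlocks in the
three-stage layout *conv, conv, PGR / conv, PGR, conv / PGR, conv, PGR*,
tapping the pyramid after the PGRBlocks at strides 8, 16 and 32. The
placement of the stride-2 convolutions is forced: with exactly five
convolutions and stride-1 residual blocks, every convolution must
downsample to reach stride 32.

## AIFI-HiLo

The encoder's intra-scale block flattens the stride-32 map to tokens,
adds 2-D sinusoidal positions, applies attention plus a feed-forward
block with post-norm residuals, and reshapes back. In the baseline the
attention is standard multi-head self-attention. In AIFI-HiLo it is
**HiLo**: of the `Nh` heads, `floor(a * Nh)` low-frequency heads attend
from full-resolution queries to `s x s` average-pooled keys and values,
and the remaining high-frequency heads run non-overlapping `s x s` window
attention; the two branch outputs are concatenated. Each branch carries
its own output projection on its own sub-dimension, so the total
projection cost `3 d^2 + d_hi^2 + d_lo^2` never exceeds the `4 d^2` of
standard attention — the swap cannot add parameters, and the package
asserts this for every split fraction.

Defaults `a = 0.5`, `s = 2` keep both branches active and suit the 20x20
grid that a 640 input produces at stride 32. Maps not divisible by the
window are reflect-padded and cropped back (reflect rather than zero, to
avoid biasing window statistics with artificial tokens); positions enter
the query/key paths only, and the pooled value path reads the raw map.

## MaSA, RetBlock and RetC3

The spatial-decay attention used inside RetC3 is decomposed into two
one-dimensional passes: attention along each column with an `H x H` mask,
then along each row with a `W x W` mask, where `spatial_decay_mask(L,
gamma)` is `gamma^|n - m|` — closer tokens attend more strongly, distant
ones are attenuated. Decomposition makes the cost linear rather than
quadratic in the token count, which the profiler quantifies.

Two published conventions exist for applying such a mask; the package
multiplies the post-softmax scores elementwise by the mask and
renormalizes each row, which keeps every attention row a convex
combination and is numerically stable for any `gamma` in `(0, 1]`. The
per-head decay factors default to a log-spaced schedule on `[0.6, 0.98]`
(stronger decay on early heads), exposed in the configuration. As
`gamma` shrinks toward zero each token attends only to itself, a limit
the test suite verifies monotonically.

`ret_block()` wraps MaSA in a pre-norm transformer unit with a 3x3
depthwise convolution as a local positional term on the input (the
"positional enhancement" — some concrete form is needed, and a depthwise
convolution is the cheapest local one) and a 2x FFN. `retc3_block()` is
C3 wiring: two 1x1 projections, `depth = 3` RetBlocks on one branch
(mirroring RepC3's depth so the ablation is a like-for-like swap),
concatenation and a 1x1 output projection.

## The box-loss family

All losses act on corner-form boxes and are finite for every pair,
including degenerate zero-area boxes, via an epsilon denominator guard
that reproduces the stated conventions (IoU 0 on empty union,
distance ratio 1 on an empty enclosure) instead of NaN:

* `box_iou`, `giou_loss` — the classical quantities;
* `wiou_v1_loss` — `exp(center_dist^2 / (Wg^2 + Hg^2)) * (1 - IoU)`, the
  enclosing-box dimensions gradient-detached;
* `wiou_v3_loss` — multiplies by the non-monotonic focusing coefficient
  `r = beta / (delta * alpha^(beta - delta))`, with outlier degree `beta`
  = detached IoU loss over its running mean, held in a `wiou_state()`
  updated by per-iteration exponential moving average;
* `focaler_iou` — the piecewise-linear remap `[(IoU - d) / (u - d)]`
  clamped to `[0, 1]`;
* `focaler_wiou_v3_loss` — the composite `L_WIoUv3 + IoU - IoU_Focaler`,
  implemented literally as an additive correction; at `(d = 0, u = 1)`
  it collapses to WIoUv3 exactly.

Defaults `d = 0, u = 0.95, alpha = 1.9, delta = 3, momentum = 0.01`
follow the reference settings of the original Focaler and WIoU
formulations.
`detection_box_objective()` keeps the standard detection-transformer
weighting (L1 5, IoU-family 2) and swaps only the IoU term; the Hungarian
matching cost keeps plain GIoU.

## Complexity accounting and calibration

`profile_model()` counts parameters in closed form per layer
(kernel-width x kernel-height x C_in x C_out / groups, plus biases and
normalization affine pairs) and cross-checks the sum against the actual
tensor sizes — the two disagreeing is an error, not a warning. FLOPs are
layer-wise output-area x per-pixel-parameter products on the fused
inference graph (RepConv fuses to its 3x3 branch), with one
multiply-accumulate counted as two operations — the convention under
which the published figures for comparable YOLO-scale detectors are
standard. Normalization, activations and pooling are not charged, as in
the common profilers. Serialized size is `params * B_params / 1024^2`
with `B_params = 2` (half-precision export), the only byte width
consistent with the published size column.

The architecture leaves several widths open (PGRNet stem and stage
widths, fusion-block hidden widths, the encoder and decoder FFN widths).
These were calibrated once, by coordinate search over a small integer
grid, so that the default builds profile to the published complexity of
the corresponding variants, and then frozen as the `phrf_config()`
defaults: PGRNet stem 16 and stage widths (48, 128, 256); RepC3 hidden 96
at the stride-8 insertion and 128 elsewhere; RetC3 hidden 24/48/144 at
strides 8/16/32; encoder FFN 2048; decoder FFN 1152. The decoder follows
the standard r18-scale setting (3 layers, 300 queries, width 256) with
multi-head cross-attention over the flattened multi-scale memory, memory
keys/values projected once and shared across layers, and query selection
by per-token classification score; denoising query groups are omitted (a
training aid with no effect on the inference graph that the accountant
measures).

## Metrics

`evaluate_detections()` computes precision `TP / (TP + FP)` and recall
`TP / (TP + FN)` at IoU 0.5 over the supplied detections, per-class AP as
the area under the precision-recall curve (101-point interpolation by
default, continuous all-point integration as an option), mAP50 and
mAP50:95 as class means, and F1 as the harmonic mean. Matching is greedy
in descending score, one-to-one per ground-truth box, ties broken to the
higher IoU and then the lower detection index. The AP code is tested
against a brute-force ranked-list oracle. `confusion_matrix_det()` adds
a background row (false detections) and column (missed truths) around
the class block.

## The synthetic scene generator

`generate_scene()` emulates the statistical shape of the task, not its
photographic appearance: a textured soil background; five plant classes
drawn as rosettes of elliptical lobes whose lobe count, elongation and
hue differ by class (so a trivial color classifier already separates
them, which a test checks — the fixtures are learnable); tight boxes from
the drawn masks; global illumination jitter; and the three layouts
observed in field imagery — single target, multiple targets, and mutual
occlusion, the last guaranteeing a box pair with IoU above 0.1. Output
is bit-identical for a fixed spec and seed.

What it deliberately does not model: leaf venation and fine texture,
perspective and ground-plane geometry, motion blur, inter-plant shadows,
growth stages, and any background vegetation. Tests passing on these
scenes therefore demonstrate that the architecture, losses, matching and
metrics interoperate and can fit data — they say nothing about accuracy
on real field imagery, which would require the real dataset and
GPU-scale training.

## Problem sizes used by the test and smoke harnesses

Numerical forward tests run reduced widths (encoder width 32, two decoder
layers, 20 queries) on 64 x 64 inputs; complexity checks always profile
the full-width builds at 640 x 640, which costs no tensor arithmetic.
The end-to-end smoke harness trains the full final-variant wiring at the
reduced widths (one decoder layer) on twenty 64 x 64 single-target
scenes with Adam (learning rate 2e-3, 80 epochs), evaluating on the
training images as an overfit check. Because this harness trains at
batch size one, its evaluation normalizes each map with its own
statistics rather than the running averages: statistics collected one
image at a time track the most recent images, not the set, and are not a
faithful inference statistic in that regime (the `batch_stats` option of
`predict_detections()`; `bn_recalibrate()` offers the cumulative-average
alternative). These sizes are the package's chosen desk-scale study
conditions; the published training schedule for the real dataset (300
epochs, batch 8, learning rate 1e-4 on GPU hardware) is not reproduced
here.

## Known limitations

* The autodiff core favors clarity over throughput; it is adequate for
  desk-scale training and exactness checks, not for full-resolution
  training runs.
* Deformable attention and denoising training are not implemented; the
  decoder uses dense cross-attention with shared projected memory.
* Published accuracy columns (P/R/mAP on the real weed dataset) are out
  of reach by construction — the dataset is not public — and are not
  targets of any test in this package.
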