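---
title: "Attention residual U-Net segmentation: models, training and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention residual U-Net segmentation: models, training and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the model and
its assumptions, the parameters that matter, what the synthetic data
emulates, the numerical choices, and the design decisions taken where
the design was genuinely open. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## Problem and model

Gastrointestinal lesion segmentation assigns every pixel of an
endoscopy or capsule-endoscopy frame to lesion or background. The
package implements a family of fully convolutional encoder–decoder
networks for this task, all built from three blocks:

* **Plain convolution block** — two stages of 3×3 same-padding
  convolution → batch normalization → ReLU. Spatial size is preserved;
  outputs are nonnegative.
* **Residual unit** — `y = F(x) + shortcut(x)`, with `F` the plain
  block above and the shortcut either the identity (equal channel
  counts) or a 1×1 convolution projection. The additive shortcut lets
  gradients bypass the transformation, easing optimization of deeper
  encoders; with `F` zeroed the unit is exactly the identity, a
  property the suite checks bit-exactly.
* **Additive attention gate** — from encoder features `x_l`
  (C×H×W) and the gating signal `g` taken one level deeper (2C
  channels, H/2×W/2), the gate computes
  `α = sigmoid(ψ(relu(θ(x_l) + φ(g))))` where `θ` is a 1×1 convolution
  with stride 2 (bringing `x_l` to `g`'s resolution), `φ` and `ψ` are
  1×1 convolutions, and each convolution is followed by batch
  normalization before its nonlinearity. The coarse `α` is upsampled
  bilinearly back to `x_l`'s resolution and multiplied into every
  channel. `α ∈ [0,1]` by construction: with all gate weights zero,
  `α = 0.5` everywhere.

The **attresunet** architecture uses residual units in the encoder and
bottleneck, attention gates on every skip connection, and plain
convolution blocks in the decoder; **attunet** drops the residual
structure; **unet** additionally drops the gates. Encoder stages halve
resolution (2×2 max pooling) and double channel width; decoder stages
upsample 2× (nearest neighbour followed by a 3×3 convolution, batch
normalization and ReLU), merge the (gated) skip by concatenation, and
apply a plain block. A 1×1 convolution and sigmoid give per-pixel
foreground probabilities.

Assumptions: binary masks (one foreground class), 2D single-frame
input, input sizes divisible by `2^depth`.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `depth` | 4 | downsampling stages; receptive field grows as `2^depth` |
| `base_filters` | 64 | width of stage 1; widths double per stage |
| `input_size` | 128×128 | working resolution (px); images are resized to it |
| `batch_size` | 40 | minibatch size |
| `epochs` | 50 | maximum epochs |
| `learning_rate` | 1e-3 | Adam step size (0 = strict no-op, for degenerate runs) |
| `beta1`, `beta2` | 0.9, 0.99 | Adam moment decays — 0.99 (not 0.999) follows the stated protocol and is kept as stated |
| `early_stop_patience` | 10 | epochs without validation-loss improvement before halting |
| `threshold` | 0.5 | probability cut for binarization |
| rotation / zoom | 20° / 0.1 | augmentation magnitudes, each transform drawn with probability 1/2 |

The protocol source states optimizer, batch size, epoch budget and the
use of early stopping but not the learning rate, patience, loss
function or augmentation magnitudes; the defaults above are the
conventional choices for sigmoid-output binary segmentation (binary
cross-entropy; Dice loss is available via `train_config(loss =
"dice")`), and mild augmentation ranges typical in medical imaging.
All are configurable.

## Synthetic scenes: what they emulate and what they do not

`generate_scene()` produces endoscopy-like frames: a pink-brown
smoothly textured background (low-resolution Gaussian field upsampled
bilinearly), one or more red-dominant lesion blobs, and additive
Gaussian pixel noise clipped to [0,1]. Lesion boundaries are radially
perturbed ellipses, `radius(θ) = base·(1 + irregularity·s(θ))` with
`s` a low-order random trigonometric series — cheap, smooth and
reproducible. The mask is 1 exactly on lesion pixels, so ground truth
is noiseless. Radius range 4–14 px on a 64×64 scene spans small to
large lesions (foreground fractions differing by more than 4×),
mirroring the size diversity of the public polyp and red-lesion
collections.

What they do **not** have: specular highlights, vignetting, instrument
artifacts, mucosal folds, lesions with ambiguous annotated borders, or
JPEG artifacts. Passing the end-to-end test therefore shows the
pipeline — generation, augmentation, optimization, early stopping,
evaluation — learns genuinely from pixels, not that the architecture
reaches clinical-dataset accuracy; the published benchmark numbers
require the original datasets and full-scale training, which are out
of scope here.

## Numerical choices

* Arrays are `(H, W, C, N)`; convolutions run by im2col lowering to a
  BLAS matrix product (C++/RcppArmadillo), and all backward passes are
  exact adjoints, verified against central finite differences.
* Batch normalization uses biased batch variance, ε = 1e-5, and
  running statistics with momentum 0.1; inference always uses the
  frozen running statistics, making prediction deterministic.
* Weight initialization is He (variance `2/fan-in`); batch-norm scale
  and shift start at identity with running mean 0 / variance 1, so a
  freshly built block at default statistics applies a known
  `1/sqrt(1+ε)` scale — the hand-computed oracles in the tests include
  this factor.
* Binary cross-entropy clamps probabilities to `[1e-7, 1-1e-7]`.
* Bilinear resampling (attention-coefficient upsampling and image
  resizing) uses separable align-corners interpolation matrices; masks
  are always resampled nearest-neighbour so they stay exactly binary.
  The same kernels serve the network's differentiable path and
  `resize_sample()`, keeping one coordinate convention throughout.
* Mask binarization on load thresholds at the source bit-depth
  midpoint (>127 on 8-bit), idempotent on already-binary masks.
* `split_dataset()` sizes validation and test as `round(n·fraction)`
  and gives the remainder to training (deterministic, favours
  training data). The default split is 60/20/20; an 80/20 protocol is
  `dataset_split(0.8, 0, 0.2)`.
* Rotation/zoom fill out-of-frame pixels with 0 (image) and background
  (mask) rather than inventing tissue texture. Augmentation is applied
  on the fly to training batches only, never to validation or test
  data.
* Dice and Jaccard of two empty masks are defined as 1 (perfect
  agreement). `evaluate_dataset()` reports per-image means as the
  headline and pooled-pixel metrics alongside, since aggregation
  conventions differ across the literature.
* Early stopping monitors validation loss, halts after `patience`
  epochs without strict improvement, and restores the best epoch's
  weights *and* running statistics.

## Open design points and how they were settled

* **Residual structure in the decoder.** The architecture description
  contains both a statement that residual modules appear in encoder
  and decoder and a later, more specific statement that the decoder
  has none; the specific statement wins: residual encoder, plain
  decoder.
* **Block ordering.** Convolution → batch norm → ReLU (post-activation
  ordering) throughout, matching the assembly description; the sum
  `F(x)+x` is not followed by an extra activation, which is what makes
  the zeroed-`F` identity exact.
* **Attention-gate intermediate width** defaults to half the gating
  channels (minimum 1), a common convention keeping the gate cheap;
  configurable.
* **Coefficient upsampling** is bilinear — the 2D analogue of the
  trilinear interpolation named in the 3D-flavoured description of the
  gate.
* **Decoder upsampling** is nearest-neighbour + convolution (an
  "upsampling layer"), avoiding transposed-convolution checkerboard
  artifacts.
* **Bottleneck block type** follows the encoder convention (residual
  for attresunet), as it lies on the contracting side of the U.

## The synthetic study

The acceptance script and the end-to-end test train a small
`attresunet` (depth 3, base 8 filters, 142k parameters) and the `unet`
baseline on 200 synthetic 64×64 scenes (60/20/20 split) for at most 15
epochs. Problem sizes were chosen so the full study runs on a single
CPU in minutes while still exercising every component at realistic
depth. Two deliberate departures from the full-scale defaults:

* **Batch size 10** rather than 40. With 120 training scenes, batch 40
  yields 3 optimizer steps per epoch — an order of magnitude fewer
  steps per epoch than any full-scale run of this protocol, which is
  an optimization-budget artifact of miniaturization, not a property
  of the method. Batch 10 gives 12 steps per epoch so that the
  15-epoch budget corresponds to a sensible optimization length.
* **Epoch cap 15** rather than 50, for the same miniaturization
  reason; early stopping remains active.

## Known limitations

* CPU-only, double precision; full-width 128×128 training at
  `base_filters = 64` is possible but slow — the package is built for
  method study and small experiments, not production GPU training.
* Binary segmentation only; no multi-class head.
* Training-mode batch normalization with very small batches (< 4) can
  be noisy; the defaults avoid this.
* Bit-exact reproducibility holds for a fixed platform/BLAS; across
  different BLAS builds results agree only to floating-point
  tolerance.
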