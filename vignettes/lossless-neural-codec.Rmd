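---
title: "Methods: a learned lossless codec for grayscale images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a learned lossless codec for grayscale images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`lfc` compresses an 8-bit grayscale image $x \in \{0,\dots,255\}^{W\times H}$
losslessly by splitting the work between a conventional codec and learned
prediction. The polyphase decomposition assigns each pixel of the 2×2
sampling lattice to one of four half-resolution subimages
$x_a, x_b, x_c, x_d$ (with 1-based indexing, $x_a$ holds the odd-row,
odd-column pixels — the top-left corner of every 2×2 block). $x_a$ is
stored with a lossless base codec; the other three are coded
sequentially in the order $d \to b \to c$, each by a network that sees
all previously coded subimages (inputs $\{a\}$, $\{a,d\}$, $\{a,d,b\}$).
The three networks are independent — no shared parameters — because each
solves a different conditional problem with a different input arity.

Each network produces, from one forward pass over a shared latent grid
(the *middle matrix*):

* a real-valued pixel prediction $\hat Y$ for its target subimage, and
* a per-pixel probability distribution $\hat p$ over 511 residual
  classes, via a U-Net head ending in a channelwise softmax.

The prediction is integerized — rounded half away from zero and clipped
to $[0,255]$ — *before* the residual is formed, so the residual class

$$Q = (Y - \hat Y_{\mathrm{int}}) + 255 \in \{0, \dots, 510\}$$

is an exact integer difference and decoding is exact by algebra:
$Y = \hat Y_{\mathrm{int}} + Q - 255$. (Rounding a floating-point
residual instead would make losslessness hinge on tie-breaking
conventions; integerizing the prediction removes that hazard entirely,
while preserving the 511-class range, with class 255 meaning a perfect
prediction.) The classes are range-coded under the model's
distributions; since the decoder re-runs the identical inference on the
already-decoded subimages, no probability tables are transmitted. The
container stores dimensions, padding flags, the base-codec id, the model
version hash (so a decoder refuses the wrong model before emitting any
pixel) and a CRC-32 of the original pixels, making losslessness
self-verifying at decode time. The byte layout is fixed in `FORMAT.md`.

## Architecture choices

Published descriptions of this family of codecs leave the convolutional
details open; the fill-ins here are the canonical ones and all sizes sit
in `lfc_config()`:

* *feature extractor*: 3×3 convolution to `base_channels`, ReLU, one
  residual block (two 3×3 convolutions with an additive skip);
* *prediction head*: 3×3 conv, ReLU, 3×3 conv to one channel. The head's
  output is added to the **mean of the normalized input subimages**, and
  its last layer is zero-initialized. The head therefore learns an
  offset from the mean-of-available-phases predictor — a natural anchor
  for interleaved lattices — and an untrained model already predicts
  sensibly (its residuals are small on smooth content) instead of
  emitting noise;
* *probability U-Net*: `n_scales` downward processes (residual block +
  stride-2 3×3 convolution, channels doubling per scale, capped at 512)
  and `n_scales` upward processes (nearest-neighbour upsampling, 3×3
  convolution, concatenation with the matching encoder features, fusion
  convolution, residual block), closed by a zero-initialized 3×3
  convolution to 511 channels and a softmax. Zero initialization makes
  the untrained distribution uniform — the safe maximum-entropy start.
  Inputs whose sides are not multiples of $2^{\texttt{n\_scales}}$ are
  reflect-padded internally and cropped back.

Reference defaults are `base_channels = 64`, `n_scales = 4`,
`n_classes = 511`. Everything in this package's tests and acceptance
script runs the same code at desk scale (`base_channels = 4`,
`n_scales = 2`), chosen so the full suite — including a 200-image
losslessness sweep and a training run — completes in minutes on one CPU
core. The 511-class output is never reduced: it is structural.

All inference runs in deterministic double-precision C++ loops. The
losslessness argument needs encoder and decoder to produce bit-identical
activations, which a fixed summation order guarantees on a given
platform; the evaluation-precision contract here is 64-bit doubles
rather than 32-bit floats because that is R's native numeric and no
accelerator dictates otherwise.

## Training

The loss is $L = \lambda_{SPL} L_{SPL} + \lambda_{PPL} L_{PPL}$ with
both weights 1 by default:

* $L_{SPL}$ — mean absolute error between predicted and true pixels (on
  the 0–255 scale);
* $L_{PPL}$ — weighted cross-entropy
  $-\frac1N \sum_i w_{Q_i} \log \hat p_i(Q_i)$, natural log,
  probabilities floored at $10^{-12}$ inside the logarithm.

The class weights counter the extreme imbalance of residuals: a working
predictor concentrates nearly all mass around class 255, so plain
cross-entropy underweights exactly the rare, expensive large residuals.
The default schedule is a symmetric doubling staircase — weight 8 on
classes 0–99 and 411–510, 4 on 100–149 and 361–410, 2 on 150–199 and
311–360, and 1 on the central band 200–310. The published anchors fix
only weight 8 for classes 0–99 and weight 1 for 200–300; 200–300 is not
symmetric about class 255, so the weight-1 band is extended to the
smallest symmetric superset [200, 310] and the staircase in between is
the simplest monotone completion. `weight_schedule()` accepts any
symmetric, magnitude-monotone partition if a user prefers another
interpolation.

Reference training (the package defaults in `lfc_training_config()`):
Adam, batch 24, 2000 epochs, initial learning rate $10^{-3}$ halved
every 500 epochs, random 128×128 grayscale patches (RGB sources collapse
through BT.601 luma). Each network is supervised on its own subimage
with ground-truth teacher inputs — equivalent to coded inputs, because
coding is lossless. Training is deterministic under a fixed seed; two
identical runs produce bundles with identical version hashes.

The *smoke-scale* recipe used by the tests and the acceptance script
trains `base_channels = 4`, `n_scales = 2` networks for 120 epochs of
one 4-patch batch on 32×32 crops of synthetic linear ramps, with
learning rate $10^{-2}$. The higher rate compensates for the tiny step
count (120 Adam steps move a weight by at most ≈ 1.2); ramps are the
smoke material because their optimal prediction correction is a small
constant per network, so a short run can reach sub-half-intensity
accuracy — the regime where the residual histogram's mode lands exactly
on class 255 and the rate drops far below 8 bits per pixel.

## Entropy coding

Per-pixel distributions are quantized to integer counts summing to
$2^{16}$ by largest-remainder rounding, with every class floored at one
count (mass borrowed from the largest classes) so that any realizable
residual stays encodable even where the model assigns essentially zero
probability — a worst-case cost of 16 bits for that pixel, never a
failure. The coder itself is a byte-oriented carry-propagating range
coder (32-bit range, renormalizing below $2^{24}$): terminator overhead
at most 6 bytes and truncation loss below $\log_2 e \cdot 2^{-8} \approx
0.006$ bits per symbol, which the test suite bounds against both the
quantized ideal length and an exact big-integer arithmetic coder written
independently in Python. ANS was not used: byte-aligned range coding is
equally bit-exact and simpler to specify for interoperability
(`FORMAT.md`).

## Synthetic data

`generate_image()` supplies the evaluation material: constants, linear
ramps, Gaussian blobs, uniform noise, and a CT-like phantom (a body disk
with a bright shell and internal lesions, plus mild Gaussian noise).
These exercise the regimes that matter structurally — flat regions,
smooth slopes, sharp boundaries, incompressible noise, and
piecewise-smooth anatomy-like content with both smooth and fluctuating
residual regions. They do *not* reproduce the texture statistics,
bit-depth conventions or acquisition noise of real scanners, so passing
tests demonstrate the codec's correctness contracts (exactness,
determinism, accounting) and qualitative learning behaviour, not
clinical compression ratios. `ablation_run()` exists to compare plain
and weighted cross-entropy training at any scale; at desk scale no
direction of the difference is asserted.

## Degenerate inputs and edge cases

* 1×1 up to odd-sided images: odd dimensions edge-replicate one row or
  column before splitting (flagged in the header and cropped on decode).
* Empty images, values outside [0, 255], and non-finite predictions are
  rejected with errors.
* An empty symbol sequence encodes to the coder's terminator alone.
* A base codec that fails its own round trip aborts compression
  (self-check on every call).
* Tampered streams fail by construction: payload-length reconciliation,
  class-range checks during reconstruction, and the final CRC-32.

## Limitations

* Single-channel 8-bit only; no multi-frame volumes, tiling, or DICOM
  container handling.
* Decoding requires exactly the encoding bundle (enforced by hash).
  Streams are not portable across platforms whose floating-point
  evaluation of the same parameters differs.
* The hand-rolled network stack is CPU-bound and single-threaded;
  reference-scale training (2000 epochs, batch 24) is intended for
  larger hardware than the test environment.
* The residual coder assumes the 511-class alphabet; other bit depths
  would need a different class range and weight schedule.
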