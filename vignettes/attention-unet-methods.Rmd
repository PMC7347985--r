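---
title: "Gland segmentation with a spatial-channel attention U-Net: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gland segmentation with a spatial-channel attention U-Net: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The segmentation problem

Glands in H&E-stained histology sections are tubular epithelial structures:
a ring of darkly stained epithelial cells around a bright, often near-white
lumen, embedded in pink stroma. Semantic segmentation assigns every pixel to
gland (foreground) or background. Two features make this harder than it
looks: the bright lumen resembles background, so naive models punch holes in
gland interiors, and adjacent glands with fuzzy shared borders tend to be
merged ("sticking").

`scaunet` implements an encoder-decoder segmentation network in which
feature maps are *recalibrated* by two lightweight, plug-and-play attention
modules — one over spatial positions, one over channels — trained end to end
with a combined cross-entropy + Dice loss. Everything, including the
backward pass and the Adam optimiser, is implemented on plain R arrays
(BLAS matrix products under an im2col formulation, with the patch
extraction in compiled code); no deep-learning framework is involved.

## Architecture

The backbone is the classic symmetric U-Net. `Block(x)` is
`conv3x3 -> batchnorm -> ReLU` applied twice, producing `x` output
channels; 3x3 convolutions use padding 1 and stride 1 so spatial shape is
preserved. The encoder applies `depth` blocks (default 4), each followed by
2x2 max pooling; channel counts double each level
(`base_channels` = 64 by default: 64, 128, 256, 512, with a 1024-channel
bottleneck block). The decoder mirrors it: bilinear x2 upsampling
(half-pixel, `align_corners = FALSE` convention), concatenation with the
same-level encoder output (the skip "copy"), and a block reducing back to
the level's channel count — after concatenating the upsampled
`base * 2^l` channels with the `base * 2^(l-1)` skip channels, the decoder
block at level `l` outputs `base * 2^(l-1)`. A 1x1 convolution maps the
final 64 channels to 2 class scores per pixel; masks are decoded by argmax
with ties resolved to background.

Inputs must have height and width divisible by `2^depth`; the network is
fully convolutional, so any such size works, with 512x512 as the reference
training resolution.

### Spatial attention (SA)

For a feature map `U` of shape C x H x W, global average pooling over the
channel axis yields a spatial descriptor `p` (H x W). A two-layer
convolutional learner turns it into per-position weights

```
t = sigmoid(conv3x3_{m->1}(ReLU(conv3x3_{1->m}(p)))),   t[h,w] in (0,1),
```

and the module output is `U'[c,h,w] = U[c,h,w] * t[h,w]`. The hidden width
`m = 16` is an absolute constant, not a fraction of C. SA is attached to
low-level encoder outputs — by default level 1 only, where contours and
edges live — and is applied *before* the skip copy, so both the skip path
and the pooled path see the recalibrated features. The set of levels is
configurable (`sa_levels`); no decoder-side insertion is implemented.

### Channel attention (CA)

Dually, global average pooling over the spatial axes yields a channel
descriptor `q` (length C), and a two-layer fully connected learner produces
per-channel weights

```
v = sigmoid(W2 ReLU(W1 q + b1) + b2),   v[c] in (0,1),
```

with `W1` of shape K x C, `W2` of shape C x K, and K = 32 hidden neurons
(again an absolute constant — this differs from the squeeze-and-excitation
`C/r` reduction convention). The module output is
`U'[c,h,w] = U[c,h,w] * v[c]`. CA is attached to the bottleneck output,
where high-level, many-channel features live.

Both modules are shape preserving, and since every weight lies strictly in
(0,1), both strictly attenuate every nonzero feature value — recalibration
is relative emphasis, not amplification. With all module parameters zero,
both gates output exactly sigmoid(0) = 0.5, a property the tests use as an
exact ablation oracle. Both conv layers in SA and both dense layers in CA
carry biases, matching the SE/CBAM designs this family of modules derives
from. Disabling both modules yields a plain U-Net, parameter for parameter.

## Loss

Training minimises, with mixing weight `lambda` (default 0.5),

```
Loss = lambda * CE + (1 - lambda) * DiceLoss
CE       = -(1/n) sum_i [ y_i log y'_i + (1 - y_i) log(1 - y'_i) ]
DiceLoss = 1 - (2 sum(y' y) + eps) / (sum y' + sum y + eps)
```

where `y'` is the softmax foreground probability and `y` the binary ground
truth. The soft Dice *coefficient* is maximal at perfect overlap, so the
minimised loss is one minus it (the V-Net convention). Numerical guards:
probabilities are clipped to `[1e-7, 1 - 1e-7]` before logarithms, and the
Dice ratio is smoothed with `eps = 1e-6` in numerator and denominator so
empty-mask pairs give loss 0 rather than 0/0. CE is averaged over every
pixel; the Dice term is computed per image and then batch-averaged, which
follows the single-image form of the soft Dice sums.

## Training regime

Adam (beta1 0.9, beta2 0.999, eps 1e-8 — conventional defaults) with
initial learning rate 1e-4, mini-batches of 4, 100 epochs by default, and a
step decay dividing the rate by 10 every 30 epochs
(`lr(e) = lr0 * 0.1^floor(e/30)`). After every epoch the mean Dice of the
binarised predictions on the validation set is computed, and the parameters
with the best validation Dice are the returned model — there is no early
stopping; best-Dice checkpointing absorbs late overfitting. Training is
bit-reproducible from the seed on one device: shuffling, augmentation and
initialisation all derive from explicitly passed seeds.

The validation set is an explicit argument; passing the test set mirrors
the common small-dataset practice of checkpointing against the evaluation
split, and the ablation harness does exactly that so all four arms see
identical data.

Batch norm uses batch statistics (biased variance) in training and running
averages (momentum 0.1) in evaluation, so evaluation is deterministic.

## Metrics

On binary masks A (ground truth) and B (prediction):
Dice `2|A n B|/(|A|+|B|)`, Jaccard `|A n B|/|A u B|` (both defined as 1
when both masks are empty), and the signed relative volume difference
`RVD = (|B|-|A|)/|A|` (positive = over-segmentation; undefined and reported
as missing when the ground truth is empty, never coerced to 0). Dice and
Jaccard obey `D = 2J/(1+J)`, which the tests verify to 1e-9 as an internal
consistency oracle. Metrics are computed per image on argmax masks and
averaged over the evaluation set; the per-image table is the primary
output, the means are derived from it.

## The phantom generator

Real gland datasets require downloads and GPU-scale training, so the
package carries a seeded generator of H&E-like phantoms used by every test:
star-convex blobs with boundary
`radius(theta) = r0 (1 + sum_{k=1..4} a_k cos(k theta + phi_k))`, painted
as a purple rim around a near-white lumen (the lumen radius is
`lumen_fraction` of the local gland radius) on a pink background, with
additive Gaussian pixel noise. Harmonic boundaries were chosen over random
walks because they are closed and hole-free like real gland cross-sections
and have an exact enclosed area, `pi r0^2 (1 + sum a_k^2 / 2)`, giving the
rasteriser an analytic oracle. The amplitudes `a_k` are drawn proportional
to `boundary_irregularity` and scaled by 1/k so the worst-case perturbation
keeps the radius positive.

The phantoms deliberately reproduce two failure modes of real glands —
bright interiors that tempt the model to punch holes, and (with
`allow_touching`) adjacent blobs that can merge — but they are *not*
histology: no nuclei texture, no stain variation, no morphological grading.
Passing tests on phantoms demonstrates that the architecture, loss,
optimiser and pipeline are implemented correctly and can fit gland-like
structure; they say nothing about accuracy on real slides, which is why no
benchmark-level claim is attached to them.

Default colours (rim ~ (120,60,140), lumen ~ (235,225,235), background ~
(230,180,200), noise sd 8 on the 8-bit scale) approximate H&E hues and are
configuration, not claims about any dataset.

## Data pipeline conventions

Images load as `[0,1]` double arrays from PNG/TIFF/BMP; masks are
single-channel PNGs binarised by `value > 0`. Resizing uses one documented
interpolation operator for both the decoder upsampling and dataset
resizing: separable bilinear resampling under the half-pixel convention,
with nearest-neighbour for masks everywhere (bilinear would break
binarity). Augmentation applies one jointly drawn geometric transform to
image and mask: right-angle rotations by default (free-angle rotation is
available behind a flag but introduces boundary interpolation artefacts in
masks, so it is off), flips, and scale jitter in `[1-j, 1+j]` followed by a
centre crop/pad back to size. Every augmentation draw is a pure function of
(seed, sample index, epoch). The train/test split is a seeded shuffle with
`round(frac * n)` training samples.

## Numerical and design choices

* **Convolutions** are im2col + BLAS `dgemm`; the patch extraction and its
  transpose live in a small C++ file. Cache-free forward passes chunk the
  image into column strips when the patch matrix would exceed ~256 MB
  (overridable via `options(scaunet.patch_bytes=)`), so full-width 512x512
  inference stays within desktop memory; the strip decomposition is exact,
  not an approximation, and is tested against the single-shot path.
* **Initialisation** is Kaiming-uniform (`U(-b, b)`, `b = sqrt(6/fan_in)`)
  for conv and dense weights, zeros for biases, unit batch-norm scale, all
  under the config seed.
* **Ties** in argmax decoding go to the background class; 8-bit export of
  weight maps uses half-up rounding (127.5 -> 128) because R's `round()`
  is round-half-even.
* **Degenerate inputs**: empty masks give Dice/Jaccard 1 against empty
  predictions and an undefined (missing) RVD; indivisible input sizes are
  rejected at forward time with the required divisor in the message;
  non-finite losses abort training with the epoch, learning rate and batch
  identified.
* **Problem sizes in the tests** are deliberately desk-scale: the overfit
  check trains a depth-3/base-8 model on four 64x64 phantoms for 240
  gradient steps at a constant 1e-4 (reaching training Dice >= 0.95), the
  ablation harness uses 16 + 8 phantoms for two epochs per arm, and the
  full 512x512/base-64 configuration is exercised for its shape contract
  only. These sizes are the package's own choice of a fast, reproducible
  demonstration; the default configuration retains the full-scale settings.

## Known limitations

Two-class heads only; no instance separation (touching glands merged by the
semantic mask stay merged); no stain normalisation or tiling for very large
slides (whole-image resize only); no GPU path — the implementation is
single-threaded R + BLAS and is meant for method study and small images,
not high-throughput training; gradient checkpointing is not implemented, so
training memory grows with image size.
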