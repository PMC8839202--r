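---
title: "Multi-path U-Net segmentation: model, training protocol and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-path U-Net segmentation: model, training protocol and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpunet)
```

## The model

`mpunet` implements an encoder–decoder segmentation network built from
several *receptive-field pathways*. Each pathway is a complete U-shaped
branch with its own square pooling window $p$: an encoder of depth $d$ whose
levels apply a two-convolution block (3×3, stride 1, size-preserving
padding, each convolution followed by instance normalization and leaky ReLU
with slope 0.1), $p \times p$ max pooling and spatial dropout; a bottleneck
two-convolution block; and a mirrored decoder whose transposed convolutions
have kernel and stride equal to $p$. Because the pathways pool at different
rates, they see the image at different sequences of resolutions — a pool-4
pathway reaches a coarse, wide-context view in two levels while a pool-2
pathway descends gradually through four — which is valuable when the objects
of interest (bacterial colonies, cells) are small and not well localized.

Pathways must be *coherent*: every pathway's total downsampling factor
$p^d$ must be identical (e.g. $4^2 = 2^4 = 16$), so that all bottleneck
feature maps share spatial dimensions. At the bottleneck the pathway
outputs are concatenated along the channel axis and normalized across
channels: for example $n$, channel stack $X^n$ with $lk$ channels,

$$\mu_n = \frac{1}{lk}\sum_{i,j} X^n_{i,j}, \qquad
  \sigma_n = \frac{1}{lk}\sum_{i,j} (X^n_{i,j}-\mu_n)^2,$$

$$X^n_{\mathrm{out}} = g \cdot \frac{X^n - \mu_n}{\sqrt{\sigma_n + \epsilon}} + b,$$

where $g$ and $b$ are learned gain/bias maps with the spatial dimensions of
one feature map, broadcast over examples and channels, and the statistics
are per example and per spatial position (never shared across examples).
This cross-channel normalization is what intertwines the pathways: gradients
flowing into any one pathway's bottleneck depend on all of them. Spatial
dropout — dropout of whole feature maps rather than pixels — follows the
normalization and the conv/deconv blocks of every level, promoting
independence between feature maps.

The normalized, dropout-regularized bottleneck stack feeds **every**
pathway's decoder. Skip connections are intra-pathway: each encoder level's
output is concatenated with the same-resolution decoder level of the same
pathway. The full-resolution decoder outputs of all pathways are
concatenated and reduced by a 1×1 convolution to per-class logits, followed
by a per-pixel softmax. Channel 1 is background and channel 2 foreground
throughout the package.

### Normalization and parameter-count conventions

Instance normalization standardizes each channel of each example by its own
spatial statistics and carries **no trainable parameters** (the common
non-affine convention). The layer-norm gain and bias are per spatial
position only, following the definition above literally. Under these
conventions the reference two-pathway configuration — pool 4 with encoder
filters [40, 240] and bottleneck 240, pool 2 with [40, 80, 160, 220] and
bottleneck 220, at a 512×512×3 input with two classes — counts 10,077,190
trainable scalars, i.e. 10.08 M:

```{r params, eval = FALSE}
config <- mpunet_config(
  pathways = list(pathway_spec(4, c(40, 240), 240),
                  pathway_spec(2, c(40, 80, 160, 220), 220)),
  input_size = c(512, 512), input_channels = 3, num_classes = 2)
count_trainable_parameters(build_multipath_unet(config))  # 10077190
```

An affine instance norm would add ~9.6k scalars and push the rounded count
to 10.09 M; the non-affine convention is also self-consistent in that a
convolution bias directly before a non-affine instance norm is a dead
parameter (the normalization removes any per-channel constant), which is
why gradient checks report exactly zero for those biases. The biases are
retained nonetheless, matching the stated layer composition.

## The training protocol

Training minimizes the unweighted sum of a Tversky loss and per-pixel
categorical cross-entropy. With soft confusion counts
$TP = \sum p t$, $FP = \sum p(1-t)$, $FN = \sum (1-p)t$ over the foreground
probability $p$,

$$L_{\mathrm{Tversky}} = 1 - \frac{TP + s}{TP + \alpha FP + \beta FN + s},$$

with defaults $\alpha = \beta = 0.5$ and smoothing $s = 1$; at these
defaults the loss is exactly one minus a smoothed Dice similarity
coefficient $\mathrm{DSC} = 2TP/(2TP+FP+FN)$, a property the test suite
verifies to $10^{-10}$. Soft counts are used in the loss because they are
differentiable; evaluation uses hard masks thresholded at 0.5. The
empty-vs-empty Dice is defined as 1 (a correctly predicted empty image is a
perfect prediction).

Optimization uses Adam (initial learning rate $10^{-4}$,
$\beta_1 = 0.9$, $\beta_2 = 0.999$) with a time-based decay
$\eta_t = \eta_0 / (1 + \delta t)$. The decay constant defaults to
$\eta_0 / 200$ so that after the 200-epoch cap the rate has fallen by less
than 10% — a gentle schedule appropriate for an already-small initial rate.
Early stopping monitors the epoch-mean *training* loss: a strict decrease by
more than $10^{-6}$ counts as improvement, and training stops after 20
consecutive non-improving epochs or at 200 epochs, whichever comes first.
After every epoch the per-class validation DSC is computed and the running
best (and the weights that achieved it) is retained. Evaluation uses
five-fold cross-validation with equally sized validation sets (a seeded
permutation split into contiguous chunks); per-fold bests are aggregated as
mean ± standard deviation per class.

Batch size defaults to 2. Per-image losses are averaged within a batch and
epochs average over images, so the reported epoch loss is comparable across
batch sizes.

## CFU quantification

Colony-forming units are quantified from binary masks by
connected-component labeling (`count_components`), 8-connected by default:
biologically, a colony touching another diagonally is still one colony; the
4-connected alternative is available, and no minimum-size filter is applied
by default because very small colonies are precisely the interesting cases.
Counts are compared as mean absolute error over images, binned into the
food-safety intervals $[0,40)$, $[40,300)$, $[300,\infty)$, and optionally
into fine-grained equal-width bins (20 by default, spanning the dataset's
maximum true count, the last bin extended to infinity — "equally sized"
is read as equal-width; an equal-population quantile reading would need the
count distribution and is not what interval-based grading uses). Binning
accuracy is reported overall and grouped by the *true* bin. Bin indices
are 0-based.

## Preprocessing

Inputs are rescaled to 512×512 (configurable) with Gaussian anti-aliasing —
per axis, a blur of $\sigma = s/3$ where $s$ is that axis's shrink factor,
applied only when shrinking — followed by bilinear interpolation;
non-square images are resized anisotropically, since a fixed square target
with no aspect-ratio caveat implies it. Masks use nearest-neighbor
sampling, which preserves binarity exactly. Each image is then z-scored
with one mean and one *population* standard deviation over all pixels and
channels (denominator guarded by $10^{-8}$; a constant image maps to
zeros). Because z-scoring removes scale, 8-bit and 16-bit inputs need no
prior conversion. All preprocessing is deterministic.

## The synthetic scene generator

Real plate and cell datasets are large, partly proprietary, and not needed
to validate the machinery; the generator produces scenes with *exact*
ground truth instead. A CFU scene is a circular plate on a darker
background with low-frequency texture (blurred white noise), carrying
disk-shaped colonies with a cosine-tapered intensity rim; radii are drawn
from 3–8 px (at the default 128×128 canvas), contrast defaults to 0.6 of
the 8-bit range and may be negative (darker colonies), and mild Gaussian
sensor noise is added before 8-bit quantization. When overlap is
disallowed, placement is rejection-sampled so the mask's 8-connected
component count equals the colony count by construction — this is what
makes the generator a counting oracle. Cell scenes replace disks with
randomly oriented ellipses with a low-order sinusoidal boundary
perturbation, emulating irregular cell outlines. Optional artifacts — dark
pen-stroke glyphs and a specular highlight — alter the image but never the
mask, so artifact-robustness fixtures are pairs of scenes differing only in
image pixels.

What the generator does *not* emulate: real agar color palettes and
off-axis illumination, merged/overgrown colonies, condensation, or
annotation noise. Tests passing on synthetic scenes therefore demonstrate
that the architecture, losses, training loop and counting pipeline work as
specified — not that any particular accuracy carries over to real plates.

## Scaled-down end-to-end study

The test suite trains a reduced model end to end: ten 128×128 grayscale
plates with 5–25 colonies each, and a coherent two-pathway model
(pool 2 / filters [8, 16] / bottleneck 16 and pool 4 / [8] / 16, ~32k
parameters), Adam at 2·10⁻³, up to 30 epochs, batch 2, dropout 0.05,
five-fold cross-validation. These sizes were chosen so a CPU-only run
finishes in minutes while leaving clear headroom over the internal bars
(best foreground DSC above 0.9 on every fold; held-out count MAE below 2);
the larger learning rate compensates for the short schedule on an easy,
high-contrast task. The full-size 512×512 reference configuration is
exercised structurally (assembly and parameter counting), not trained:
CPU-scale training of a 10 M-parameter network is out of scope.

## Numerical choices and degenerate inputs

* Normalization epsilons (instance and layer norm) default to $10^{-5}$;
  probabilities are clipped to $[10^{-7}, 1-10^{-7}]$ in the cross-entropy.
* Weight initialization is He-uniform
  ($\pm\sqrt{6/\mathrm{fan_{in}}}$) for conv and deconv layers; layer-norm
  gain starts at 1, bias at 0. All randomness (initialization, fold
  permutation, batch order, dropout masks) flows through seeds carried in
  the configuration objects, and runs are bit-reproducible on a fixed
  machine.
* The foreground decision rule is strict (`p > threshold`), so ties at the
  threshold go to background.
* Convolutions use im2col + GEMM; memory for one layer scales as
  $9 \cdot H \cdot W \cdot C_{\mathrm{in}}$ doubles, which is why training
  runs use the desk-scale input sizes.
* Max pooling requires each spatial dimension divisible by the pooling
  window at every level; the configuration constructor enforces
  divisibility by the common factor up front.
* A degenerate all-background training set is legal: the Tversky smoothing
  constant keeps the loss finite, and empty/empty Dice is 1.

## Known limitations

* One example at a time (no batched GEMM across examples); batches group
  examples per Adam step only.
* The decoder wiring after the shared bottleneck follows the reference
  diagram (every decoder consumes the full normalized bottleneck stack;
  skips stay within their pathway); other wirings are conceivable but not
  configurable.
* Weight files are plain JSON — portable and diff-able, but not compact;
  fine for desk-scale models, unwieldy for the 10 M-parameter reference
  configuration.
* `simulate()`/`residuals()` methods are deliberately absent: a
  segmentation network has no useful analogue of either; the synthetic
  generator plays the simulation role explicitly.
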