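---
title: "Segmenting low-contrast ultrasound nodules with lcanet: models, blocks and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting low-contrast ultrasound nodules with lcanet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcanet)
```

## The problem

Thyroid nodules in B-mode ultrasound are low-contrast lesions with weak
(blurred) boundaries embedded in multiplicative speckle texture, variable in
size and often clipped by the image border. Plain convolutional
encoder–decoders segment their interiors well but lose the faint contour,
because small kernels see only local neighborhoods; attention-based models
capture context but blur local detail. `lcanet` implements a hybrid
encoder–decoder that commits to both: residual large-kernel convolution
blocks for local detail, windowed cross-attention for context, and an
input-adaptive mixture of dilated convolutions to cope with nodule scale.

This vignette explains the model and the package's own design decisions —
what was specified by the architecture we implement, what was genuinely
open, and how the open points were resolved.

## The three blocks

### Context-attention

Feature maps are partitioned into non-overlapping 8×8 *query* windows and
overlapping 10×10 *key-value* windows slid at stride `s` (default 1). With
queries, keys and values produced by LayerNorm + 1×1 convolutions at
embedding width $C'$, the attention is

$$\mathrm{Attn}(\hat Q,\hat K,\hat V) =
  \mathrm{softmax}\!\left(\frac{\hat Q \hat K^\top + \varphi}{\sqrt{C'}}\right)\hat V,$$

where $\varphi$ is a learned relative-position bias indexed by the clipped
2-D offset between the query and key pixel. The block is residual: the
attended map is projected back by a zero-initialized 1×1 convolution and
added to the input, followed by a LayerNorm + 1×1 convolution stage, also
residual and zero-initialized, so a freshly built block is the identity. In
the decoder the query is drawn from the same-level encoder skip and
key-value from the upsampled deeper decoder stream, which fuses
fine-resolution localization with coarse semantics.

Design choices that were open:

* **Residual addition, not concatenation.** The combination operator of the
  two residual stages is described ambiguously, but both stages declare
  output shape $C_1\times H_1\times W_1$, which concatenation would
  violate; element-wise addition is used.
* **Logit layout and scaling.** The printed shapes of $\hat Q$, $\hat K$
  only admit $\hat Q^\top \hat K \in \mathbb{R}^{M_1\times M_2}$, matching
  the declared bias shape; standard $\sqrt{C'}$ scaling is used.
* **Attention scope.** The bias shape $M_1 \times M_2$ implies every query
  pixel attends to every key-value pixel ("global"); this is quadratic in
  pixel count, so global attention is applied only at pyramid levels whose
  spatial size is at most `attn_max_hw` (default 32). A "paired" mode —
  each 8×8 query window attends to its aligned 10×10 key-value window with
  a 1-pixel halo — is provided for larger maps.
* **Overlap handling.** With stride 1 the key-value windows repeat each
  pixel up to 100 times. Duplicated rows carry identical content, position
  and hence logits, so softmax over the duplicated set is *exactly* softmax
  over unique pixels with the log multiplicity added to the logit. The
  block computes the unique-pixel form (the tests verify equality against
  the literal duplicated-window brute force to 1e-5 relative); the
  `split_kv()` primitive still materializes the literal overlapping
  windows.
* **Embedding width** $C'$ is unspecified; the default is $C/2$.
* **Padding.** Maps are reflect-padded (bottom/right) to multiples of 8
  that are at least the key-value window size, and outputs cropped back.
* The bias table is zero-initialized with clipping radius 15; attention is
  single-map (no multi-head decomposition).

### Factorized large-kernel backbone block

A residual block whose feature extractor is a 7×1 convolution followed by a
1×7 convolution — the same 7×7 receptive field at $14C^2$ instead of
$49C^2$ weights, a reduction of $100(1 - 2k/k^2) \approx 71.4\%$ for
$k = 7$ ("approximately 72%"). The pair is followed by batch
normalization, a 1×1 convolution, the Mish activation
$x\tanh(\mathrm{softplus}(x))$, and a second, zero-initialized 1×1
convolution before the residual addition. Biases are omitted where a
following batch-norm would absorb them. Whether the 1×1 convolutions form
an internal bottleneck was open; the default keeps $C$ throughout.

### Nodule-adaptive convolution (NAC)

Four parallel branches — a 1×1 convolution and 3×3 convolutions with
dilations 2, 3 and 5, i.e. receptive fields 1, 5, 7 and 11 — are each
passed through batch-norm and Mish, then mixed by weights
$\alpha_k(X)$ predicted from the input by global average pooling, one fully
connected layer, and a softmax, which enforces
$0 \le \alpha_k \le 1,\ \sum_k \alpha_k = 1$ exactly. A 1×1
convolution + batch-norm + Mish closes the block. The branch with receptive
field 1 can only be a 1×1 convolution, which resolves the apparent conflict
between "dilation 1" and "receptive field 1" readings; mixing is a weighted
sum of branch outputs (not a concatenation, and not mixing of kernel
tensors). The block sits at the end of the encoder (the bottleneck).

## Network assembly

A 5-level U-shape by default (widths 16–256 at 256×256 input; the tests use
a 4-level, 8–64 width desk configuration at 64×64). The full-resolution
stage uses two plain 3×3 convolutions + Mish (the input/output ports care
about fine texture); each deeper encoder stage is 2×2 max-pool → 3×3
convolution + Mish (channel change) → backbone block → context-attention
(where the level's size permits); the bottleneck ends with NAC. The decoder
mirrors the encoder with nearest-neighbor upsampling + 1×1 convolution,
decoder attention (query = encoder skip), skip addition, and a backbone
block; the head is a 1×1 convolution with per-pixel 2-class softmax
(matching the two-class one-hot loss convention). The published
architecture's exact depths and widths are not stated, so absolute scores
on the clinical datasets are not an implementation target; module switches
(`use_backbone`, `use_attention`, `use_nac`) reproduce the ablation
structure instead.

All forward/backward passes are hand-written (Rcpp/Armadillo kernels for
convolution, pooling and attention; analytic gradients for every layer),
verified against central finite differences in the test suite.

## Loss functions

The class-imbalance ("LCA") pixel loss is

$$L = -\frac{1}{HW}\sum_{x,y}\sum_{c\in\{0,1\}} R_{x,y,c}
  \log\!\left(p(1-p)^2 + \tfrac{p^2}{2}\right),\qquad p = p_{x,y,c},$$

with a $(1-p)^2$ factor that up-weights misclassified pixels and a
$p^2/2$ fine-tuning term. The inner polynomial
$g(p) = p(1-p)^2 + p^2/2$ has derivative $3p^2 - 3p + 1 > 0$, so the loss
is strictly decreasing in the true-class probability; its minimum is
$\log 2$ at $p=1$ (not 0) — implemented as printed, with the curve offset
simply documented. Two readings of the trailing "2" are possible; the
default takes it as a denominator on the fine-tuning term (consistent with
"we add $p^2$ as the fine-tuning"), and the alternative
$\left(p(1-p)^2+p^2\right)/2$ is exposed as `variant = "halved"`. The log
argument is clamped at $10^{-7}$ because the raw expression diverges at
$p=0$; division is by $HW$ only (no class-count normalization), exactly as
printed. BCE and soft-Dice (smoothing $\varepsilon_d = 1$) are provided as
baselines for the loss ablation.

## Metrics

Dice, pixel accuracy and Jaccard are reported as percentages; precision,
recall, FPR and FNR as fractions — the mixed convention of the field's
comparison tables. A zero denominator (e.g. precision with no predicted
positives) yields `NaN` rather than an error and is excluded from
per-image means: empty masks never arise in the intended evaluation, and
crashing is worse than flagging. The default aggregation is the per-image
mean (box-plot-style reporting is per-image); pooled aggregation over
summed confusion counts is available and differs whenever nodule sizes
vary.

## The phantom generator

Real clinical datasets cannot be redistributed, so the package generates
ultrasound-like phantoms that exercise the three difficulties the model
targets: weak edges, low contrast, and variable size/position.

* **Background**: a smooth reflectivity field (Gaussian-blurred noise
  generated on a padded grid so its statistics are stationary up to the
  border, mean 0.5, amplitude 0.02) — bright/dark regional trends without
  structure. The amplitude is kept below half the weakest nodule contrast
  so even the faintest nodules remain detectable, a stated requirement of
  the phantom design.
* **Nodule**: a randomly oriented ellipse (aspect 0.5–1) with low-order
  harmonic boundary perturbation (amplitude ≤ 0.08), darkened by a
  contrast drop drawn from [0.05, 0.3]. The darkening *profile* is
  Gaussian-blurred (default 1.5 px at 256×256; 0.5 px in the 64×64 desk
  configuration, the scale-consistent miniature) so the image edge is
  weak.
* **Mask semantics**: the ground truth is the geometric ellipse support
  *before* blurring — the weak edge is a property of the image only,
  mirroring expert-annotation semantics.
* **Speckle**: multiplicative gamma noise, variance scaling with the
  squared local mean as the tests verify. The default shape is 100
  (coefficient of variation 0.1): the phantoms emulate *display-stage*
  ultrasound frames — log-compressed, post-processed images whose speckle
  contrast is far below the raw envelope's — after resizing to the working
  resolution, which further averages the (spatially correlated) speckle.
  Raw-envelope statistics (CoV ≈ 0.4–0.5) can be requested via
  `speckle_shape`, but they describe a different imaging stage than the
  PNG-like inputs this package targets and make faint nodules physically
  undetectable at 64×64.
* **Size classes**: small 0.5–2%, medium 2–8%, large 8–25% of image area;
  placements center/edge, with edge nodules clipped against the border so
  the contour touches it. Datasets balance classes and placements
  round-robin.

What the phantoms do **not** emulate: anatomy (gland, trachea), acoustic
shadowing and enhancement, depth-dependent resolution, heterogeneous or
calcified nodule interiors. Passing the desk-scale tests therefore shows
the architecture and training loop can learn weak-edged low-contrast
objects under speckle — not clinical performance.

## Training recipe

Loss "lca", AdaBound optimizer (Adam-style steps clipped into a band that
shrinks onto `final_lr` = 0.1, so training starts Adam-like and ends
SGD-like; bound speed 1e-3), initial learning rate 1e-3, cosine annealing
over the full schedule with no restarts, augmentation with probability
10/11 (rotation uniform in ±10°, bilinear for images / nearest for masks
with zero fill, then horizontal flip with probability 0.5). Batch size
defaults to 16; gradient accumulation over single-sample passes implements
the batch, so batch-norm uses per-sample statistics with running averages
for inference (documented instance-style behavior). The best checkpoint by
validation Dice is kept; there is no early stopping. All randomness —
weight initialization, shuffling, augmentation — derives from the control
seed, so fits are bit-reproducible on a platform.

The desk-scale configuration used by the package's own end-to-end tests:
depth 4, widths 8/16/32/64, 64×64 phantoms (boundary blur 0.5 px), 200
training / 50 validation / 50 held-out test images, 30 epochs, global
attention at levels of size ≤ 16 (the 32-pixel level adds no measurable
accuracy at substantially higher cost in this regime). The desk runs use
an accumulation batch of 1: with sample-wise gradient accumulation, batch
size does not affect memory, and more optimizer updates within the fixed
epoch budget measurably improve convergence; the default batch size
remains 16. These sizes were chosen as the smallest problem on which the
architecture's behavior (learning to high Dice; ablation ordering) is
observable and stable. Under these conditions the 30-epoch desk run
reaches a held-out mean Dice of about 80%: large and medium nodules score
in the mid-80s to low 90s, small (20–80 px) nodules about 70 — above a
per-image optimal-threshold baseline, i.e. near the geometric ceiling that
a blurred boundary imposes at that size — and border-clipped nodules about
70, the remaining gap being concentrated in the zero-filled rotation
augmentation's interaction with the image border.

## Numerical choices

* Mish is evaluated via $\tanh(\log(1+e^x)) = (u^2+2u)/(u^2+2u+2)$,
  $u = e^x$ — one exponential, cancellation-free in both tails.
* Attention softmax subtracts row maxima; non-finite logits abort with a
  diagnostic rather than propagating NaN.
* Zero-initialized residual projections make every block the identity at
  initialization, which keeps early training stable in a deep U-shape.
* Ties in the two-class argmax resolve to background (strict inequality
  for the nodule class).
* The 8:1:1 split takes `floor(0.8 n)` for training and gives an odd
  remainder's extra item to validation.
* Phantom draws use rejection sampling (≤ 60 tries) to enforce the area
  class after border clipping; infeasible specs raise a validation error.

## Known limitations

* Global attention is quadratic in pixel count; at 256×256 it is only
  applied from the 32×32 level down (`attn_max_hw`), and "paired" mode is
  the escape hatch for larger maps.
* Batch statistics are per-sample (see above); large-batch batch-norm
  behavior is not reproduced.
* Training is single-threaded CPU code: practical for the desk-scale
  problems the package targets, not for 256×256 clinical-scale training.
* The phantom generator's realism limits are listed above; no claim about
  clinical data follows from phantom results.
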