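---
title: "Lightweight partial-convolution VGG networks: models, budgets and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lightweight partial-convolution VGG networks: models, budgets and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gppwvgg)
```

## The problem and the model family

Classifying crop varieties from top-down canopy photographs is a
fine-grained task: varieties of the same crop differ by subtle, consistent
leaf texture and colour statistics rather than by gross shape. Field
deployment adds a hard constraint — the classifier must fit on a phone, so
parameter memory and multiply–accumulate (MAC) count matter as much as
accuracy.

This package implements a family of convolutional networks that starts from
VGG11 and progressively lightens it:

* **vgg11** — the classic configuration-A baseline (eight 3×3 convolutions,
  five 2×2 max-pools, three fully connected layers with dropout).
* **re_vgg11** — the channel-reconfigured baseline: widths
  32–64–64–64–128–128–256–256 with batch normalisation after every
  convolution and a 1024-wide fully connected head.
* **scheme1…scheme3, g_ppw_vgg11** — a nested ablation grid over four
  options: (a) partial convolution, (b) a pointwise-convolution +
  global-average-pooling head, (c) multi-kernel partial convolution in the
  deepest stage, and (d) efficient channel attention. The final model,
  g_ppw_vgg11, enables all four.

### Partial convolution (PConv)

Channel activations in wide convolutional layers are heavily redundant.
A partial convolution therefore convolves only the first
$c_p = \lfloor r \cdot C_{in} \rfloor$ channels with a dense $k \times k$
kernel (stride 1, same padding, no bias), passes the remaining
$C_{in} - c_p$ channels through unchanged, and restores cross-channel
mixing with a bias-free 1×1 pointwise convolution, followed by batch
normalisation and ReLU. The package uses $r = 1/4$ and a contiguous
leading-channel subset; both follow the convention of the partial-convolution
literature, and — together with the bias placement below — they reproduce
the family's published memory budgets, which is how the package pins down
choices the architecture description leaves open.

### Partially-mixed multi-kernel convolution (PMConv)

The 3×3 kernels of the reduced network limit receptive-field diversity.
PMConv splits the convolved subset into contiguous, near-equal groups and
convolves each group densely within-group with a different odd kernel
(ascending order). With $c_p = 64$ and kernels $\{3,5,7\}$ the group plan is
21/21/22: the remainder channel goes to the largest kernel, where the extra
parameters buy the widest receptive field. The stage then proceeds like
PConv (pointwise mix, batch norm, ReLU). PMConv replaces the partial stage
**only in stage 8**: placed there it adds exactly +1,846 values = +0.01 MB
over the pure-PConv model, matching the published budget delta; adding it to
stage 7 as well would overshoot that printed figure.

### Efficient channel attention (ECA)

Each stage output can be gated per channel: global average pooling produces
one descriptor per channel, a single 1-D convolution of width $k$ across the
channel axis (zero same-padding, no bias, no dimensionality reduction)
captures local cross-channel interaction, and a sigmoid yields weights in
$(0,1)$. The kernel width adapts to the channel count $C$:

$$ k = \left| \frac{\log_2 C + b}{\gamma} \right|_{odd}, \qquad
   \gamma = 2,\; b = 1, $$

where $|\cdot|_{odd}$ means the integer part rounded up to the next odd
number. The package clamps $k \ge 3$ (standard ECA practice: for tiny $C$
the raw rule yields $k = 1$, which degenerates into an independent
per-channel gate). For the family's widths this gives $k = 3$ for 32–64
channels and $k = 5$ for 128–256. Eight gates add only 32 values in total,
which is why attention is "free" at the reported rounding.

One subtlety the gate inherits from zero padding: channels within
$\lfloor k/2 \rfloor$ of either end of the channel axis see a truncated
window, so the "equal inputs give equal gates" symmetry holds exactly only
for interior channels. The tests check exactly that.

### The pointwise classifier head (FL2PWConv)

In re_vgg11 the fully connected head holds ~92% of all parameters. The
replacement head is two bias-free 1×1 convolutions (256 → 1024 → classes)
around a ReLU, followed by global average pooling over the 7×7 grid. No
batch normalisation is used inside the head; with the expand–reduce widths
above this head costs 268,288 values against the 13.9 M of the fully
connected head it replaces.

## Budget accounting

The accounting module is calibrated so that enumeration of the model's
tensors reproduces the family's published budget table. The conventions are
deliberate design choices, stated here once:

* **Learnable values**: convolution and linear weights and biases,
  batch-norm affine pairs ($2C$), attention kernels.
* **Stored values**: learnable plus batch-norm running mean/variance
  (another $2C$) — everything a checkpoint actually holds, which is the
  right basis for a *memory-footprint* metric.
* **Parameter memory**: stored values × 4 bytes (fp32) ÷ $2^{20}$, reported
  in MiB **truncated** to two decimals. Truncation, not rounding: the
  unmodified baseline's exact value is 491.2984 MiB and its published
  figure is 491.29, so the published table truncates.
* **Bias placement**: dense 3×3 convolutions keep their (framework-default)
  biases; partial/grouped stages and all pointwise convolutions are
  bias-free.
* **Reduction percentages** (the $(x - x_1)/x$ improvement metric) are
  rounded to two decimals.

Under these conventions: vgg11 = 491.29 MiB, re_vgg11 = 57.62 MiB
(published 57.63; the residual 0.01 is reporting-convention noise we could
not attribute under any bias/normalisation convention we enumerated), the
head share of re_vgg11 = 92.03% (published 92.02, same caveat),
scheme2 = 1.78, scheme3 = g_ppw_vgg11 = 1.79, and the memory reductions are
99.64% (vs vgg11) and 96.89% (vs re_vgg11), both exact.

**MAC counting** is convention-flagged because published complexity figures
rarely name their tool: the default counts convolution/linear
multiply–accumulates plus bias adds plus one op per element through
activations and batch norm, and excludes pooling. Partial and grouped
stages count only their convolved subset. Under the default flags the
baseline totals 7,619.89 M — within 0.02% of the published 7,618.57 M —
and the tolerance in the tests is 0.5%.

## Data protocol

The augmentation pipeline applies, in order: independent vertical and
horizontal flips (probability 0.5 each — the protocol names both flips but
not their probabilities), rotation uniform in [−30°, 30°], photometric
jitter, a random 300×400 crop, and a bilinear resize to 224×224. Choices the
protocol leaves open, fixed here: rotation borders are filled by
*reflection* (a custom bilinear sampler; stock rotations offer constant
fill only); the brightness and saturation factors in [0.9, 1.1] act
multiplicatively on HSV value and saturation with clamping; the hue
"factor" acts as a bounded additive shift of $0.25 \cdot (f - 1)$ hue turns
(≤ ±9°), since a multiplicative hue is not well defined on a circular
channel. All draws come from one seed; the same seed gives byte-identical
outputs.

The mobile-app rule is separate: images whose longer side exceeds 300 px
are resized to 300×300 and then to 224×224; smaller images go directly to
224×224.

Splitting is stratified per class: 60/40 train/test with `round(0.6 n)`
training items per class (within one item of the nominal fraction), and
stratified k-fold assignment (default k = 3) for cross-validation, which is
standard leave-one-fold-out.

## The synthetic canopy generator

Real field photographs cannot ship with a package, so the generator renders
class-conditioned stand-ins: each class carries a distinct signature — a
stripe orientation $\theta_c$, stripe frequency $f_c$ and hue centre $h_c$
in the green band — rendered as an oriented sinusoidal leaf texture over a
brown cluttered background, plus per-pixel Gaussian noise. The "easy"
difficulty spaces hues across [0.16, 0.46] with light clutter and noise;
"hard" compresses the hue band to [0.26, 0.36] and increases both.

What this emulates: the premise that varieties differ by subtle, consistent
texture/colour statistics, with tunable difficulty. What it does not:
perspective, specular highlights, occlusion, illumination fields,
inter-plant variation. A passing desk-scale run therefore demonstrates that
the architecture, optimiser and pipeline are implemented correctly and can
extract class signal end-to-end — not that field-data accuracies transfer.

Two generator-facing checks are worth noting. With noise and clutter off,
the rendered texture is a pure oriented sinusoid, so a 2-D FFT peak recovers
$\theta_c$ to within 2°. And 32-bin hue histograms with a 3-nearest-neighbour
classifier separate a held-out 40% of 300 easy images above 80% — the
training harness always has signal to find.

## Training harness

Training is AdamW (decoupled weight decay) on softmax cross-entropy. The
published recipe — batch 112, 120 epochs, initial learning rate 0.005,
decay factor 0.5 — is the `train_config()` default; the decay *cadence* is
unstated there, implemented as ×0.5 every 30 epochs and exposed as
configuration. Argmax ties break towards the lowest class index; F1 is
defined as 0 where precision + recall = 0; headline precision/recall/F1 are
macro averages and AUC is one-vs-rest macro from softmax scores (the
multiclass reductions are otherwise unspecified).

Two implementation notes specific to short CPU runs:

* **Batch-norm recalibration.** After a short run the exponentially-averaged
  running statistics lag the still-moving weights, and evaluation-mode
  normalisation can be arbitrarily far from the batch statistics the network
  trained with. `ppw_train()` therefore ends with `refresh_bn()`: weights
  frozen, running statistics replaced by cumulative averages of batch
  statistics over the training set.
* **Desk-scale profile.** `desk_train_config()` (32 px inputs, batch 32,
  learning rate 10⁻³, ~12 epochs, weight decay 10⁻⁴) is the package's own
  desk-experiment condition, chosen once so that the full pipeline —
  synthesise, split 60/40, train g_ppw_vgg11, evaluate — runs in about a
  minute on one CPU and reaches 100% held-out accuracy on easy synthetic
  data. The test suite uses these problem sizes throughout (e.g. 6 classes ×
  40 images; 48-step trainability fits across all six presets); they are
  deliberate scalings of the full protocol, not calibrated constants.

## Numerical engine

The tensor engine is written in R against BLAS: convolution is im2col plus
one matrix multiply per layer (column-major offset blocks), with explicit
backward passes for every operator (including the attention gate's path
through pooled channel descriptors). Everything is deterministic given a
seed: weight initialisation is He-normal, pooling ties break to the first
window position, and no threading-dependent reductions are used. Gradients
are verified against central differences across every layer type; the only
caveat is the usual one at ReLU kinks, where the analytic value is a valid
one-sided subgradient (zero-initialised biases make exact kinks reachable,
so the gradient tests perturb biases into general position).

## Known limitations

* Parameter budgets for `scheme1` (partial convolution with the fully
  connected head retained) cannot be reconciled with its published memory
  figure under any convention we enumerated — the printed value is below
  the cost of the stated fully connected head alone. The preset is provided
  but excluded from budget checks.
* The engine targets desk-scale problems; the full 224-px, batch-112,
  120-epoch recipe is expressible but not practical on one CPU.
* Only square inputs whose side is a multiple of 32 are supported (the five
  2×2 pools must land on integer grids).
* `device = "cpu"` is the only backend.
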