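---
title: "Methods: adaptive multi-scale attention networks for leaf-disease images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adaptive multi-scale attention networks for leaf-disease images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(amwnet)
```

# The problem and the model

Leaf-disease photographs defeat plain convolutional classifiers in two
characteristic ways: lesion boundaries fade gradually into healthy tissue
(edge blur), and early lesions occupy only a handful of pixels. `amwnet`
addresses both with a ResNeXt-style backbone carrying two purpose-built
blocks directly after the stem, trained with a hybrid focal loss, and with a
metaheuristic learning-rate search.

The forward path is: 7×7 stride-2 stem convolution with batch normalisation
→ ARPC → MTDFA → 3×3/2 max pool → four bottleneck stages (3, 4, 6, 3 blocks;
grouped 3×3 convolutions with cardinality 32) → global average pool → linear
classifier. With 224-pixel inputs the two custom blocks operate on the
112×112×64 stem map.

## ARPC: adaptive residual pyramid convolution

Four parallel grouped convolutions (kernels 3/5/7/9, groups 1/4/8/16)
capture context at increasing scales. A trainable 4-vector `W` passes
through a softmax to give branch weights `ω`, and three fused maps are
formed by sliding that weight vector over the branch outputs:

* `combined1 = ω1·c1 + ω2·c2 + ω3·c3 + ω4·c4`
* `combined2 = ω1·c2 + ω2·c3 + ω3·c4`
* `combined3 = ω1·c3 + ω2·c4`

`combined2` and `combined3` reuse the leading weights without
renormalisation — this is deliberate fidelity to the block's defining
equation, not an oversight. The three fused maps are concatenated with a
3×3 residual convolution of the input (kernel size our choice; it matches
the branch spatial behaviour), squeeze-and-excitation gating is applied to
the concatenated 4×64-channel map, and a 1×1 convolution reduces back to 64
channels. Choices where the design was open: each branch emits the same
channel count as the block output (64 at full width); SE acts *before* the
1×1 reduction (the reduction is described as the final step); the SE
bottleneck ratio is the standard r = 16; `W` initialises to zeros so
training starts from uniform branch weights.

## MTDFA: triplet disease-focus attention

An *attention gate* is applied along three orientations of the feature map —
channel–width (view `(B,H,W,C)`), height–channel (view `(B,W,H,C)`) and the
untouched height–width view. In each view the gate compresses the leading
non-batch axis with S-Pool (a max-pool plane concatenated with a
softmax-weighted "soft" pool plane), reduces the two planes to one logit map
with a depthwise-separable convolution plus a 1×1-convolution/batch-norm
shortcut (`Drsc`), normalises the logits with a softmax *over all spatial
positions of the view* so the weights sum to one per sample, and rescales
the input. The softmax axis is a design choice (the defining property is
only that the weights sum to one); its consequence — gate outputs of
magnitude ~1/(H·W) — is absorbed by the trailing 1×1 fusion convolution.

The fourth branch, *MinorAttention*, targets minute lesions with
local-window (outlook-style) attention: a value projection is unfolded into
3×3 windows; per-position, per-head 9×9 logits are produced by a linear map
of stride-1 average-pooled features (pool stride is our choice; the
defining description only asks for a spatial reduction), scaled by
`head_dim^{-1/2}`, softmax-normalised over the source axis, used to
aggregate the window values, folded back, and projected with dropout
(rate 0.1; the mechanism names dropout without a rate). Folding uses
overlap-count normalisation so constant inputs map to constant outputs.

Branches fuse as `0.5(X_CW + X_HC)` and `0.5(X_HW + Y)`, concatenated and
reduced by a 1×1 convolution (the final convolution's size is unstated; 1×1
is the minimal choice that performs pure channel fusion).

## WfrLoss

`WFL(p_t) = −α_t (1 − p_t)^γ log p_t` with γ = 2; γ = 0 recovers
cross-entropy. The per-class weights follow the anchor rule tied to class
shares — 20% → 1.0, 19% → 1.2, 18% → 1.3 — linearly interpolated between the
anchors and clamped outside [0.18, 0.20]; the rule is only specified at
those three shares, so the interpolation/clamping treatment of other shares
is ours. The L2 term defaults to `β/B · Σ‖z‖²` on the logits entering the
loss (reading the regularised "inputs" as the loss inputs, squared for
differentiability); a `weights` mode penalising all parameters is available
because the surrounding description also speaks of limiting parameter size.
β defaults to 1e-4 (unstated). `p_t` is clamped at 1e-12 with a warning;
batch reduction is the mean.

## TPSAO

A bounded minimiser hybridising snow-ablation moves with particle-swarm
velocities:

* **Tent-chaotic initialisation.** Uniform draws pass once through the tent
  map and are rescaled to `[Lb, Ub]`. We use the normalised map
  `x/α, (1−x)/(1−α)`: the printed `2x/α`-style prefactors leave `[0,1]`
  whenever α ≠ 0.5, while the normalised form preserves the ergodic intent
  for all α and coincides with the classic map at α = 0.5. Likewise the
  rescale uses `Lb + x·(Ub − Lb)` rather than multiplying by `Ub` alone,
  so both bounds are respected.
* **Dual population.** Each iteration the swarm splits at random into an
  exploration set (moves around an elite drawn uniformly from {global best,
  second best, third best, centroid of the top half}) and an exploitation
  set (contracts towards `M·G` at the melt rate
  `M(t) = (0.35 + 0.25(e^{t/tmax}−1)/(e−1))·e^{−t/tmax}`). The exploitation
  share shrinks as `Nb(t) = max(1, round((N/2)(1 − t/tmax)))` — the
  schedule is stated only as "gradually declining", so the linear form is
  ours.
* **PSO velocity.** `v ← w·v + c1 r1 (p_i − x_i) + c2 r2 (G − x_i)` with the
  *pre-update* position as reference (the reference is unstated; the
  pre-update position is the conventional reading), clipped elementwise to
  `[Lb − cand, Ub − cand]` so the final position stays in the box; the
  position is additionally clamped after the update because the
  snow-ablation candidate itself may exit the bounds. `w` decays linearly
  0.9 → 0.4 and `c1 = c2 = 2` — standard swarm values, as only the symbols
  are specified. Velocities initialise at zero; personal bests initialise
  from the first evaluation.

Learning-rate search runs the optimizer in one dimension over
`[1e-4, 1e-2]` with N = 50 and 100 iterations. Non-finite objective values
become `+∞` with a warning; the best-so-far history has one entry per
iteration and is non-increasing by construction.

# The synthetic data generator

The packaged generator replaces field photographs: it draws a rotated
elliptical leaf with a midrib on a dark background and overlays
class-specific primitives — large dark blotches with heavily blurred
boundaries and chlorotic halos (anthracnose; the edge-blur challenge),
grey-brown water-soaked irregular patches (phytophthora blight), nothing
(healthy), 18–35 pixel-scale dark specks (bacterial spot; the minute-lesion
challenge) and low-frequency yellow mottling (mosaic virus). Class shares
default to 21/18/21/21/19%. The morphologies are *fixtures*: they are
deliberately colour- and texture-separable so that a small network can
learn them, and a passing end-to-end run demonstrates that the training
machinery works — not that the architecture would reach any particular
accuracy on real pepper leaves. Real photographs vary in illumination,
pose, background clutter and lesion appearance in ways the generator does
not attempt to model.

Augmentation follows the standard recipe: random resized crop (area scale
[0.6, 1.0], aspect [3/4, 4/3] — magnitudes our choice, as only "different
sizes and aspect ratios" is specified), horizontal flip with probability
0.5, ImageNet mean/std normalisation. Evaluation resizes to 8/7 of the crop
side and centre-crops (the 256 → 224 convention), which also matches the
scale statistics of the training crops. The split is stratified 8:2.

# Numerical and engineering choices

The network runs on a package-local reverse-mode autodiff engine: an R tape
over C++ kernels (grouped im2col convolution with a single-GEMM 1×1 path,
max/average pooling, unfold/fold, channel/spatial broadcasts, the
local-window aggregation). Batch normalisation uses batch statistics in
training and exponential running statistics (momentum 0.1, ε = 1e-5) in
evaluation; the running variance is the unbiased estimate. Convolutions are
He-initialised; the final batch-norm scale of every bottleneck initialises
at zero so each residual block starts as an identity and the 16-block
network optimises quickly in the short desk-scale schedule. The optimizer
is Adam (β = 0.9/0.999, ε = 1e-8) at the configured initial learning rate
0.001 with batch size 32. All layer gradients are validated against central
finite differences in the test suite.

Degenerate inputs are handled explicitly: empty pooling regions and
non-finite attention inputs raise errors; `p_t = 0` is clamped; zero
denominators in precision/recall report 0 with a note rather than `NaN`;
objective functions returning non-finite values cost `+∞`.

# Desk-scale profile and problem sizes

The test suite and the acceptance script exercise a reduced profile chosen
as a sensible scientist's desk experiment: width multiplier 0.25 (stem 16
channels), 64-pixel images, 625 synthetic images split 500/125, 15 epochs,
batch 32 — about 240 optimisation steps and roughly 1.5M trainable values.
The full-scale configuration (224 px, width 1, 200 epochs) is retained
behind the `"full"` profile of `experiment_config()`. Unit tests run the
blocks at full-scale shapes (e.g. 112×112×64 through ARPC and MTDFA) to
pin the interface contracts.

# Known limitations

* The synthetic fixtures cannot support claims about real-world accuracy;
  they validate mechanism, shapes, gradients and training dynamics.
* The engine is CPU-only and single-threaded apart from BLAS; full-scale
  200-epoch training is out of its intended scope.
* TPSAO's learning-rate search is exercised against analytic proxy
  objectives in the tests; wiring it to a full training objective works but
  is computationally heavy.
* `AAC` is implemented as mean per-class recall; the defining indices are
  ambiguous and this reading is consistent with its use as an "average
  accuracy" across classes.
* The k-fold harness keeps other hyperparameters fixed (batch 32, learning
  rate 0.001, Adam) and records each fold's best validation accuracy.
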