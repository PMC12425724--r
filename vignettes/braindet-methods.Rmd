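---
title: "Methods: attention operators, the HKCIoU loss and the profiled detector graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: attention operators, the HKCIoU loss and the profiled detector graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(braindet)
```

`braindet` implements the building blocks of a lightweight single-stage
detector for brain tumors in axial MRI slices: three attention operators,
a hook-reweighted bounding-box regression loss, a declarative model graph
with exact parameter/FLOP accounting, a synthetic scene generator, and a
CPU micro training/evaluation loop. This vignette explains the model
choices, the tunable parameters, and what the desk-scale experiments do
and do not demonstrate.

## Attention operators

All three operators are shape-preserving, multiplicative transforms of a
feature map indexed `(batch, channel, row, col)`.

**Shuffle3D** composes a channel permutation with a parameter-free
spatial-inhibition gate. The permutation (`channel_shuffle()`) defaults to
the deterministic group-interleave reshuffle of shuffle networks with
`groups = 4`; a seeded uniform permutation is available as
`mode = "random"` for the randomized-rearrangement reading of the design.
The gate (`energy_gate()`) scores each position of a `(batch, channel)`
slice by its deviation from the slice statistic

$$e = \frac{1}{HW - 1}\sum_{ij} x_{ij}, \qquad
u_{ij} = \frac{(x_{ij} - e)^2}{4\,(e + \alpha)} + \beta, \qquad
y_{ij} = \sigma(u_{ij})\, x_{ij},$$

with regulators $\alpha = 10^{-4}$ and $\beta = 0.5$. The energy
denominator uses the *mean-style* term $\sum x / (HW-1)$ exactly as
defined; the related parameter-free attention this draws on normalizes by
a variance, so `energy_gate_params(variance = TRUE)` switches the
denominator to $\sum (x - e)^2/(HW-1)$ for comparison. The default stays
with the defining form. Composition order is shuffle first, then gate,
and the shuffled channel order is kept afterwards so downstream
convolutions train against it consistently. Since $\sigma(u) \in (0,1)$
the gate strictly contracts every nonzero activation; the operator has no
learned parameters, so substituting it for a convolution always removes
capacity rather than relocating it.

**Spatial attention** (`spatial_attention()`) pools the channel axis with
max and mean into two spatial descriptors, convolves the 2-channel stack
with a single 7×7 filter (stride 1, padding 3, bias), and multiplies the
input by the sigmoid of the result. With all-zero weights the gate is
exactly 0.5 everywhere, which the tests use as a wiring check.

**Dual-channel attention** (`dual_channel()`) captures multi-scale context
in the style of parallel-kernel inception blocks: a depthwise 3×3 context
convolution, two parallel convolutions with distinct kernels (3 and 5)
onto `branch_channels` channels each, concatenation, a 1×1 fuse back to
the input width, a spatial-attention map computed from the fused tensor,
and a final multiplication of the *input* by that map (the fused tensor
itself is never mixed additively into the output, so zero weights again
give exactly `0.5 * x`). The default `branch_channels = channels_in / 8`
makes the block at 256 channels cost 297,891 parameters — deliberately
lighter than the multi-head attention block it replaces (249,728
parameters would be removed, 297,891 added at the single 20×20 site while
the much larger per-head convolutions are removed elsewhere); this width
is the configuration pinned by the published parameter table, and it is
exposed in `dual_channel_config()` rather than hard-coded.

## The HKCIoU loss

CIoU extends IoU with a center-distance penalty and an aspect-ratio
penalty:

$$\mathrm{CIoU} = \mathrm{IoU} - \frac{\rho^2(b^p, b^t)}{c^2} - \alpha v,
\qquad v = \frac{4}{\pi^2}\left(\arctan\frac{w^t}{h^t} -
\arctan\frac{w^p}{h^p}\right)^2,
\qquad \alpha = \frac{v}{1 - \mathrm{IoU} + v}.$$

The hook function $f(x) = a x + b/x$ (with $ab > 0$) is convex on
$x > 0$ with its minimum at $\sqrt{b/a}$; with the default $a = b = 0.5$
the minimum value 1 sits at $x = 1$. Applying the hook to the box loss
$L = 1 - \mathrm{CIoU}$ and multiplying back by $L$ gives the HKCIoU
loss, which simplifies algebraically to

$$\mathrm{HKCIoU}(L) = (aL + b/L)\,L = a L^2 + b.$$

The package evaluates the simplified form, which is finite at $L = 0$
(value $b$) where the literal form is undefined. Its gradient $2aL$
exceeds the plain CIoU-loss slope 1 precisely when $L > 1$ — poor boxes
are penalized more steeply, good boxes more gently, which is the stated
convergence rationale. Two interpretations of "adjusting the CIoU" are
possible; only the loss-side reading produces this amplification, so
`hook_params(mode = "loss")` is the default and `mode = "metric"`
(applying $a x^2 + b$ to the CIoU value itself) is retained for
comparison. Note the constant offset $b$ makes absolute HKCIoU values
incomparable to plain CIoU loss values; only gradients and orderings are
comparable.

Analytic gradients of IoU, CIoU and HKCIoU with respect to the predicted
box corners are implemented alongside the values (including the
dependence of $\alpha$ on the prediction) and are verified against
central finite differences at tolerance $10^{-4}$ in the tests.

The total detection loss is the weighted three-term sum
$L_{total} = \alpha L_{box} + \beta L_{obj} + \gamma L_{cls}$ with
$L_{box} = L_{CIoU} + L_{DFL}$. In the anchor-free decoupled head there
is no separate objectness output: the confidence role is absorbed by the
per-class sigmoid scores, and the $\beta$ weight slot acts on the
distribution-focal component (`loss_weights()` accepts `w_dfl` as an
alias). The weight values are not part of the published description;
the defaults (7.5 / 1.5 / 0.5) follow common practice for this detector
family and are exposed in the configuration.

## Model graphs and profiling

`build_model()` constructs the n-scale detector graph declaratively:
backbone (stem convolutions, C3K2 stages, SPPF, then a post-SPPF
attention block), an FPN-style neck fusing strides 8/16/32, and three
decoupled heads (box branch: two CBS convolutions then a 1×1 onto
`4 * reg_max` DFL bins; class branch: depthwise-separable pairs then a
1×1 onto the class logits). Channel widths follow the publicly documented
n-scale layout (width 0.25, depth 0.50, channel cap 1024), which is the
fidelity anchor for the parameter and FLOP accounting. At 640×640 the
heads predict at 80², 40² and 20² positions — 8,400 candidates.

Every node expands into a flat table of primitive convolutions and batch
norms, and **both** the profiler and the runtime weight allocation consume
that same table, so closed-form counts and instantiated tensors agree
exactly (asserted in the tests). FLOPs use the 2×MACs convention of the
profiler behind the published numbers: a convolution contributes
`out_positions * cout * (k² cin / g + bias)` MACs, a batch norm
`4 * elements`, and activations, pooling, upsampling, concatenation and
the attention matrix products contribute nothing.

The modified variant (`build_ha()`) applies three substitutions:

* the post-SPPF multi-head attention block is replaced by dual-channel
  attention (lighter and much cheaper at the 20×20 site);
* on every head, the first CBS of the box branch and the first depthwise
  convolution of the class branch become Shuffle3D gates; because
  Shuffle3D cannot change channel counts, the following convolution is
  widened to read the head's incoming channels directly — a net
  parameter reduction;
* a standalone spatial-attention gate is applied to the network input.
  The published tables pin this placement indirectly: the spatial module
  adds ≈0.1 GFLOPs at ≈0 parameters, which among the candidate insertion
  points only a full-resolution gate (99 parameters, 0.081 GFLOPs at
  640²) reproduces. It is a package design decision, exposed through the
  `spatial` argument.

Resulting profiles (computed, then rounded to the published precision):
baseline 2.59 M / 6.4 GFLOPs; Shuffle3D-only 2.47 M / 5.8; dual-channel
only 2.64 M / 6.5; full variant 2.52 M / 5.9 — a 2.7 % parameter and
7.8 % FLOP reduction at the table's printed precision.

## Synthetic scenes

`generate_dataset()` emulates the schema of the four-class axial-slice
dataset used for the study (classes glioma / meningioma / no-tumor /
pituitary; default per-class counts 1153/1449/711/1424 train and
136/140/100/136 val, scaled by `scale`). Each scene is a dark field, a
bright skull ellipse, speckled brain tissue, and for tumor classes one
bright blob drawn from class-conditional priors: glioma — large,
irregular (lobed boundary), intensity ≈0.72; meningioma — smooth, round,
peripheral, ≈0.95; pituitary — small, central-inferior, ≈0.84. The
intensity gaps are several times the texture noise, so a trivial
mean-intensity threshold classifier separates the classes (asserted
>90 % in the tests) and the detection task is learnable at micro scale.
Boxes are recomputed from the rendered blob mask, so annotations are
tight by construction. "No tumor" images carry one brain-region box of
class 2, mirroring datasets whose PR curves include the absent-tumor
state as a detected class; `annotate_no_tumor = FALSE` switches to the
empty-annotation convention. One master seed drives a splitmix-style
per-image seed derivation, making every image independently reproducible.

What the generator does **not** emulate: MRI physics (bias fields, coil
inhomogeneity, partial-volume effects), anatomical structure beyond one
ellipse, multiple or absent-but-ambiguous lesions, and class overlap in
appearance. Passing micro-scale tests therefore demonstrates that the
training loop, losses and evaluator are correctly wired and that the
architecture can fit a separable detection task — not that the full model
reaches any particular accuracy on real MRI data.

## Micro training and evaluation

Training the 2.6 M-parameter graphs at 640² is out of desk-scale reach,
so the harness trains `build_micro()`: a five-conv plain backbone (bias +
SiLU, no normalization) with the same three-stride head geometry and
light two-conv heads (≈130 k parameters), at 64×64 input with
`reg_max = 8`. The optimizer follows the study settings — SGD with
initial learning rate 0.01, momentum 0.937, weight decay 0.0005 — with a
3-epoch linear warmup (the published schedule is not fully specified;
constant-after-warmup is the package's choice), batch 8, horizontal-flip
and brightness-jitter augmentation (the mosaic-style augmentation and its
end-of-training shutdown are out of scope). Backpropagation is
implemented in the package: conv transposes via `col2im`, SiLU and
softmax-expectation chain rules, and the analytic CIoU/HKCIoU corner
gradients.

Target assignment is a deliberately simple, oracle-checkable rule rather
than a task-aligned assigner: an anchor is positive when its point lies
inside a ground-truth box and the box's longer side falls in its
stride's range. Ranges are `(0, 4s]` per stride (unbounded at stride 32):
four cells is half the distribution-focal range, keeps box-side/stride
balanced, and routes the brain-sized no-tumor boxes to the stride-16 head
whose receptive field spans the whole brain — a local stride-8 cell
cannot decide "no blob anywhere". Ties go to the smallest box area, and a
box too small to contain any anchor center receives its nearest free
anchor, so every ground-truth box has at least one positive.

Evaluation decodes DFL distributions by softmax expectation, filters at a
confidence threshold, applies per-class greedy NMS (IoU 0.7), and scores
with COCO-style mAP: greedy confidence-ordered matching, one match per
ground truth, 101-point interpolated precision, averaged over IoU 0.50
and 0.50:0.05:0.95. The evaluator is pinned against an independent
reference implementation at $10^{-6}$ and against enumerable worked
cases.

**Problem sizes.** The micro experiments use 100 training and 11
validation images (the study's per-class ratios at scale ≈0.021), 20
epochs, three seeds, both box-loss configurations. Under these
conditions both losses reach a strictly lower final loss than initial
loss and a seed-averaged held-out mAP50 above 0.5 (the HKCIoU
configuration has averaged ≈0.9 in the sessions recorded during
development, the CIoU configuration ≈0.7). These numbers are properties
of the micro setup; they are not comparable to the full-scale published
accuracies, whose reproduction requires the external dataset and
GPU-scale training and is explicitly out of scope.

## Numerical choices and limitations

* Convolutions use zero padding `(k-1)/2`; biases are enabled wherever
  batch norm is absent; attention blocks contain no normalization.
* The energy gate divides by `4(e + α)`; for slices whose mean-style term
  approaches `-α` the energy spikes and the sigmoid saturates — inputs
  are finite-checked, and the variance-mode denominator is nonnegative
  by construction.
* `ciou()` defines `α = 0` at the coincident-box corner case
  (`IoU = 1, v = 0`), making the breakdown exact at its maximum.
* Gradient subtleties: the IoU subgradient is taken as 0 at tie
  boundaries (measure-zero events for continuous boxes); DFL targets are
  clamped to `reg_max - 1 - 10⁻³` so the upper bin always has a defined
  neighbor.
* The trainer supports the micro graph only (plain conv chain + micro
  heads); the full graphs are forward-only at this scale. Inference for
  every variant, including attention substitutions, is exercised by the
  forward smoke tests at 256².
* `evaluate_map()` treats classes without ground truth as absent from the
  mean rather than scoring zero, matching the reference convention.
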