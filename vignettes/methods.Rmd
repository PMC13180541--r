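---
title: "Methods: magnitude-aware linear attention and spatial retention for MRI lesion detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: magnitude-aware linear attention and spatial retention for MRI lesion detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mridetr)
```

## The problem

Brain tumour lesions in MRI present with low contrast against surrounding
tissue, indistinct boundaries, and irregular morphology. Real-time detection
transformers (the RT-DETR family) are attractive for this task because they
are NMS-free — one-to-one set prediction during training removes the need
for non-maximum suppression at inference — but three of their standard
components are poorly matched to MR image statistics:

* a plain residual CNN backbone attenuates the shallow, low-contrast texture
  cues that mark lesion boundaries;
* kernelised linear attention in the intra-scale encoder block discards the
  magnitude of query vectors, flattening exactly the signal-amplitude
  differences that distinguish lesion from normal tissue;
* convolutional cross-scale aggregation carries no explicit prior about
  spatial continuity, which is what makes morphologically irregular lesions
  cohere as single objects.

`mridetr` implements the three replacement operators that target these
deficiencies, their conventional baselines, and everything needed to train
and evaluate them end to end at desk scale: a seeded phantom generator,
Hungarian-matched set-prediction training, COCO-style mAP evaluation, a
parameter/MAC profiler, and Grad-CAM explainability. All computation runs
on a small reverse-mode tape engine over base-R arrays, so every operator
is directly inspectable and differentiable without external frameworks.

## The three operators

### Gated-CNN cross-stage-partial backbone

The backbone stacks gated convolutional blocks

$$y = x + \sigma(W_g\,\mathrm{Norm}(x)) \circ \mathrm{conv}(W_f\,\mathrm{Norm}(x))$$

inside cross-stage-partial (CSP) stages: after an entry convolution the
channels are split in half, one half passes untouched (preserving shallow
spatial detail), the other half runs through the gated blocks, and the two
are concatenated and fused by a pointwise convolution. `Norm` is layer
normalisation over channels, `conv` a 7×7 depthwise convolution, and the
logistic gate performs per-position, per-channel feature selection. This is
the "gated CNN without a state-space model" token mixer; no SSM is used.
With the default expansion ratio of 1 the equation holds verbatim and the
residual is exact when the feature branch is zeroed (a property the tests
pin down at weight level). The stage layout is a stride-4 stem followed by
four stages with strides (1, 2, 2, 2); S3/S4/S5 tap the last three stages
at strides 8/16/32. Full-scale depths (2, 2, 6, 2) and widths
(64, 128, 256, 512) follow the MambaOut convention; the source publication
for this architecture family does not print its exact depths/widths, so
parameter totals are a design choice here and only the *ordering* against
the ResNet18-style baseline (identical equation-level basic blocks with
batch normalisation) is asserted.

### Magnitude-aware linear attention (AIFI-MALA)

Standard linear attention computes $\phi(Q)[\phi(K)^\top V]$ with the
positive kernel $\phi(x)=\mathrm{ELU}(x)+1$, avoiding the $N\times N$
score matrix — but a *normalized* kernel attention is exactly invariant to
positive rescaling of a query, so lesion-discriminative amplitude
information is lost. The magnitude-aware core restores it. With
$\hat Q, \hat K$ the rotary-encoded queries and keys,
$\bar K = \tfrac1N\sum_i \phi(\hat K)_i$, $\bar V = \tfrac1N\sum_i V_i$ and
$z = \phi(\hat Q)\bar K^\top$:

$$\mathrm{MALA}(Q,K,V) = \phi(\hat Q)[\phi(\hat K)^\top V]\odot
\left[1 + (z+\varepsilon)^{-1}\right] - z \odot \bar V$$

The $(z+\varepsilon)^{-1}$ factor re-weights each query by its kernelised
magnitude, and the $z\odot\bar V$ term subtracts a magnitude-proportional
global-mean bias. At a single position the algebra collapses to
$\mathrm{out} = \tfrac{z}{z+\varepsilon}V$, which the tests verify
numerically. Two deliberate readings of the printed formulation:

* $\bar K$ is taken as the mean of the *kernel-mapped, rotated* keys, so
  $z>0$ always and $(z+\varepsilon)^{-1}$ is bounded; the raw-key reading
  admits $z \le -\varepsilon$ and a division blow-up.
* No denominator normalisation is applied — the formula is implemented as
  printed, which is exactly what makes the operator magnitude-sensitive.

Around the core: Q, K, V and the gate O come from one fused 1×1 convolution;
a 5×5 depthwise convolution of V adds a local positional perturbation with
no cross-channel mixing; the gate multiplies the sum elementwise before a
1×1 output projection; and a post-norm two-layer GELU feed-forward closes
the block as $Y' = \mathrm{LN}(X + \mathrm{LN}\{Y + W_2\,
\mathrm{GELU}(W_1 Y)\})$. Layer normalisation of an exactly zero vector
with zero affine bias is defined as zero (variance floor $10^{-5}$). The
block is applied to S5 only, the usual placement of intra-scale interaction
in hybrid encoders.

### Two-dimensional axial rotary encoding

Each head's channels are split in half — the first half rotated by angles
$h\,\omega_h$, the second by $w\,\omega_w$ — and within each half
consecutive channel pairs $(a,b)$ rotate as complex numbers
$(a\cos\theta - b\sin\theta,\; a\sin\theta + b\cos\theta)$. Frequencies
follow the inverse-power spacing $\omega_i = 10000^{-2i/(d/2)}$. The
printed form of this map ("$t\odot\cos\theta + \mathrm{shift}(t)\odot
\sin\theta$") is implemented as the true rotation, because only the
rotation yields the relative-position property the encoding exists for:
rotated inner products depend solely on the positional offset, which the
tests check over 100 random trials per head width. The row/column split of
channels is a documented convention; defaults set
$\omega_h = \omega_w$.

### Manhattan-decay retention (RetBlockC3)

Manhattan self-attention masks softmax attention with a spatial decay
matrix,

$$A = \mathrm{softmax}(QK^\top/\sqrt d)\odot D, \qquad
D[n,m] = \gamma^{|x_n-x_m| + |y_n-y_m|},$$

*without* renormalising rows afterwards — the retention convention, which
makes attention mass genuinely decay with distance rather than being
redistributed. $D$ factorises exactly as the product of 1D row and column
decays, which licenses the decomposed form: a horizontal softmax-attention
pass per row masked by $\gamma^{|c_1-c_2|}$, then a vertical pass per
column masked by $\gamma^{|r_1-r_2|}$ applied to the horizontal output.
The two operators agree exactly on single-row and single-column grids (a
test fixture) and differ in general — the decomposition is an
approximation with linear per-axis cost, not an identity. The horizontal
pass runs first; the opposite order is a different operator. Per-head decay
rates follow the retention-literature schedule $\gamma_i = 1 - 2^{-5-i}$.
The RetBlock wraps this in a pre-norm transformer unit (rotary phase on
Q/K plus the decay masks realise the 2D relative position encoding, a 5×5
depthwise local-context term on V, feed-forward ratio 2), and RetBlockC3
runs a 1×1 convolution followed by RetBlocks on one path, a 1×1 shortcut
on the other, summing the two with no trailing activation. The RepC3
baseline it replaces is the reparameterisable stack: per unit, a 3×3
convolution branch, a 1×1 branch and the batch-normalised input are summed
and passed through SiLU.

## Detector assembly

The three toggles (backbone, intra-scale block, aggregation block) span a
2³ variant grid. The pipeline is: backbone → 1×1 projections to the hidden
width → intra-scale block on S5 → cross-scale fusion (top-down then
bottom-up, one aggregation block at each of the four fusion points) →
per-token class/box heads on the flattened pyramid → top-K query selection
by objectness with deterministic index tie-break → a standard multi-head
cross-attention decoder (pre-norm, 3 layers at full scale) → sigmoid
center-size box heads against the selected tokens' reference boxes. The
decoder is deliberately plain: no deformable attention, no denoising
queries; the source design inherits its decoder and prints none of it, so
bit-exactness there is a non-goal. "IoU-aware" query selection is realised
as top-K objectness plus the auxiliary encoder-proposal loss: the proposal
boxes and scores are trained with the same Hungarian-matched focal/L1/GIoU
objective as the decoder outputs, so the selection score is trained to
reflect localisation quality.

Training uses AdamW (defaults: batch 8, 100 epochs, patience 10, seed 0,
image size 640 — mirroring the standard recipe; learning rate 1e-4 and
weight decay 1e-4 are package defaults since the recipe leaves them
unstated), horizontal flip as the only augmentation, and early stopping on
validation mAP@50, with strict improvement required to reset patience.
Matching minimises $2(-p_{c}) + 5\|b\|_1 + 2(1-\mathrm{GIoU})$ via a
shortest-augmenting-path assignment solver written in-package (no
assignment solver ships with the R environment used). The total loss is
exactly $\sum_i \lambda_i\,\mathrm{component}_i$, a bookkeeping identity
the tests assert.

## The phantom generator

The generator stands in for public brain-tumour MRI collections and is the
fixed study condition for every end-to-end result, not a tunable knob. Per
sample: an elliptical brain-like background with smooth tissue texture, and
one lesion drawn by class signature —

* **pituitary**: small regular ellipse near the lower centre (sellar
  region), sharp boundary, mild heterogeneity;
* **meningioma**: well-defined ellipse attached to the brain rim (dural
  attachment);
* **glioma**: irregular star-convex blob (periodically interpolated random
  radii), the upper half of the boundary-blur range and full internal
  heterogeneity;
* **no tumor**: no lesion, one whole-image box. This box convention is a
  package decision: category-level precision/recall/mAP for a "no tumor"
  class is only computable if lesion-free scans carry a box, and a
  whole-image box is the least informative choice consistent with that.

Class weights default to the proportions (880, 1738, 1408, 1705)/5731 of
the public collection being emulated. Contrast offsets (0.15–0.35 of the
dynamic range), boundary blur (0.5–2.5 px Gaussian sigma) and Rician noise
($|s + n_1 + i n_2|$, the magnitude-MRI noise model, $\sigma = 0.05$) were
chosen once as a realistic caricature of low-contrast MR lesions. Bounding
boxes always derive from the noiseless soft lesion mask (pixels at or above
half the peak), never from the rendered image — a zero-contrast lesion
still has its correct box, which is what makes the annotation exact by
construction. What the phantoms deliberately do **not** model: true MR
physics, multi-sequence contrast, 3D anatomy, partial-volume effects,
scanner artefacts, or multiple lesions per scan. A detector that learns
phantoms has demonstrated that the training loop, matching, and heads work;
it has demonstrated nothing about clinical MRI.

## Numerical and scale choices

Everything runs on the package's reverse-mode tape over base-R arrays
(BLAS matmuls, single-node convolutions via im2col, batched attention with
heads and batch folded into one loop dimension). Gradient correctness is
established against central differences for every operator class. The
attention core never materialises an $N\times N$ matrix; its largest
intermediates are $N\times d$ and $d\times d$ per head.

Test-scale problem sizes were chosen so the whole suite runs comfortably on
one CPU: 96×96 phantoms, hidden width 16–32, stage widths (8, 16, 24, 32),
20 queries, 2 decoder layers. The scaled-down end-to-end check trains the
full improved variant on 400 two-class phantoms (meningioma and pituitary —
the two lesion classes with distinctive, learnable signatures; a no-tumour
class would make half the task a constant-box regression) for at most 14
epochs at learning rate 1e-3 and batch 16, evaluating on 100 held-out
phantoms from an independent seed; the pass rule is 2 of 3 fixed seeds at
mAP@50 ≥ 0.60, and remaining seeds are skipped once two have passed.
Validation for early stopping uses a 12% split of the training pool.

Other conventions: boxes are 0-based pixel xyxy half-open internally,
normalised center-size in YOLO text, pixel xywh in COCO JSON, all enforced
by converters with round-trip tests at 1e-5; average precision uses
101-point max interpolation (COCO convention — the integral definition
alone does not fix the interpolation rule, and the tooling lineage of this
model family implies COCO); a class with no ground truth and no detections
has undefined AP and is excluded from means; precision/recall are reported
at IoU 0.50 for detections above score 0.25 by default; GFLOPs are reported
as 2 × MACs; grayscale phantoms are replicated to three channels at the
detector input.

## Known limitations

* The decomposed Manhattan attention is not equal to the full operator on
  general 2D grids; only the 1D degeneracies are exact.
* Training determinism holds because every kernel here is deterministic
  base-R arithmetic; the same claim would be best-effort on platforms with
  nondeterministic BLAS threading.
* The profiler counts MACs of matrix products and convolutions executed on
  the tape; elementwise work and normalisations are excluded by
  convention, so absolute GFLOPs are comparable within this package, not
  across frameworks.
* Parameter totals of the full-scale assemblies are design choices (see
  above); accuracy figures from the emulated study are not reproducible
  from phantoms and are not claimed.
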