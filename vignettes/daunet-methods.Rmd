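---
title: "DA-UNet methods: model, phantoms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DA-UNet methods: model, phantoms, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the segmentation
model and its assumptions, the synthetic phantoms the pipeline is
exercised on, the numerical conventions, and the places where the
design was genuinely open and a choice had to be made.

## The segmentation problem

Contrast-enhanced CT angiography renders arterial lumen bright
(around 300 HU at arterial-phase trigger levels) against soft tissue
(tens of HU).  Segmenting the lateral circumflex femoral artery and its
perforator branches from such volumes is the computational core of
CTA-based perforator mapping for anterolateral thigh flap planning: the
surgeon needs the skin-surface exit point of each perforator before
incising.  The package covers the full chain: segment the artery tree,
find where its branches pierce the skin surface, and score both the
voxel segmentation and the point localization.

## DA-UNet

The backbone is a 2-D U-Net: an encoder of `depth` levels (two 3×3
convolutions, each followed by batch normalisation and ReLU, then 2×2
max-pooling; channels double per level from `base_channels`), a
bottleneck block, and a mirrored decoder (nearest-neighbour ×2
upsampling, concatenation with the encoder skip, two conv–BN–ReLU).
Three decoder-side mechanisms distinguish DA-UNet from the plain U-Net:

* **Squeeze-and-excitation.**  After each decoder conv block the
  feature map `D ∈ ℝ^{w×h×e}` is squeezed channel-wise to its spatial
  mean, excited through a bottleneck MLP of width `e / se_reduction`
  (ReLU, then sigmoid), and every channel is rescaled by its
  excitation weight, which lies strictly in (0, 1).
* **Attention gates.**  The raw gate recipe — add the skip features `y`
  and the gating features `g`, rectify, convolve, squash — is
  under-determined when `y` and `g` differ in channel count and
  resolution, as they always do inside a U-Net.  The package uses the
  minimal completion that makes the arithmetic well-typed: `g` is the
  decoder feature *after* upsampling to `y`'s resolution, both tensors
  are brought to a common intermediate width (`= y`'s width) by 1×1
  convolutions (the gate branch carries the bias), and the rectified
  sum is collapsed by a 1×1 convolution to a *single-channel*
  coefficient map `κ ∈ (0,1)` that multiplies every channel of `y`.
* **Deep supervision.**  Each of the `supervision_levels` finest
  decoder levels emits a class-logit map through its own 1×1
  convolution (how per-level features acquire class channels is again
  unstated in the usual formulation; a per-level 1×1 class projection
  is the obvious completion).  Coarser maps are upsampled to full
  resolution by fixed bilinear interpolation (×2, ×4, ×8 …) and the
  maps are *summed before* a single softmax, so the network output is
  one probability simplex per voxel.

Setting `use_se = FALSE`, `use_attention = FALSE`,
`supervision_levels = 1` yields the matched plain U-Net baseline with
identical conv/BN parameterisation.  A stronger structural check is the
*block-bypass equivalence* the test suite enforces: freezing the SE
weights at 1 and `κ` at 1 inside a DA-UNet reproduces, weight for
weight, the plain U-Net's forward pass.

### Loss

Training minimises the mean voxel cross-entropy
`−(1/M) Σ_m Σ_k Z_m^k log z_m^k` with one-hot gold labels `Z` and
predicted probabilities `z`.  (One sometimes sees this printed with the
gold label inside the logarithm, which would make the loss constant in
the prediction; the standard definition is implemented.)  Probabilities
are clamped at `1e-7` before the logarithm in the user-facing
`cel_loss()`; the training path uses a fused softmax–cross-entropy with
the numerically stable log-sum-exp form.

### Candidate fusion

Slicing one volume along the axial, coronal and sagittal axes and
segmenting each stack gives `N = 3` candidate segmentations — the
slice-sampling direction is otherwise arbitrary, and three orthogonal
passes are the natural choice for a slice-wise 2-D model.  Fusion
scores class `k` as `Σ_n W_{n,k}·c_{n,k} + α_k` and takes the arg-max
(ties to the lower class index, so background wins a tie).  Scalar
per-(candidate, class) weights are the default — uniform weights are
exactly majority voting — with voxelwise weight arrays accepted;
`fit_fusion_weights()` provides an optional least-squares fit of `W`
and `α` against gold masks on a validation set, since nothing in the
forward model pins the weights down.

### Coarse-to-fine cascade

`c2f_segment()` composes `restore ∘ fine ∘ crop ∘ coarse`:

* the coarse stage segments a block-averaged, `down_factor`-reduced
  copy (intensities are averaged on the way down; labels travel back up
  by nearest-neighbour, as interpolating labels is meaningless);
* the crop is the tightest axis-aligned box containing the coarse
  foreground, expanded by `margin` voxels (default 8 — the fine network
  needs context beyond the lumen) and clipped to the volume;
* the fine mask is zero-padded back to the original grid using the
  recorded 0-based, half-open `[low, high)` box.

The cascade's output is therefore *contained* in the expanded coarse
box by construction: a branch the coarse stage misses entirely cannot
be recovered by the fine stage.  An empty coarse mask is reported as a
distinct no-artery outcome (all-zero mask plus flag), not an error.
Coarse and fine stages take independent networks (or any function from
a slice to labels — test doubles plug in directly); nothing forces them
to share weights.

## Metrics

All five quality indices are functions of the voxel confusion counts,
kept in exact integer arithmetic with a single division at the end:
Dice `2TP/(2TP+FP+FN)`, Jaccard `TP/(TP+FP+FN)` (related by
`D = 2J/(1+J)`), sensitivity `TP/(TP+FN)`, and a count-based
balanced-accuracy "AUC" `1 − ½(FPR + FNR)` — the form appropriate for
scoring a *hard* segmentation, not a threshold-sweep ROC area.

`avd_paper()` computes the signed relative volume difference
`(|B|−|A|)/|A|`.  Parts of the vascular-segmentation literature report
this quantity under the name "average Hausdorff distance"; it is a
volume ratio, not a distance, so the package keeps it under an honest
name and ships the conventional spacing-aware mean surface distance as
`average_hausdorff()` (symmetric mean of directed nearest-surface
distances between the 6-connectivity surface voxel sets).

Degenerate inputs follow documented conventions rather than silent
guesses: two empty masks score Dice = Jaccard = 1 (perfect agreement on
absence); sensitivity with an empty gold standard and the AUC with an
absent class raise errors; `avd_paper` with an empty prediction raises
(its denominator is the predicted volume).

## The phantom generator

Real clinical CTA with gold-standard annotations cannot ship with a
package, so the generator produces what the pipeline assumes: a bright,
gently curving main artery running along the volume's long axis
(centerline = smoothed random walk, default radius 3 mm), two to four
thinner perforator branches (default radius 1.4 mm) that leave the main
vessel and rise toward a flat "skin" plane, terminating exactly on it,
embedded in soft-tissue background.  Default intensities are HU-like —
lumen 300, tissue 50, additive Gaussian noise SD 15 — chosen to match
arterial-phase contrast levels; the spec constructor refuses parameter
sets with `lumen ≤ tissue + 3·noise_sd`, so every phantom is learnable
by construction.  Branch skin-exit points are redrawn (seeded) until
pairwise separation is at least 6 mm, so "one blob per perforator at
the skin" — and with it exact count recovery — is well-posed.
Everything (geometry, noise, dataset splits) derives from one integer
seed, bit-for-bit.

What the phantoms deliberately do **not** model: CT reconstruction
artefacts, beam hardening, partial-volume blur, contrast-bolus timing,
anatomical variation of the thigh, neighbouring bright structures
(bone, veins).  Passing phantom tests therefore demonstrates that the
implementation is correct and the architecture can learn tubular
bright-on-dark structures — it does not certify clinical segmentation
accuracy, which would require patient data.

## Perforator localization

`build_frame()` constructs the landmark coordinate system: origin at
the midpoint of the iliac–patellar line, longitudinal axis along it,
surface axis from a normal hint orthogonalised against the line
(Gram–Schmidt), third axis by right-handed completion.
`extract_exit_points()` takes the mask voxels within 1.5 voxels of the
skin plane, clusters them by face connectivity, and projects each
blob's centroid onto the plane.  Matching is greedy — all
within-threshold pairs sorted by distance, each point used once —
because at two to four perforators per thigh greedy and optimal
assignments almost always coincide, greedy is deterministic and
transparent, and an exhaustive optimal matcher is available behind
`method = "optimal"` for small sets.  The default threshold of 10 mm is
of the same order as reported clinical localization errors (~11–12 mm
between preoperative and intraoperative positions).

Detection statistics need a true-negative count to define specificity,
but "a site where no perforator exists and none was predicted" has no
natural denominator in a continuous field.  The package refuses to
invent one: specificity (and count-based accordance) are only computed
when the caller supplies an explicit `candidate_sites` total, and are
`NA` otherwise.

## Numerical choices

* Weight initialisation: He-style normal (SD `√(2/fan_in)`) for all
  convolution and dense weights; BN scale 1, shift 0.  Convolutions
  that feed a batch norm carry no bias (it would be absorbed).
* Batch norm: biased batch variance for normalisation, running moments
  with momentum 0.1 for inference, `eps = 1e-5`.
* Optimiser: Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e-8), learning rate
  1e-3, batch size 8 — conventional defaults, surfaced in the run
  configuration; plain SGD is available where a provably monotone
  full-batch loss trace is wanted.
* Softmax uses the row-max shift; cross-entropy clamps at 1e-12
  internally, 1e-7 in the user-facing loss.
* Index conventions: 0-based, half-open `[low, high)` crop boxes;
  voxel centres at `(i − 0.5)·spacing` mm.
* Inputs whose extents are not divisible by `2^depth` are rejected by
  the forward pass with an explicit message; `predict()` pads
  symmetrically with the training-set mean intensity and crops back.
* NIfTI stores voxel spacing in single precision; round-trips preserve
  integer masks exactly and spacing to float32 accuracy.

## Desk-scale problem sizes

The package's reference experiments (test suite and acceptance script)
run at a scale chosen for a single CPU: 64³-voxel phantoms at 1 mm
spacing, twelve phantoms split 0.7/0.15/0.15, 200 training slices of
64×64, the full `network_spec()` architecture (depth 4, 16 base
channels, ~1.9 M parameters), two training epochs, three weight seeds
for the DA-UNet versus plain U-Net comparison; localization studies use
10–20 phantoms with 2–4 perforators each.  On the high-contrast
phantom task the loss is already near convergence after the first
epoch, so two epochs are enough for a stable comparison; the engine
sustains roughly one mini-batch of eight 64×64 slices per two seconds
on one core.  The training comparison is a *directional* check — the
attention-gated, deeply supervised network should not trail its plain
backbone — not a reproduction of any clinical accuracy figure.

## Known limitations

* The engine is 2-D slice-wise; no native 3-D convolutions.  Multi-view
  fusion recovers some cross-slice consistency but not true 3-D
  context.
* Pure-R training is desk-scale: clinical-resolution volumes would need
  a GPU framework behind the same interfaces.
* Greedy matching can differ from optimal assignment in pathological
  point configurations; the optimal matcher is exhaustive and limited
  to small sets.
* The phantom generator's realism limits are listed above; in
  particular no claim about patient CTA accuracy follows from phantom
  metrics.
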