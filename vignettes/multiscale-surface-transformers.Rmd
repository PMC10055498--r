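---
title: "Multiscale windowed attention on icosahedral cortical meshes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale windowed attention on icosahedral cortical meshes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mssit)
```

## The problem

Cortical surface analysis works with per-vertex scalar maps — sulcal depth,
curvature, cortical thickness, T1w/T2w myelination — living on sphericalised
meshes of the cortical sheet. Convolutions do not transfer cleanly to this
domain, but sequence models do: a mesh signal is a sequence of local patches.
The catch is that global self-attention costs O(L²) in the sequence length,
which is prohibitive at the resolutions where cortical detail lives
(tens of thousands of patches). `mssit` implements a hierarchical
transformer that restricts attention to local mesh windows, shares
information across windows by cyclically shifting the patch sequence, and
merges neighbouring patches 4-to-1 to build a multiscale representation.
The same backbone supports whole-surface prediction (e.g. age regression)
and, in a U-shaped variant with skip connections, vertex-wise parcellation.

## The icosphere hierarchy carries the whole architecture

Everything is anchored in the nested icosphere family `I_k`: `k` rounds of
4-to-1 face subdivision of a fixed icosahedron (poles on ±z), giving
`|V_k| = 10·4^k + 2` vertices and `|F_k| = 20·4^k` faces. Two ordering
conventions, fixed once, make the architecture pure index arithmetic:

* subdivision appends edge-midpoint vertices after all existing vertices, so
  the order-(k−1) vertices are a prefix of the order-k vertices;
* the four children of face `f` are stored at `4f..4f+3`.

Consequences: the descendants of any coarse face are a contiguous run of
positions, attention windows are contiguous runs of 64, patch merging is a
stride-4 regrouping, and the shifted-attention pass is a plain cyclic roll.
The test suite verifies that this arithmetic agrees with an independent
geometric oracle (point-in-spherical-triangle containment of face centroids)
for every face of every order up to ico6.

A signal on the order-6 mesh (40962 vertices) is tokenised by the order-5
patch grid: each of the 20480 coarse faces covers 6 fine vertices (3 corners,
3 edge midpoints, midpoint *i* opposite corner *i*), concatenated across the
C channels into a token of length 6C. Corner vertices are shared between
neighbouring patches; faces are not.

## Encoder, windows, and the shifted pass

The token sequence passes through up to four levels. Level `l` projects to a
`2^(l−1)·D`-dimensional embedding, applies `depths[l]` local-attention
blocks, and (except at the last level) merges sibling tokens 4-to-1,
concatenating features. Sequence lengths for an ico6 input are therefore
20480 → 5120 → 1280 → 320. Each block is pre-norm and runs four residual
sub-steps:

    LN → W-MHSA  → +x     LN → FFN → +x
    LN → SW-MHSA → +x     LN → FFN → +x

W-MHSA restricts attention to windows given by the icosphere three
subdivision levels below the sequence grid — 64 patches per window — so the
per-level attention cost is `w_l · |F_{6−l}|` score entries per head instead
of `|F_{6−l}|²`. At the last level no such coarser grid exists and attention
is global over the 320 tokens. SW-MHSA is the same operation after cyclically
rolling the sequence by `round(shift_fraction · w_l)` positions (default half
a window), so half of each window's patches attend together with the
neighbouring window's patches; the output is unrolled afterwards. No
attention masking is applied across the roll boundary: the sphere has no
border, and under the canonical ordering the wrapped positions are legitimate
mesh neighbours at the window-grid scale. `window_depth` generalises the
"three levels down" rule so that down-scaled models (e.g. ico3 or ico4
inputs used throughout the tests) retain genuinely local windows; the
default of 3 reproduces the full-size architecture.

For regression/classification the final 320 tokens are averaged and passed
through a linear head. For segmentation the encoder keeps each level's
pre-merge output; the decoder mirrors the hierarchy upward, copying each
parent token to its 4 children (1-to-4 patch partition), concatenating the
skip connection, and projecting back to the level's width. A final head maps
every patch token to 6·K vertex logits scattered onto the patch's 6 vertices;
vertices shared by several patches average their contributions. Decoder
levels are projection-only by default (`decoder_depths = 0`): on the
synthetic tasks the skip connections carry enough high-resolution detail, and
adding decoder attention blocks roughly doubles the cost; they can be enabled
per level when more decoder capacity is wanted.

## Parameters that matter

* `base_dim` (D): first-level embedding width; deeper levels double it. The
  full-size default is 96 with depths (2,2,6,2) and heads (3,6,12,24), a
  compact Swin-style parameterisation; the desk-scale experiments in this
  package use D = 16, depths (1,1,1,1).
* `shift_fraction` (default 0.5): fraction of the window rolled in the
  shifted pass. 0 disables cross-window mixing (the shifted sub-step then
  equals the windowed one exactly — a property the tests assert).
* `mlp_ratio` (default 4): FFN expansion factor.
* Augmentation (`augmentation_config`): applied with probability 0.8; when
  applied, a rotation (probability 0.5) with per-axis angles uniform in
  ±30° for regression / ±15° for segmentation, composed x→y→z; otherwise an
  elastic warp displacing the order-2 control icosphere's vertices
  tangentially by at most 1/8 of each vertex's mean neighbour distance,
  interpolated barycentrically to the signal mesh. The 1/8 bound keeps the
  warped mesh diffeomorphic — the tests check that no face orientation ever
  flips. Angles are drawn per axis (the composition order is a convention the
  recipe leaves open); displacements are tangential before reprojection,
  again a convention, noted because an unconstrained 3-D displacement of the
  same norm would be slightly weaker.
* Optimiser: AdamW (β = 0.9/0.999, decoupled weight decay on matrices only)
  with the cosine schedule
  `lr(t) = lr_min + (lr_max − lr_min)(1 + cos(πt/T))/2`. Regression uses MSE
  on z-scored targets; segmentation uses 0.5·soft-Dice + 0.5·cross-entropy
  with Dice smoothing 1e−5. Regression batches are drawn by a balanced
  sampler that bins targets (default width 1, i.e. one week for age-like
  targets) and weights samples inversely to bin occupancy.

## Numerical choices

Barycentric resampling locates the face hit by the radial ray through each
target point — hierarchical descent through the nested face tree for
canonical icospheres (exact, O(log) per point), an exhaustive
max-min-edge-determinant scan for arbitrary sphere meshes — and interpolates
with the planar barycentric weights of the radial projection, clamped at
edges so outputs remain convex combinations (constants are exact, coincident
vertices are identities). Label maps use the same transform with
nearest-corner assignment, keeping channels and labels consistent under
augmentation. Ties on window/face boundaries resolve to the face with the
largest minimum edge determinant, which is deterministic. LayerNorm uses
ε = 1e−6; GELU is exact (via the normal CDF); softmax is max-subtracted.
All gradients are hand-derived and checked against central finite
differences to 1e−6 on both task heads, including the shifted-attention
roll, the scatter-average segmentation head, and the Dice+CE loss.

## What the synthetic data emulates — and what it does not

The generators stand in for neonatal/adult cohort data so that every claim
in the package is testable offline:

* Regression: per subject a scalar target `t` (PMA-like weeks, 26–45, drawn
  from a term-dominated skewed mixture by default so the balanced sampler has
  something to do) and channels `base_c + g(t)·effect_c + noise`, with the
  fields mixtures of rotated zonal spherical harmonics (degree ≤ 8) and
  `g(t)` linear — so channels are smooth and depend monotonically on the
  target.
* Segmentation: a fixed nearest-seed geodesic parcellation (Fibonacci-spread
  seeds) shared across subjects; channels are region-mean signatures plus
  smooth variation and noise; each subject gets a small (±3°) rotational
  jitter applied consistently to channels and labels.
* Native meshes: a jittered latitude/longitude sphere — closed, 2-manifold,
  non-icosahedral — for exercising native-to-ico6 resampling.

These datasets are deliberately easy: signal components are unit-scale with
noise sd 0.1, and region identity is recoverable from channel values alone.
Passing the learning checks therefore demonstrates that the architecture,
gradients, augmentation and optimisation pipeline are correct, not that the
model reaches state-of-the-art accuracy on real cortical data — real
metrics have inter-subject variability, registration error and
scanner effects that these generators do not attempt to simulate, and the
published full-scale results require cohort data and GPU-scale training that
are out of scope here.

## Problem sizes used by the checks

The heavy checks run at reduced resolution, chosen as the smallest sizes at
which every architectural mechanism (local windows, shifts, four levels,
merging, U-decoder) is still exercised: learning sanity uses ico4 inputs
(2562 vertices, 640 patches) with n = 200 subjects for regression (val MAE
compared against the constant mean-of-train predictor on the same split) and
n = 40 subjects / 8 regions for segmentation (held-out mean Dice); both use
the tiny D = 16 model and 80 optimiser steps. Oracle-equivalence checks run
exhaustively up to ico6; the attention-vs-masked-global oracle runs on an
ico3-input model with order-0 windows (`window_depth = 2`, 16 patches per
window).

## Known limitations

* Single-threaded CPU implementation in base R matrix code: suitable for
  desk-scale models (ico4 inputs train in minutes), not for full-size
  (ico6, D = 96) training, though full-size *forward* passes run in seconds.
* The shifted pass does not mask attention across the roll boundary (see
  above); a masking variant is a possible extension and the config reserves
  room for it.
* Positional embeddings are learned per level-1 position only; deeper levels
  rely on the merge structure.
* GIFTI support covers the metric/label/surface subset with ASCII and
  Base64(+gzip) encodings — not external-file data blocks or CIFTI.
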