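---
title: "Graph fully convolutional networks for stroke lesion segmentation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph fully convolutional networks for stroke lesion segmentation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Acute ischemic stroke is routinely assessed with CT perfusion: from a
contrast bolus, scanners derive hemodynamic parameter maps — cerebral blood
flow (CBF), cerebral blood volume (CBV), mean transit time (MTT) and
time-to-maximum (Tmax) — alongside the non-contrast CT. Inside an infarcted
core these maps show a characteristic signature (depressed CBF/CBV, elevated
MTT/Tmax), but manual delineation is slow and observer-dependent.

`gfcn` segments the lesion with a *graph* fully convolutional network. Each
2-D slice is converted to a pixel graph: one node per retained brain pixel
carrying the five modality values, edges joining 4- or 8-adjacent pixels, and
per-edge *pseudo-coordinates* — the relative displacement `(Δrow, Δcol)`
mapped affinely from `[-d, +d]` to `[0,1]^2`. Unlike spectral graph
convolutions, the trainable kernel here is a grid of `k1 × k2` control
points over that pseudo-coordinate square, interpolated by open uniform
B-splines of degree `m`; because only the `(m+1)^2` basis products straddling
an edge's pseudo-coordinate are nonzero, the kernel assigns genuinely
different weights to different edge *directions* at convolution cost
independent of `k`. The node update is

    out_i = (1/|N(i)|) Σ_{j∈N(i)} [ Σ_p B_p(u_ji) W_p ]ᵀ x_j  +  Rᵀ x_i  +  b

with a separate root weight `R` for the center pixel (no self-loops are added
to the graph) and mean aggregation over neighbors, which keeps feature scale
stable across coarsening levels where node degrees vary widely.

## Encoder, pooling, decoder

The encoder stacks `depth` blocks (default 4); each block applies two spline
convolutions with batch normalization and ELU, doubles the feature width
(base width `b`, so widths `b, 2b, 4b, 8b` from inputs of 5 channels), and is
followed by a pooling step producing topologies `V0 → V1 → … → V_depth`.
Three pooling operators are provided:

* **Graclus matching** (default): visit nodes in a seeded order and greedily
  match each with the unmatched neighbor maximizing the normalized-cut score
  `1/d_i + 1/d_j` (uniform edge weights), so clusters have size ≤ 2 and the
  node count at least halves every other level. Features aggregate with the
  per-channel **max**; average aggregation is deliberately not offered
  (it is prone to vanishing gradients in this architecture). Coarse nodes
  sit at their members' centroid; coarse edges are the deduplicated
  inter-cluster images of fine edges, and pseudo-coordinates are
  renormalized by each level's own maximum displacement since coarse grids
  are irregular.
* **Top-k selection**: a trainable projection scores nodes; the top
  `⌈ratio·N⌉` survive with features gated by `tanh(score)` (gradients flow
  through the scores); the coarse graph is the induced subgraph.
* **Farthest-point sampling with radius assignment**: centers chosen by FPS
  on positions, every node assigned to its nearest center, max aggregation.

The decoder is FCN-style: a per-node linear *score* layer reduces selected
feature maps to one channel, score maps are fused by addition, and
*unpooling* operators restore earlier topologies using the stored pooling
records. The three variants differ only in skip connections: **32s** unpools
the top score map straight to `V0`; **16s** adds the `V2` score before the
final unpoolings; **8s** adds scores at `V_{depth-1}` and `V_{depth-2}` on
the way up. A sigmoid yields per-node lesion probabilities, thresholded at
0.5.

Three unpooling rules are implemented:

* **isotropic** — copy the coarse value to every cluster member;
* **proportional** — redistribute it with weights
  `p_i = v_i / Σ_{j∈cluster} v_j` computed from the feature snapshot stored
  at pooling time, so members sum back exactly to the coarse value. The
  weights are treated as constants under differentiation (gradient-stop):
  the backward pass routes gradient only through the coarse features. For
  1-channel score maps unpooled against a multi-channel snapshot the
  weights come from the snapshot row-means (the redistribution rule is
  scalar in its original form); clusters whose stored sum is below
  `epsilon` fall back to uniform weights, covering the 0/0 case;
* **kNN interpolation** — inverse-squared-distance weighted average of the
  `k` nearest coarse nodes (default `k = 3`), the partner of Top-k pooling
  whose dropped nodes have no cluster. All coarse nodes tied with the k-th
  nearest distance are included, which keeps the operator well-defined and
  relabeling-invariant on regular grids where distance ties are common.

## Design choices in the open

* **Spline hyperparameters.** Kernel size 5×5 at degree 1 by default: on an
  8-neighborhood these give direction-selective kernels with modest
  parameter count; both are configurable.
* **Connectivity.** Default 8 — diagonal edges give the spline kernel
  distinct directions to weight; 4-connectivity is available.
* **Graclus visiting order.** A seeded *random* order realized as a
  deterministic hash of node positions rather than node indices. This keeps
  clustering reproducible under a seed while making the whole network
  equivariant to node relabeling — an index-based random order cannot be
  both.
* **Skip fusion on score maps.** Raw feature widths differ across levels, so
  skips operate on 1-channel score maps (the classical FCN recipe) rather
  than on feature tensors.
* **16s tap point.** The 16s skip taps the pooled features at `V2`; one
  textual description of the architecture family places it at `V3`, but the
  `V2` reading is the one consistent with the 8s/16s/32s progression.
* **Batch normalization across graphs.** Batches are disjoint unions of
  slice graphs, so BN normalizes over all nodes of the batch; placement
  before ("pre", default) or after ("post") the ELU is configurable.
* **Activation.** ELU throughout (the architecture family does not pin the
  nonlinearity; ELU avoids dead units at the low learning rates used in
  the fixed-rate protocol).
* **Empty-mask slices** are kept in training — real CTP stacks contain
  lesion-free slices and the slice-wise metrics must reflect them.

## Metrics and their conventions

Per mask pair the package reports Dice (DCS), accuracy, precision, recall,
Hausdorff distance (HD) and a coefficient of determination (COD), in two
aggregation schemes: *sample-wise* (mean over the slices of a case, then
over cases) and *volume-wise* (metrics on the stacked 3-D case volume, then
mean over cases), with lesion-size terciles (small/medium/large) stratifying
the volume-wise rows.

Two formulas are implemented twice on purpose. The Dice variant
`2TP/(2TP+TN+FN)` (flag `as_printed`) substitutes TN where the standard
formula has FP; its magnitudes are inconsistent with near-unity accuracy on
large images, so `2TP/(2TP+FP+FN)` is the default. The COD default
normalizes the residual sum of squares by deviations of the *prediction*
from the truth's mean — this reproduces the characteristic large negative
values of that variant — while conventional R² is available as
`standard_r2`.

Degenerate inputs follow explicit conventions: empty-vs-empty Dice is 1;
HD is 0 when both masks are empty and the image diagonal when exactly one is
(a large, finite miss penalty); a zero COD denominator yields a `-Inf`
sentinel that aggregation excludes and counts. HD uses all foreground
voxels by default (`boundary_only` is available), scaled by voxel spacing.

## The phantom generator

Real CTP training data (e.g. the 94-case ISLES2018 cohort) is access-gated,
so the package ships a seeded pseudo-CTP phantom generator that preserves
the *structure* of the task: a brain-shaped support (superellipsoid filling
roughly 60% of the grid; voxels outside are exactly zero so min–max
normalization and CT masking behave as on real data); constant per-modality
baselines at physiologic magnitudes (CT 40, CBF 50, CBV 4, MTT 4, Tmax 2)
whose disparate ranges force per-volume normalization; a lesion of 1–3
anisotropic blobs with total size drawn log-uniformly from 0.5–15% of the
brain (a long tail spanning the small/medium/large strata); stroke-polarity
contrast inside the lesion (CBF ×0.3, CBV ×0.4, MTT ×2.5, Tmax ×3.0,
CT ×0.9), so a model must integrate multi-channel evidence; Gaussian noise
(σ = 5% of baseline) inside the brain, clipped at zero; and lesions confined
to a central slab so that some slices are lesion-free, as in real stacks.

What the phantoms do *not* emulate: acquisition physics, partial-volume and
beam-hardening artifacts, anatomical texture, inter-scanner variability, and
the fuzzy low-contrast boundaries of real infarcts. Passing the learning
checks below therefore demonstrates that the architecture, operators,
gradients and training loop work end-to-end on data with the right
multi-modal structure — not that the reported Dice transfers to clinical
images.

## Training protocols and the scaled study

Two protocols mirror the two experimental regimes the model family is used
in: `ablation` (constant learning rate 1e-6, 100 epochs — for comparing
convergence speed across architectural choices) and `comparison` (Adam,
early stopping on validation volume-wise DCS with patience 25, at most 300
epochs, learning rate ÷10 after epoch 100). Batches hold 4 slices as
disjoint graph unions; `steps_per_epoch = 45` reproduces the
100-epochs-=-4500-steps accounting. The best checkpoint by validation
volume-wise DCS is always the one reported — never the last epoch.
Fourfold cross-validation splits cases 3:1 and the training portion 9:1
into train/validation, evaluating volume-wise on the held-out fold; paired
two-sided t-tests on per-case metrics compare operator choices on identical
folds.

The package's own desk-scale study — what the test suite and
`scripts/acceptance.R` run — uses 20 phantom cases of 4×48×48 voxels
(16 train / 4 validation), GFCN-8s with base width 8, Graclus + isotropic
unpooling, Adam at 1e-3 for 45 epochs with batch 4. These sizes are the
smallest configuration on which the learning signal is unambiguous: the
validation volume-wise DCS crosses 0.7 around epoch 25 and plateaus near
0.71 (an all-background prediction scores 0). The learning rate suits the
phantom contrast, which is far stronger than clinical data and does not
need the conservative 1e-6 of the fixed-rate protocol. The same study
trains a no-pooling variant for 10 epochs and isotropic-versus-proportional
pairs over three seeds to check the qualitative ordering of Hausdorff
distances (isotropic tends to adhere better to lesion boundaries;
proportional smooths them).

A caveat worth stating plainly: on these phantoms the *no-pooling* variant
learns faster and attains a higher Dice than the pooled model, because
per-node multi-channel contrast nearly suffices to classify a voxel and the
pooled decoder pays a quantization cost at lesion boundaries when coarse
score maps are copied back to `V0`. Pooling buys receptive field, which phantoms with strong local contrast do
not reward; its advantages — computational efficiency from shrinking
graphs, and boundary adherence under the isotropic unpooling — are what
the Hausdorff-distance comparison in the same study measures.

## Numerical notes

* Basis evaluation clamps pseudo-coordinates to `[0,1]` with a warning
  (float drift in the affine map can overshoot by ~1e-16); a hard-error mode
  exists.
* The spline convolution is evaluated as one sparse-matrix product per
  topology (the gather/scatter and degree normalization are baked into a
  precomputed sparse matrix), so slice hierarchies are prepared once and
  reused across epochs.
* Graclus ties (equal matching scores) break by the seeded position hash;
  Top-k score ties break by lower node index.
* Batch-norm uses ε = 1e-5 and running-statistic momentum 0.1; evaluation
  mode uses the running statistics, making inference deterministic.
* Soft Dice uses `smooth = 1`, which defines the loss as 0 on slices where
  both prediction and target are empty.
* Adam uses the standard (0.9, 0.999, 1e-8) moments with bias correction.

## Limitations

Everything here is CPU R; it is sized for method study and testing, not for
training on full clinical volumes. Slice-wise 2-D processing ignores
through-plane context by design. The Top-k path is trainable but known to be
less stable than the heuristic unpoolings (its selection reshuffles the
topology every step); the training loop aborts with a diagnostic on
non-finite loss rather than attempting recovery.
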