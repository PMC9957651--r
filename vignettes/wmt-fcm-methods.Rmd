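---
title: "Multitask fuzzy C-means for brain MRI segmentation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multitask fuzzy C-means for brain MRI segmentation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmtfcm)
```

## The segmentation problem

A T1-weighted brain MRI slice is, to a first approximation, a piecewise
constant intensity image: background, cerebrospinal fluid (CSF), gray matter
(GM) and white matter (WM) each have a characteristic mean intensity, ordered
background < CSF < GM < WM.  Segmenting the slice then reduces to clustering
the pixel intensities into four groups, and fuzzy C-means (FCM) is the
classical tool: every pixel receives a fractional membership in every
cluster, and memberships and cluster centres are alternately updated in
closed form until the objective

$$J_{\mathrm{FCM}} = \sum_{i=1}^{N} \sum_{j=1}^{C} u_{ij}^m\,
  \lVert x_i - v_j\rVert^2,
  \qquad \sum_j u_{ij} = 1,$$

stops decreasing.  Real scans complicate this picture in two ways this
package models explicitly: additive acquisition noise, and a smooth
multiplicative shading of the coil sensitivity (intensity nonuniformity,
INU).  Both blur the intensity histogram and make the optimisation landscape
multimodal, so FCM becomes sensitive to its random initialization.

## The multitask model

When several related slices are segmented (different subjects, or the same
subject at different corruption levels), their cluster centres carry shared
information: all of them estimate the same four tissue intensities.  The
weighted multitask extension (WMT-FCM) couples $T$ such tasks through $D$
*public* centroids $z_d$ shared by all tasks, while each task keeps its own
*private* memberships $U^{(t)}$ and centroids $v_{j,t}$:

$$J = \underbrace{\sum_t \sum_i \sum_j u_{ij,t}^m \lVert x_{i,t}-v_{j,t}\rVert^2}_{\text{per-task FCM}}
 \;+\; \lambda \underbrace{\sum_t \sum_d \sum_j w_{d,t}\, p_{jd,t}^m
   \lVert v_{j,t}-z_d\rVert^2}_{\text{coupling to the public centroids}}
 \;+\; \gamma \underbrace{\sum_t \sum_d w_{d,t}\log w_{d,t}}_{\text{weight entropy}}$$

subject to unit column sums of each $U^{(t)}$, unit row sums of each public
membership matrix $P^{(t)}$ (which fuzzily assigns private to public
centroids), and, for every public cluster $d$, task weights $w_{d,t}$ that
sum to one over tasks.  The entropy term keeps the weights interior: solving
the first-order conditions gives a softmax over tasks of the negative
dispersions $-\lambda \sum_j p_{jd,t}^m \lVert v_{j,t}-z_d\rVert^2 / \gamma$,
so a task whose private centroids sit close to a public centroid earns a
larger say in it.

All five blocks — $U$, $P$, $V$, $Z$, $W$ — have exact closed-form
minimizers with the other blocks held fixed; `wmt_fcm()` applies them in
that order each sweep, so the objective is non-increasing by construction
and the fit stops when its absolute change falls below `eps`.  Each update
is exported (`update_private_membership()`, `update_public_membership()`,
`update_private_centroids()`, `update_public_centroids()`,
`update_weights()`) so the blocks can be tested and composed independently.

## Tunable parameters

* **`m` (fuzzifier, default 2).**  Membership softness; $m \to 1$ recovers
  hard C-means.  2 is the near-universal choice for MRI intensities.
* **`lambda` (default 60).**  Strength of the coupling between private and
  public centroids, in units of membership mass (it competes with
  $\sum_i u_{ij}^m$ in the centroid update).  The conventional search grid
  is $\{20, 40, \dots, 120\}$; 60 is its midpoint and `run_grid_search()`
  implements the standard SA-maximizing selection.
* **`gamma` (default 0.6).**  Entropy coefficient of the task weights.
  Large `gamma` flattens all weights to $1/T$; small `gamma` sharpens them
  toward one-hot on the lowest-dispersion task.  Grid
  $\{0.2, 0.4, \dots, 1.2\}$, midpoint 0.6.
* **`eps` (default `1e-4`) and `max_iter` (default 100).**  Absolute
  objective-change tolerance and sweep cap.  A centroid-change stopping rule
  is available in `fcm()` as an option.

**Intensity normalization.**  `wmt_fcm()` divides all intensities by their
pooled maximum before fitting and rescales the centroids on output.  The
weight softmax exponent $-\lambda\,\mathrm{disp}/\gamma$ must be of order
one for the entropy regularizer to act at the grid values above; on raw
scanner units (intensities up to a few hundred, squared distances up to
$10^4$) it is in the thousands and the weights always collapse to one-hot.
The unit scale makes the $\lambda$ and $\gamma$ grids transferable across
acquisitions.  Classical FCM is exactly scale-equivariant, so this
convention does not change the `lambda = 0` behaviour; `normalize = FALSE`
disables it.

## Initialization and numerical choices

* **Private centroids** are `C_t` distinct pixels drawn uniformly without
  replacement under the task's seed (`seed + t - 1`), for both `fcm()` and
  `wmt_fcm()`.  This keeps the two algorithms exactly comparable: at
  `lambda = 0` the multitask trajectories coincide with standalone FCM per
  task to floating-point accuracy.
* **Public centroids** start at the $D$ evenly spaced quantiles of the
  pooled intensities (probabilities $(2d-1)/2D$).  The public clustering
  problem is tiny — it sees only $\sum_t C_t$ private centroids — and small
  fuzzy clustering problems are brittle: starts derived from the random
  private centroids leave the public level with duplicate or missing
  centroids in a substantial fraction of seeds even when every task fits
  perfectly.  The quantile start is deterministic, data-driven, and leaves
  the private initialization (the randomness whose influence the coupling
  is meant to damp) untouched.
* **Weights** start uniform at $1/T$; **public memberships** by one
  application of their update.
* **Zero distances.**  A pixel coinciding with one or more centroids (or a
  private centroid coinciding with public ones) takes the uniform limit
  split over the coinciding centroids — the continuous limit of the update,
  deterministic, and exact for the block minimum.
* **Degenerate clusters.**  A cluster whose membership mass is zero keeps
  its previous centroid and a warning is raised; sweeps never crash.
* **Weight numerics.**  The softmax is computed after subtracting the
  per-public-cluster maximum exponent, so it cannot overflow.  A weight may
  still underflow to exactly zero at extreme `lambda/gamma`; the objective
  then uses the $0\log 0 = 0$ convention (values clamped at `1e-300` before
  the log) and the public membership update takes the corresponding limit.
* **Hard labels** are the column-wise membership argmax with a first-index
  tie-break, so label maps are reproducible bit-for-bit given a seed.

## Evaluation metrics

Clustering output is permutation-invariant, so `evaluate_segmentation()`
first matches clusters to tissues by the one-to-one assignment maximizing
total overlap on the contingency table (`align_clusters()`, exact search
with a lowest-index tie-break; an intensity-ordering rule is available for
T1 data).  It then reports, per tissue, the Dice similarity coefficient
$2|S_1 \cap S_2| / (|S_1| + |S_2|)$ (two empty masks score 1 by
convention); the *pooled* tissue-average Dice, which sums the CSF, GM and
WM overlaps and sizes before forming the ratio and excludes background —
note this is not the arithmetic mean of the three per-tissue values; and
the segmentation accuracy (SA), the fraction of correctly labelled pixels
over all classes including background.  Repeated-trial experiments
summarize metrics by their plain mean across trials.

## The phantom generator

`generate_phantom()` emulates a simulated T1 slice: a deterministic nested
elliptical geometry (background ring, CSF band, GM band, WM core; default
radii 0.92/0.76/0.55 of the half-image, giving roughly 34/21/22/24 % of
pixels per class), class means $\{0, 60, 120, 180\}$ by default, and the
two corruption processes with their conventional percentage parameters:

* noise: zero-mean Gaussian with $\sigma = (\text{noise}\%/100) \cdot
  \max(\text{class means})$, i.e. relative to the brightest tissue; a
  Rician option models magnitude-MRI noise;
* INU: a smooth low-order random surface (linear, bilinear, quadratic and
  half-cosine terms), rescaled to span exactly
  $[1 - \text{INU}\%/200,\; 1 + \text{INU}\%/200]$ and applied
  multiplicatively *before* the noise.

Intensities are clipped at zero, as scanner magnitudes are non-negative;
with a background mean of 0 this halves the background noise and biases the
background centroid upward by about $\sigma/\sqrt{2\pi}$ — visible in the
recovered public centroids at high noise.  `generate_task_group()` builds
groups of tasks sharing class means and geometry with independent
corruption realizations, which is precisely the common information the
multitask model exploits.  The standard study panel is the nine
noise/INU combinations returned by `brainweb_settings()`.

What the phantoms deliberately do **not** model: anatomical shapes, partial
volume voxels, multi-sequence contrasts, spatially correlated noise.
Passing tests on phantoms therefore demonstrate correctness of the
optimisation and evaluation machinery and the direction of the noise and
stability effects — not segmentation quality on clinical data.

## Experiment protocols and problem sizes

`run_stability_trials()` repeats both algorithms on a fixed task group under
derived seeds (trial $k$ uses master seed $+\,1009(k-1)$; within a trial
both algorithms share each task's initialization, so comparisons are
paired).  `run_noise_sweep()` traces SA and average Dice against the noise
level at fixed INU; `run_grid_search()` scans the $\lambda \times \gamma$
grid and selects the cell with the highest mean SA (ties: higher average
Dice, then smaller $\lambda$, then smaller $\gamma$).  Every result row
carries the seeds and phantom parameters needed to regenerate it exactly.
The package's own studies (tests and `scripts/acceptance.R`) use
$64 \times 64$ phantoms, three-task groups and ten trials — sizes at which
all protocols run in seconds while the class structure and failure modes of
full-size slices are preserved.

## Known limitations

* **The coupling is a nudge, not a funnel.**  Relative to the data term,
  the pull of a public centroid on a private one is of order
  $\lambda w p^m / \sum_i u_{ij}^m$ — about 1 % at $\lambda = 60$ on a
  $64 \times 64$ task.  It reduces the variance of centroid estimates
  across tasks but cannot move a fit out of a bad local optimum.
* **Merged-centroid optima are absorbing.**  When two sampled initial
  centroids land in one tissue class, plain FCM can converge with both on
  the pooled centre of two classes (typically swallowing CSF, the smallest
  class).  Two coincident private centroids have identical public
  memberships and therefore receive *identical* coupling pulls, so the
  multitask objective cannot separate them either: at desk scale WMT-FCM
  inherits FCM's failure trials and its advantage is confined to the small
  consensus nudge.  Repeated-trial averages (and, for centroid recovery,
  per-component medians, since the trial distribution is bimodal) are the
  appropriate summaries.
* **Scalar intensities only.**  All solvers cluster grayscale values;
  multi-channel (e.g. multi-sequence) distances are out of scope.
* **No spatial regularization.**  Pixels are exchangeable given their
  intensity; spatially correlated artifacts are not repaired.
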