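# wmtfcm

Intensity-based fuzzy clustering for brain MRI tissue segmentation, for
researchers who need a reproducible, testable implementation of classical
fuzzy C-means (FCM) and its weighted multitask extension (WMT-FCM) —
together with the evaluation metrics and synthetic phantoms needed to study
both algorithms without any external imaging data.

## The model

A T1-weighted slice is segmented by clustering pixel intensities into
background, CSF, gray matter and white matter.  Classical FCM minimizes

    J_FCM = Σ_i Σ_j u_ij^m ‖x_i − v_j‖²,   Σ_j u_ij = 1,

by alternating closed-form membership and centroid updates.  WMT-FCM
couples T related segmentation tasks through D shared *public* centroids
z_d, with per-task public memberships p_jd,t and entropy-regularized task
weights w_d,t:

    J = Σ_t Σ_i Σ_j u_ij,t^m ‖x_i,t − v_j,t‖²
      + λ Σ_t Σ_d Σ_j w_d,t p_jd,t^m ‖v_j,t − z_d‖²
      + γ Σ_t Σ_d w_d,t log w_d,t,

subject to unit-sum constraints on every U column, every P row, and every
weight column over tasks.  All five blocks (U, P, V, Z, W) have exact
closed-form minimizers; `wmt_fcm()` applies them in that order each sweep,
so the objective never increases.  The weights are a softmax over tasks of
negative dispersions: tasks whose private centroids agree with a public
centroid earn more influence on it.  See the methods vignette
(`vignettes/wmt-fcm-methods.Rmd`) for assumptions, parameter conventions
and numerical details.

## Worked example

Three synthetic slices sharing tissue means {0, 60, 120, 180} at different
corruption levels, segmented jointly:

```r
library(wmtfcm)

g <- generate_task_group(list(c(1, 20), c(5, 20), c(7, 0)),   # (noise %, INU %)
                         shape = c(64, 64), seed = 42)
fit <- wmt_fcm(g, centers = 4, seed = 42)
summary(fit)
#> Weighted multitask fuzzy C-means fit: 3 tasks, D = 4 public clusters
#>   lambda = 60, gamma = 0.6, m = 2
#>   public centroids Z:   8.721  117.738   59.810  178.497
#>   objective: 21.44 after 9 sweeps (converged)
#>   task weights W (rows = public clusters):
#>        [,1]   [,2]   [,3]
#> [1,] 0.3355 0.3598 0.3047
#> [2,] 0.3379 0.3287 0.3334
#> [3,] 0.3334 0.3338 0.3328
#> [4,] 0.3272 0.3317 0.3412
#>   ...
```

The public centroids recover the shared tissue means (sorted: 8.7, 59.8,
117.7, 178.5 — the background estimate sits above 0 because scanner
magnitudes are clipped at zero, which biases the background mean upward at
7 % noise).  Evaluating one task against its ground truth:

```r
evaluate_segmentation(fit$tasks$task2$labels, as.integer(g$task2$truth))
#> Segmentation metrics
#>   SA     : 0.9998
#>   DSC_av : 0.9996 (pooled CSF/GM/WM)
#>   DSC    : background 1.0000  csf 0.9994  gm 0.9994  wm 1.0000
#>   cluster -> class: 0 -> 1, 1 -> 3, 2 -> 0, 3 -> 2
```

`SA` is the fraction of correctly labelled pixels after matching clusters
to tissues by maximum overlap; `DSC_av` pools the CSF/GM/WM Dice overlaps
(background excluded).  The baseline is a single-task fit with the same
initialization: `fcm(g$task2$image, centers = 4, seed = 43)`.

The experiment protocols of a full study — repeated-trial stability
(`run_stability_trials()`), noise sweeps (`run_noise_sweep()`), and the
λ × γ grid search (`run_grid_search()`) — return provenance-complete data
frames that round-trip through CSV.  A thin command-line interface over the
same functions (subcommands `phantom`, `segment`, `evaluate`, `gridsearch`,
`sweep-noise`, `stability`) is installed at
`system.file("cli", "wmtfcm.R", package = "wmtfcm")`.

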