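#' Repeated-trial stability protocol
#'
#' Runs classical FCM (independently per task) and WMT-FCM (jointly) on a
#' fixed task group `n_trials` times under distinct derived seeds, and
#' reports per-trial evaluation metrics.  Because fuzzy clustering depends
#' on the random centroid initialization, the spread of SA across trials
#' measures initialization sensitivity; multitask coupling is expected to
#' shrink it.
#'
#' Trial k uses master seed `seed + 1009 (k-1)`; within a trial, task t is
#' initialized under `trial_seed + t - 1` in both algorithms, so the two
#' algorithms start from identical centroids and any trial is reproducible
#' in isolation.
#'
#' @param group list of [phantom] objects (a task group sharing class
#'   means), e.g. from [generate_task_group()].
#' @param n_clusters clusters per task (default 4).
#' @param lambda,gamma WMT-FCM coupling and entropy parameters.
#' @param n_trials number of repeated trials (default 10).
#' @param seed master seed.
#' @param algorithms which algorithms to run.
#' @param m,eps,max_iter solver settings shared by both algorithms.
#' @return data.frame with one row per (algorithm, trial, task):
#'   `algorithm`, `trial`, `seed`, `task`, `noise_pct`, `inu_pct`,
#'   `lambda`, `gamma`, `n_clusters`, `sa`, `dsc_csf`, `dsc_gm`, `dsc_wm`,
#'   `dsc_av`, plus phantom provenance (`class_means`, `shape`,
#'   `phantom_seed`).
#' @export
run_stability_trials <- function(group, n_clusters = 4, lambda = 60,
                                 gamma = 0.6, n_trials = 10, seed = 1L,
                                 algorithms = c("fcm", "wmt_fcm"),
                                 m = 2, eps = 1e-4, max_iter = 100L) {
  stopifnot(length(group) >= 1L, n_trials >= 1L)
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  rows <- vector("list", 0L)
  for (k in seq_len(n_trials)) {
    sk <- trial_seed(seed, k)
    rows[[length(rows) + 1L]] <-
      segment_group_once(group, algorithms, sk, k, n_clusters,
                         lambda, gamma, m, eps, max_iter)
  }
  do.call(rbind, rows)
}

#' Noise-robustness sweep
#'
#' Evaluates both algorithms on task groups of increasing noise level at a
#' fixed INU level, producing the SA and average-Dice curves that show how
#' segmentation quality degrades with noise and how much of that loss the
#' multitask coupling recovers.
#'
#' At each noise level a fresh group of `n_tasks` phantoms (identical
#' geometry, independent noise realizations) is generated and
#' [run_stability_trials()] is applied.
#'
#' @param noise_levels noise percentages to sweep (default 1, 3, 5, 7, 9).
#' @param inu_pct INU percentage held fixed (default 20).
#' @param n_tasks tasks per group (default 3).
#' @param class_means,shape,geometry passed to [generate_task_group()].
#' @inheritParams run_stability_trials
#' @return data.frame as in [run_stability_trials()] with the noise level of
#'   each row in `noise_pct`.
#' @export
run_noise_sweep <- function(noise_levels = c(1, 3, 5, 7, 9), inu_pct = 20,
                            n_tasks = 3, class_means = c(0, 60, 120, 180),
                            shape = c(64, 64), geometry = NULL,
                            n_clusters = 4, lambda = 60, gamma = 0.6,
                            n_trials = 10, seed = 1L,
                            m = 2, eps = 1e-4, max_iter = 100L) {
  if (length(noise_levels) < 1L)
    stop("run_noise_sweep: need at least one noise level", call. = FALSE)
  out <- vector("list", length(noise_levels))
  for (i in seq_along(noise_levels)) {
    settings <- replicate(n_tasks, c(noise_levels[i], inu_pct),
                          simplify = FALSE)
    group <- generate_task_group(settings, class_means = class_means,
                                 seed = trial_seed(seed, i) + 500000L,
                                 shape = shape, geometry = geometry)
    out[[i]] <- run_stability_trials(group, n_clusters = n_clusters,
                                     lambda = lambda, gamma = gamma,
                                     n_trials = n_trials, seed = seed,
                                     m = m, eps = eps, max_iter = max_iter)
  }
  do.call(rbind, out)
}

#' Grid search over the WMT-FCM coupling parameters
#'
#' Runs WMT-FCM over every (lambda, gamma) cell of the given grids with
#' `n_trials` seeded trials per cell and selects the cell maximizing mean
#' SA (ties broken by higher mean average Dice, then smaller lambda, then
#' smaller gamma).
#'
#' @param group list of [phantom] objects.
#' @param lambda_grid,gamma_grid parameter grids; defaults are the
#'   conventional \{20, 40, ..., 120\} and \{0.2, 0.4, ..., 1.2\}.
#' @inheritParams run_stability_trials
#' @return An object of class `wmt_grid`: list with `results` (all rows),
#'   `cells` (per-cell mean SA and average Dice), and `best`
#'   (`lambda`, `gamma`, `mean_sa`, `mean_dsc_av`).
#' @export
run_grid_search <- function(group, lambda_grid = seq(20, 120, by = 20),
                            gamma_grid = seq(0.2, 1.2, by = 0.2),
                            n_clusters = 4, n_trials = 10, seed = 1L,
                            m = 2, eps = 1e-4, max_iter = 100L) {
  stopifnot(length(lambda_grid) >= 1L, length(gamma_grid) >= 1L)
  rows <- vector("list", 0L)
  for (la in lambda_grid) for (ga in gamma_grid) {
    rows[[length(rows) + 1L]] <-
      run_stability_trials(group, n_clusters = n_clusters, lambda = la,
                           gamma = ga, n_trials = n_trials, seed = seed,
                           algorithms = "wmt_fcm", m = m, eps = eps,
                           max_iter = max_iter)
  }
  results <- do.call(rbind, rows)
  cells <- stats::aggregate(results[, c("sa", "dsc_av")],
                            by = results[, c("lambda", "gamma")], FUN = mean)
  ord <- order(-cells$sa, -cells$dsc_av, cells$lambda, cells$gamma)
  cells <- cells[ord, ]
  best <- cells[1L, ]
  structure(list(
    results = results,
    cells = cells,
    best = list(lambda = best$lambda, gamma = best$gamma,
                mean_sa = best$sa, mean_dsc_av = best$dsc_av)
  ), class = "wmt_grid")
}

#' @export
print.wmt_grid <- function(x, digits = 4, ...) {
  cat("WMT-FCM grid search over", nrow(x$cells), "cells\n")
  cat("  best cell: lambda =", x$best$lambda, ", gamma =", x$best$gamma,
      "\n")
  cat("  mean SA =", format(x$best$mean_sa, digits = digits),
      ", mean DSC_av =", format(x$best$mean_dsc_av, digits = digits), "\n")
  invisible(x)
}

#' Write / read a metrics table as CSV
#'
#' Plain CSV round-trip for the results tables produced by the experiment
#' protocols.
#'
#' @param results data.frame of metric rows.
#' @param path destination / source file.
#' @return `path` invisibly; `read_metrics_csv` returns the data.frame.
#' @export
write_metrics_csv <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metrics_csv
#' @export
read_metrics_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# one seeded trial of the requested algorithms on a task group
segment_group_once <- function(group, algorithms, sk, k, n_clusters,
                               lambda, gamma, m, eps, max_iter) {
  T_ <- length(group)
  truth <- lapply(group, function(ph) as.integer(ph$truth))
  preds <- list()
  if ("fcm" %in% algorithms) {
    preds$fcm <- lapply(seq_len(T_), function(t)
      fcm(group[[t]]$image, centers = n_clusters, m = m, eps = eps,
          max_iter = max_iter, seed = sk + t - 1L)$labels)
  }
  if ("wmt_fcm" %in% algorithms) {
    fit <- wmt_fcm(group, centers = n_clusters, lambda = lambda,
                   gamma = gamma, m = m, eps = eps, max_iter = max_iter,
                   seed = sk)
    preds$wmt_fcm <- lapply(fit$tasks, `[[`, "labels")
  }
  rows <- list()
  for (alg in names(preds)) {
    for (t in seq_len(T_)) {
      mt <- evaluate_segmentation(preds[[alg]][[t]], truth[[t]],
                                  n_classes = n_clusters)
      p <- group[[t]]$params
      rows[[length(rows) + 1L]] <- data.frame(
        algorithm = alg, trial = k, seed = sk, task = t,
        noise_pct = p$noise_pct, inu_pct = p$inu_pct,
        lambda = if (alg == "wmt_fcm") lambda else NA_real_,
        gamma = if (alg == "wmt_fcm") gamma else NA_real_,
        n_clusters = n_clusters,
        sa = mt$sa,
        dsc_csf = unname(mt$dsc[2L]), dsc_gm = unname(mt$dsc[3L]),
        dsc_wm = unname(mt$dsc[4L]), dsc_av = mt$dsc_av,
        class_means = paste(p$class_means, collapse = "|"),
        shape = paste(p$shape, collapse = "x"),
        phantom_seed = if (is.null(p$seed)) NA_integer_ else p$seed,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
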