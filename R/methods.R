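#' @export
print.fcm <- function(x, digits = 4, ...) {
  cat("Fuzzy C-means fit (", x$config$n_clusters, " clusters, ",
      length(x$data), " pixels)\n", sep = "")
  cat("  centroids:", paste(format(x$centroids, digits = digits),
                            collapse = "  "), "\n")
  cat("  objective:", format(utils::tail(x$objective_trace, 1L),
                             digits = digits),
      "after", x$n_iter, "iterations",
      if (x$converged) "(converged)" else "(iteration limit)", "\n")
  invisible(x)
}

#' @export
summary.fcm <- function(object, ...) {
  sizes <- tabulate(object$labels + 1L, nbins = object$config$n_clusters)
  structure(list(fit = object, cluster_sizes = sizes,
                 fuzziness = mean(1 - apply(object$memberships, 2L, max))),
            class = "summary.fcm")
}

#' @export
print.summary.fcm <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("  cluster sizes:", paste(x$cluster_sizes, collapse = " / "), "\n")
  cat("  mean fuzziness (1 - max membership):",
      format(x$fuzziness, digits = digits), "\n")
  invisible(x)
}

#' @export
coef.fcm <- function(object, ...) object$centroids

#' Predict memberships or labels for new intensities
#'
#' Applies the fitted centroids to new pixel intensities via the membership
#' update, without refitting.
#'
#' @param object an [fcm()] fit.
#' @param newdata intensities (vector, matrix, or [task_data]); defaults to
#'   the training image.
#' @param type `"labels"` (0-based hard assignment) or `"memberships"`
#'   (C x N matrix).
#' @param ... unused.
#' @export
predict.fcm <- function(object, newdata = NULL,
                        type = c("labels", "memberships"), ...) {
  type <- match.arg(type)
  x <- if (is.null(newdata)) object$data else task_data(newdata)$pixels
  U <- fcm_membership_update(x, object$centroids, object$config$m)
  if (type == "memberships") U else hard_labels(U)
}

#' @export
fitted.fcm <- function(object, ...) {
  object$centroids[object$labels + 1L]
}

#' @export
residuals.fcm <- function(object, ...) {
  object$data - fitted(object)
}

#' Hard label map of a fit
#'
#' Returns the 0-based hard segmentation of an [fcm()] fit, folded back to
#' image shape when the input was an image.
#'
#' @param object an `fcm` fit.
#' @param ... unused.
#' @export
labels.fcm <- function(object, ...) {
  if (is.null(object$shape)) object$labels
  else unflatten_rowmajor(object$labels, object$shape)
}

#' @export
plot.fcm <- function(x, ...) {
  if (is.null(x$shape) || length(x$shape) != 2L) {
    graphics::plot(x$objective_trace, type = "b", xlab = "iteration",
                   ylab = "objective", ...)
  } else {
    img_show(labels(x), main = "hard segmentation", ...)
  }
  invisible(x)
}

# ---- wmt_fcm methods --------------------------------------------------------

#' @export
print.wmt_fcm <- function(x, digits = 4, ...) {
  cfg <- x$config
  cat("Weighted multitask fuzzy C-means fit: ", length(x$tasks),
      " tasks, D = ", cfg$public_clusters, " public clusters\n", sep = "")
  cat("  lambda = ", cfg$lambda, ", gamma = ", cfg$gamma, ", m = ", cfg$m,
      "\n", sep = "")
  cat("  public centroids Z:",
      paste(format(x$public$Z, digits = digits), collapse = "  "), "\n")
  cat("  objective:", format(utils::tail(x$objective_trace, 1L),
                             digits = digits),
      "after", x$n_iter, "sweeps",
      if (x$converged) "(converged)" else "(sweep limit)", "\n")
  invisible(x)
}

#' @export
summary.wmt_fcm <- function(object, ...) {
  structure(list(fit = object), class = "summary.wmt_fcm")
}

#' @export
print.summary.wmt_fcm <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  W <- x$fit$public$W
  cat("  task weights W (rows = public clusters):\n")
  print(round(W, digits))
  cat("  objective terms:\n")
  print(round(x$fit$objective_terms, digits))
  for (nm in names(x$fit$tasks)) {
    ft <- x$fit$tasks[[nm]]
    cat("  ", nm, " centroids: ",
        paste(format(ft$centroids, digits = digits), collapse = "  "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @param object a `wmt_fcm` fit.
#' @param which `"public"` for the shared centroids Z (default), `"private"`
#'   for the list of per-task centroid vectors, `"weights"` for the D x T
#'   task weight matrix.
#' @param ... unused.
#' @rdname wmt_fcm
#' @export
coef.wmt_fcm <- function(object, which = c("public", "private", "weights"),
                         ...) {
  which <- match.arg(which)
  switch(which,
         public = object$public$Z,
         private = lapply(object$tasks, `[[`, "centroids"),
         weights = object$public$W)
}

#' Per-task hard label maps of a multitask fit
#'
#' @param object a `wmt_fcm` fit.
#' @param ... unused.
#' @export
labels.wmt_fcm <- function(object, ...) {
  lapply(object$tasks, function(ft) {
    if (is.null(ft$shape)) ft$labels
    else unflatten_rowmajor(ft$labels, ft$shape)
  })
}

#' Predict labels for new intensities from a multitask fit
#'
#' @param object a [wmt_fcm()] fit.
#' @param newdata new intensities, classified with the private centroids of
#'   task `task`.
#' @param task task index or name.
#' @param type `"labels"` or `"memberships"`.
#' @param ... unused.
#' @export
predict.wmt_fcm <- function(object, newdata, task = 1L,
                            type = c("labels", "memberships"), ...) {
  type <- match.arg(type)
  v <- object$tasks[[task]]$centroids
  U <- fcm_membership_update(task_data(newdata)$pixels, v, object$config$m)
  if (type == "memberships") U else hard_labels(U)
}

#' @export
plot.wmt_fcm <- function(x, ...) {
  maps <- labels(x)
  if (is.null(dim(maps[[1L]]))) {
    graphics::plot(x$objective_trace, type = "b", xlab = "sweep",
                   ylab = "objective", ...)
    return(invisible(x))
  }
  op <- graphics::par(mfrow = c(1, length(maps)), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  for (nm in names(maps)) img_show(maps[[nm]], main = nm, ...)
  invisible(x)
}
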