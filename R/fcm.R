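#' Fuzzy C-means objective value
#'
#' The fuzzified within-cluster sum of squared distances
#' \deqn{J = \sum_{i=1}^{N} \sum_{j=1}^{C} u_{ij}^m \, \|x_i - v_j\|^2,}
#' the quantity minimized by fuzzy C-means.
#'
#' @param data intensities as a numeric vector, matrix, or [task_data].
#' @param memberships C x N membership matrix; every column must lie on the
#'   probability simplex.
#' @param centroids numeric vector of C cluster centres.
#' @param m fuzzifier (> 1); controls membership softness.
#' @return a single non-negative number.
#' @seealso [fcm()] for the full fit, [fcm_membership_update()],
#'   [fcm_centroid_update()] for the closed-form block updates.
#' @export
fcm_objective <- function(data, memberships, centroids, m = 2) {
  x <- task_data(data)$pixels
  U <- as.matrix(memberships)
  v <- as.numeric(centroids)
  if (ncol(U) != length(x) || nrow(U) != length(v))
    stop("fcm_objective: dimensions of memberships, centroids and data disagree",
         call. = FALSE)
  d2 <- sq_dist(x, v)
  sum(U^m * d2)
}

#' Fuzzy C-means membership update
#'
#' Closed-form minimizer of the fuzzy C-means objective over the membership
#' matrix with centroids held fixed:
#' \deqn{u_{ij} = \frac{\|x_i-v_j\|^{-2/(m-1)}}{\sum_l \|x_i-v_l\|^{-2/(m-1)}}.}
#' A pixel coinciding with one or more centroids receives membership split
#' uniformly over the coinciding centroids (the limit of the formula), so the
#' update is total and deterministic.
#'
#' @inheritParams fcm_objective
#' @return C x N membership matrix; every column sums to 1.
#' @export
fcm_membership_update <- function(data, centroids, m = 2) {
  x <- task_data(data)$pixels
  v <- as.numeric(centroids)
  stopifnot(length(v) >= 1L, m > 1)
  d2 <- sq_dist(x, v)
  simplex_from_inverse_power(d2, -1 / (m - 1), margin = 2L)
}

#' Fuzzy C-means centroid update
#'
#' Closed-form minimizer over the centroids with memberships held fixed:
#' the membership-weighted mean
#' \deqn{v_j = \sum_i u_{ij}^m x_i \big/ \sum_i u_{ij}^m.}
#' A cluster whose total membership mass is zero cannot be placed; its
#' centroid is left at `centroids` (previous value) with a warning, or at the
#' data mean when no previous value is supplied.
#'
#' @inheritParams fcm_objective
#' @param centroids optional previous centroids used to freeze degenerate
#'   clusters.
#' @return numeric vector of C centroids, each within the data range.
#' @export
fcm_centroid_update <- function(data, memberships, m = 2, centroids = NULL) {
  x <- task_data(data)$pixels
  U <- as.matrix(memberships)
  if (ncol(U) != length(x))
    stop("fcm_centroid_update: memberships do not match the data", call. = FALSE)
  um <- U^m
  mass <- rowSums(um)
  v <- as.numeric(um %*% x)
  dead <- mass <= 0
  v[!dead] <- v[!dead] / mass[!dead]
  if (any(dead)) {
    warning("degenerate cluster(s) with zero membership mass: centroid frozen",
            call. = FALSE)
    v[dead] <- if (!is.null(centroids)) as.numeric(centroids)[dead] else mean(x)
  }
  v
}

#' Fit classical fuzzy C-means to one image
#'
#' Segments a grayscale image by fuzzy C-means: alternating closed-form
#' membership and centroid updates until the objective changes by less than
#' `eps` or `max_iter` iterations are reached.  Cluster centres are
#' initialized as `centers` distinct pixels drawn uniformly without
#' replacement under `seed`, so a fit is fully reproducible.
#'
#' @param x intensities as a numeric vector, matrix (image), or [task_data].
#' @param centers number of clusters C (must satisfy 1 <= C < N), or a
#'   numeric vector of initial centroids.
#' @param m fuzzifier (> 1); 2 is the conventional choice.
#' @param eps convergence tolerance on the absolute change of the objective.
#' @param max_iter maximum number of iterations.
#' @param seed integer seed for the random initialization; `NULL` leaves the
#'   RNG state untouched.
#' @param stop_on stop when the objective change (`"objective"`, default) or
#'   the largest centroid change (`"centroids"`) falls below `eps`.
#' @return An object of class `fcm`: a list with `centroids`, `memberships`
#'   (C x N), `labels` (0-based hard assignment, argmax membership),
#'   `objective_trace`, `n_iter`, `converged`, `shape`, and the call.
#'   Methods: [print()], [summary()], [coef()], [predict()], [fitted()],
#'   [residuals()], [plot()].
#' @examples
#' img <- matrix(c(rnorm(50, 0, 0.01), rnorm(50, 10, 0.01)), 10, 10)
#' fit <- fcm(img, centers = 2, seed = 1)
#' sort(coef(fit))   # close to 0 and 10
#' @export
fcm <- function(x, centers, m = 2, eps = 1e-4, max_iter = 100L, seed = NULL,
                stop_on = c("objective", "centroids")) {
  stop_on <- match.arg(stop_on)
  td <- task_data(x)
  xs <- td$pixels
  N <- length(xs)
  if (length(centers) == 1L && centers == round(centers)) {
    C <- as.integer(centers)
    if (C < 1L || C >= N)
      stop("fcm: number of clusters must satisfy 1 <= C < N", call. = FALSE)
    v <- with_seed(seed, xs[sample.int(N, C)])
  } else {
    v <- as.numeric(centers)
    C <- length(v)
    if (C >= N) stop("fcm: more centroids than pixels", call. = FALSE)
  }
  stopifnot(m > 1, eps > 0, max_iter >= 1L)

  trace <- numeric(0)
  converged <- FALSE
  U <- NULL
  for (k in seq_len(max_iter)) {
    v_old <- v
    U <- fcm_membership_update(xs, v, m)
    v <- fcm_centroid_update(xs, U, m, centroids = v)
    trace[k] <- fcm_objective(xs, U, v, m)
    done <- if (stop_on == "objective")
      k > 1L && abs(trace[k] - trace[k - 1L]) < eps
    else
      max(abs(v - v_old)) < eps
    if (done) {
      converged <- TRUE
      break
    }
  }

  structure(list(
    centroids = v,
    memberships = U,
    labels = hard_labels(U),
    objective_trace = trace,
    n_iter = length(trace),
    converged = converged,
    shape = td$shape,
    task_id = td$task_id,
    config = list(n_clusters = C, m = m, eps = eps,
                  max_iter = as.integer(max_iter), seed = seed,
                  stop_on = stop_on),
    data = xs,
    call = match.call()
  ), class = "fcm")
}

# ---- shared kernels ---------------------------------------------------------

# squared Euclidean distances between scalar intensities and centres: C x N
sq_dist <- function(x, v) {
  outer(v, x, function(a, b) (b - a)^2)
}

# Normalize g = d^power row- or column-wise onto the simplex, where d holds
# (weighted) squared distances and power < 0.  Zero distances produce Inf;
# those entries take the uniform-limit split, everything else 0.
simplex_from_inverse_power <- function(d, power, margin) {
  g <- d^power
  bad <- !is.finite(g)
  if (margin == 2L) {         # columns on the simplex (membership matrices)
    out <- sweep(g, 2L, colSums(g), "/")
    fix <- which(colSums(bad) > 0L)
    for (j in fix) out[, j] <- bad[, j] / sum(bad[, j])
  } else {                    # rows on the simplex (public memberships)
    out <- sweep(g, 1L, rowSums(g), "/")
    fix <- which(rowSums(bad) > 0L)
    for (i in fix) out[i, ] <- bad[i, ] / sum(bad[i, ])
  }
  out
}

# 0-based hard labels from a C x N membership matrix; first-max tie break
hard_labels <- function(U) {
  max.col(t(U), ties.method = "first") - 1L
}
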