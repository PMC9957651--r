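#' Weighted multitask fuzzy C-means objective
#'
#' The three-term objective minimized by [wmt_fcm()]:
#' \deqn{J = \sum_t \sum_i \sum_j u_{ij,t}^m \|x_{i,t}-v_{j,t}\|^2
#'   + \lambda \sum_t \sum_d \sum_j w_{d,t}\, p_{jd,t}^m \|v_{j,t}-z_d\|^2
#'   + \gamma \sum_t \sum_d w_{d,t} \log w_{d,t}.}
#' The first term is the per-task fuzzy C-means fit; the second couples each
#' task's private centroids \eqn{v_{j,t}} to shared public centroids
#' \eqn{z_d} through public memberships \eqn{p_{jd,t}} and task weights
#' \eqn{w_{d,t}}; the third is the Shannon-entropy regularizer that keeps the
#' task weights interior (it is never positive since every
#' \eqn{w \in (0,1]}).
#'
#' @param tasks list of tasks ([task_data] objects, numeric vectors, or
#'   matrices).
#' @param state list with elements `U` (list of C_t x N_t private membership
#'   matrices), `V` (list of private centroid vectors), `P` (list of C_t x D
#'   public membership matrices), `Z` (D public centroids), `W` (D x T task
#'   weight matrix).
#' @param m fuzzifier (> 1).
#' @param lambda balance parameter (>= 0) weighting the public coupling term.
#' @param gamma entropy coefficient (> 0).
#' @param check validate the simplex constraints (tolerance 1e-6) before
#'   evaluating; violation raises an error.
#' @return the objective value, with attribute `"terms"` giving the three
#'   components (`private`, `public`, `entropy`) for diagnostics.
#' @export
wmt_objective <- function(tasks, state, m = 2, lambda, gamma, check = TRUE) {
  tasks <- lapply(tasks, task_data)
  T_ <- length(tasks)
  if (check) check_state(state, T_)
  private <- 0
  public <- 0
  for (t in seq_len(T_)) {
    x <- tasks[[t]]$pixels
    private <- private +
      sum(state$U[[t]]^m * sq_dist(x, state$V[[t]]))
    d2 <- sq_dist(state$Z, state$V[[t]])            # C_t x D
    public <- public +
      sum(t(state$W[, t] * t(state$P[[t]]^m)) * d2)
  }
  w <- pmax(state$W, 1e-300)                        # 0 log 0 = 0 convention
  entropy <- sum(state$W * log(w))
  val <- private + lambda * public + gamma * entropy
  attr(val, "terms") <- c(private = private, public = lambda * public,
                          entropy = gamma * entropy)
  val
}

#' Private membership update (per task)
#'
#' Identical in form to the classical fuzzy C-means membership update: the
#' private memberships of a task depend only on that task's pixels and
#' private centroids, not on the public centroids or weights.  Delegates to
#' [fcm_membership_update()].
#'
#' @inheritParams fcm_membership_update
#' @return C_t x N_t membership matrix with unit column sums.
#' @export
update_private_membership <- function(data, centroids, m = 2) {
  fcm_membership_update(data, centroids, m)
}

#' Public membership update
#'
#' Fuzzy assignment of a task's private centroids to the public centroids,
#' with the task weight entering inside the inverse power:
#' \deqn{p_{jd} = \frac{(w_d \|v_j - z_d\|^2)^{-1/(m-1)}}
#'   {\sum_l (w_l \|v_j - z_l\|^2)^{-1/(m-1)}}.}
#' Rows sum to 1; a private centroid coinciding with one or more public
#' centroids takes the uniform-limit split over the coinciding ones.  The
#' entropy regularizer keeps the weights mathematically interior, but a
#' weight may underflow to exactly 0 at large `lambda/gamma`; the update
#' then takes the corresponding limit (a zero weighted distance attracts
#' the row's mass), so it stays total.
#'
#' @param centroids the task's private centroids (length C_t).
#' @param public_centroids the shared public centroids (length D).
#' @param weights the task's weight column w_(.,t) (length D, all >= 0).
#' @param m fuzzifier (> 1).
#' @return C_t x D matrix with unit row sums.
#' @export
update_public_membership <- function(centroids, public_centroids, weights,
                                     m = 2) {
  v <- as.numeric(centroids)
  z <- as.numeric(public_centroids)
  w <- as.numeric(weights)
  stopifnot(length(w) == length(z), all(w >= 0), m > 1)
  wd2 <- sq_dist(z, v) * rep(w, each = length(v))   # C_t x D
  simplex_from_inverse_power(wd2, -1 / (m - 1), margin = 1L)
}

#' Private centroid update
#'
#' Weighted mean of the task's pixels and the public centroids:
#' \deqn{v_j = \frac{\sum_i u_{ij}^m x_i + \lambda \sum_d w_d p_{jd}^m z_d}
#'   {\sum_i u_{ij}^m + \lambda \sum_d w_d p_{jd}^m},}
#' so each private centroid lies in the convex hull of the pixels and the
#' public centroids.  With `lambda = 0` this is exactly the classical
#' centroid update.
#'
#' @inheritParams fcm_objective
#' @param pub_memberships the task's C_t x D public membership matrix.
#' @param weights the task's weight column (length D).
#' @param public_centroids the shared public centroids (length D).
#' @param lambda balance parameter (>= 0).
#' @param centroids optional previous centroids used to freeze a cluster
#'   whose total mass is zero (degenerate), with a warning.
#' @return numeric vector of C_t updated private centroids.
#' @export
update_private_centroids <- function(data, memberships, pub_memberships,
                                     weights, public_centroids, m = 2,
                                     lambda = 0, centroids = NULL) {
  x <- task_data(data)$pixels
  U <- as.matrix(memberships)
  P <- as.matrix(pub_memberships)
  w <- as.numeric(weights)
  z <- as.numeric(public_centroids)
  um <- U^m
  pm <- t(w * t(P^m))                               # C_t x D, w_d p_jd^m
  num <- as.numeric(um %*% x) + lambda * as.numeric(pm %*% z)
  den <- rowSums(um) + lambda * rowSums(pm)
  v <- num
  dead <- den <= 0
  v[!dead] <- v[!dead] / den[!dead]
  if (any(dead)) {
    warning("degenerate private cluster(s): centroid frozen", call. = FALSE)
    v[dead] <- if (!is.null(centroids)) as.numeric(centroids)[dead] else mean(x)
  }
  v
}

#' Public centroid update
#'
#' Each public centroid is the weight- and membership-weighted mean of all
#' tasks' private centroids:
#' \deqn{z_d = \frac{\sum_t \sum_j w_{d,t} p_{jd,t}^m v_{j,t}}
#'   {\sum_t \sum_j w_{d,t} p_{jd,t}^m}.}
#'
#' @param centroid_list list over tasks of private centroid vectors.
#' @param pub_membership_list list over tasks of C_t x D public membership
#'   matrices.
#' @param weight_matrix D x T task weight matrix.
#' @param m fuzzifier (> 1).
#' @param public_centroids optional previous public centroids used to freeze
#'   a public cluster with zero total mass (degenerate), with a warning.
#' @return numeric vector of D public centroids, each within the range of
#'   the private centroids.
#' @export
update_public_centroids <- function(centroid_list, pub_membership_list,
                                    weight_matrix, m = 2,
                                    public_centroids = NULL) {
  D <- nrow(weight_matrix)
  num <- numeric(D)
  den <- numeric(D)
  for (t in seq_along(centroid_list)) {
    pm <- t(weight_matrix[, t] * t(pub_membership_list[[t]]^m))  # C_t x D
    num <- num + as.numeric(crossprod(pm, centroid_list[[t]]))
    den <- den + colSums(pm)
  }
  z <- num
  dead <- den <= 0
  z[!dead] <- z[!dead] / den[!dead]
  if (any(dead)) {
    warning("degenerate public cluster(s): centroid frozen", call. = FALSE)
    z[dead] <- if (!is.null(public_centroids))
      as.numeric(public_centroids)[dead]
    else mean(unlist(centroid_list))
  }
  z
}

#' Task weight update
#'
#' The entropy-regularized optimal weights are a softmax over tasks of the
#' negative public dispersions:
#' \deqn{w_{d,t} = \frac{\exp(-\lambda \sum_j p_{jd,t}^m \|v_{j,t}-z_d\|^2 / \gamma)}
#'   {\sum_h \exp(-\lambda \sum_j p_{jd,h}^m \|v_{j,h}-z_d\|^2 / \gamma)}.}
#' A task whose private centroids sit close to public centroid \eqn{z_d}
#' (small dispersion) receives a large weight for that public cluster.  The
#' softmax is computed after shifting each public cluster's exponents by
#' their maximum, so it neither overflows nor underflows for any finite
#' input; for each d the weights over tasks sum to 1.
#'
#' @inheritParams update_public_centroids
#' @param public_centroids the shared public centroids (length D).
#' @param lambda balance parameter (>= 0).
#' @param gamma entropy coefficient (> 0); large gamma flattens the weights
#'   toward 1/T, small gamma sharpens them toward one-hot.
#' @return D x T weight matrix with unit row sums and entries in (0, 1].
#' @export
update_weights <- function(centroid_list, pub_membership_list,
                           public_centroids, m = 2, lambda, gamma) {
  stopifnot(gamma > 0, lambda >= 0)
  z <- as.numeric(public_centroids)
  D <- length(z)
  T_ <- length(centroid_list)
  disp <- matrix(0, D, T_)
  for (t in seq_len(T_)) {
    d2 <- sq_dist(z, centroid_list[[t]])            # C_t x D
    disp[, t] <- colSums(pub_membership_list[[t]]^m * d2)
  }
  e <- -lambda * disp / gamma
  e <- e - apply(e, 1L, max)                        # shift-invariant softmax
  w <- exp(e)
  w / rowSums(w)
}

#' Fit weighted multitask fuzzy C-means
#'
#' Jointly segments several related grayscale images (tasks).  Each task
#' keeps its own fuzzy C-means fit (private memberships U and centroids V)
#' while all tasks share public centroids Z that carry the cross-task common
#' information; public memberships P assign each task's private centroids to
#' the public ones, and an entropy-regularized task weight matrix W lets
#' cleaner tasks contribute more to each public centroid.  The objective
#' ([wmt_objective()]) is minimized by block-coordinate descent with exact
#' closed-form updates applied in the order U, P, V, Z, W each sweep, which
#' guarantees a non-increasing objective.
#'
#' With `lambda = 0` the objective decouples and every task's trajectory
#' equals a standalone [fcm()] fit started from the same initialization
#' (task t is initialized under seed `seed + t - 1`).
#'
#' Intensities are rescaled internally to \[0, 1\] (division by the pooled
#' maximum absolute intensity) and all centroids are rescaled back before
#' they are returned.  The coupling strength `lambda` and entropy
#' coefficient `gamma` are calibrated for this unit scale: the weight
#' softmax exponent `-lambda * dispersion / gamma` must stay of order one
#' for the entropy regularizer to bite, which it cannot on arbitrary
#' scanner units.  Classical fuzzy C-means is exactly scale-equivariant, so
#' this changes nothing for `lambda = 0`; `normalize = FALSE` disables it.
#'
#' @param tasks list of tasks: [task_data] objects, numeric vectors,
#'   matrices (images), or [phantom] objects.
#' @param centers per-task cluster counts C_t (scalar recycled to all
#'   tasks); each must satisfy 1 < C_t < N_t.
#' @param public_centers number D of public centroids; defaults to
#'   `max(centers)` (4 clusters for background/CSF/GM/WM segmentation).
#' @param lambda balance parameter (>= 0) for the public coupling term;
#'   default 60, the midpoint of the conventional search grid
#'   \{20, 40, ..., 120\}.
#' @param gamma entropy coefficient (> 0) for the task weights; default 0.6,
#'   the midpoint of the grid \{0.2, 0.4, ..., 1.2\}.
#' @param m fuzzifier (> 1).
#' @param eps convergence tolerance on the absolute change of the full
#'   objective between sweeps.
#' @param max_iter maximum number of sweeps.
#' @param seed integer master seed; task t's centroids are initialized under
#'   `seed + t - 1`.
#' @param normalize rescale intensities to \[0, 1\] internally (default
#'   `TRUE`; see Details).
#' @return An object of class `wmt_fcm`: a list with per-task fits in
#'   `$tasks` (each with `centroids`, `memberships`, `labels`, `shape`),
#'   the shared state in `$public` (`Z`, `P`, `W`), `objective_trace`,
#'   `objective_terms`, `n_iter`, `converged`, `config`, and the call.
#'   Methods: [print()], [summary()], [coef()], [predict()], [plot()].
#' @examples
#' g <- generate_task_group(list(c(1, 0), c(3, 0), c(5, 0)),
#'                          shape = c(48, 48), seed = 7)
#' fit <- wmt_fcm(g, centers = 4, seed = 7)
#' round(sort(coef(fit)), 1)   # public centroids near 0, 60, 120, 180
#' @export
wmt_fcm <- function(tasks, centers, public_centers = NULL, lambda = 60,
                    gamma = 0.6, m = 2, eps = 1e-4, max_iter = 100L,
                    seed = NULL, normalize = TRUE) {
  tasks <- lapply(tasks, task_data)
  scale <- if (normalize) {
    s <- max(abs(unlist(lapply(tasks, `[[`, "pixels"))))
    if (s > 0) s else 1
  } else 1
  if (scale != 1)
    tasks <- lapply(tasks, function(td) {
      td$pixels <- td$pixels / scale
      td
    })
  T_ <- length(tasks)
  if (T_ < 1L) stop("wmt_fcm: need at least one task", call. = FALSE)
  stopifnot(m > 1, lambda >= 0, gamma > 0, eps > 0, max_iter >= 1L)
  Ct <- as.integer(rep_len(centers, T_))
  for (t in seq_len(T_)) {
    if (Ct[t] < 1L || Ct[t] >= length(tasks[[t]]$pixels))
      stop("wmt_fcm: cluster count of task ", t,
           " must satisfy 1 <= C_t < N_t", call. = FALSE)
  }
  D <- if (is.null(public_centers)) max(Ct) else as.integer(public_centers)
  stopifnot(D >= 1L)

  # initialization: private centroids are random distinct pixels per task
  # (the random element whose influence the coupling is meant to damp); Z
  # starts at D evenly spaced quantiles of the pooled intensities — a
  # deterministic, data-driven start that keeps the small public clustering
  # problem (T * C_t points only) away from degenerate configurations;
  # W uniform; P by one public-membership update
  V <- vector("list", T_)
  for (t in seq_len(T_)) {
    xs <- tasks[[t]]$pixels
    V[[t]] <- with_seed(if (is.null(seed)) NULL else seed + t - 1L,
                        xs[sample.int(length(xs), Ct[t])])
  }
  Z <- as.numeric(stats::quantile(unlist(lapply(tasks, `[[`, "pixels")),
                                  probs = (2 * seq_len(D) - 1) / (2 * D),
                                  names = FALSE))
  W <- matrix(1 / T_, nrow = D, ncol = T_)
  P <- lapply(seq_len(T_), function(t)
    update_public_membership(V[[t]], Z, W[, t], m))
  U <- vector("list", T_)

  trace <- numeric(0)
  converged <- FALSE
  for (k in seq_len(max_iter)) {
    for (t in seq_len(T_))
      U[[t]] <- update_private_membership(tasks[[t]]$pixels, V[[t]], m)
    for (t in seq_len(T_))
      P[[t]] <- update_public_membership(V[[t]], Z, W[, t], m)
    for (t in seq_len(T_))
      V[[t]] <- update_private_centroids(tasks[[t]]$pixels, U[[t]], P[[t]],
                                         W[, t], Z, m, lambda,
                                         centroids = V[[t]])
    Z <- update_public_centroids(V, P, W, m, public_centroids = Z)
    W <- update_weights(V, P, Z, m, lambda, gamma)
    trace[k] <- wmt_objective(tasks,
                              list(U = U, V = V, P = P, Z = Z, W = W),
                              m = m, lambda = lambda, gamma = gamma,
                              check = FALSE)
    if (k > 1L && abs(trace[k] - trace[k - 1L]) < eps) {
      converged <- TRUE
      break
    }
  }

  fit_tasks <- lapply(seq_len(T_), function(t) {
    list(centroids = V[[t]] * scale, memberships = U[[t]],
         labels = hard_labels(U[[t]]),
         shape = tasks[[t]]$shape, task_id = tasks[[t]]$task_id)
  })
  names(fit_tasks) <- make.unique(vapply(tasks, `[[`, character(1L),
                                         "task_id"))
  J <- wmt_objective(tasks, list(U = U, V = V, P = P, Z = Z, W = W),
                     m = m, lambda = lambda, gamma = gamma, check = FALSE)

  structure(list(
    tasks = fit_tasks,
    public = list(Z = Z * scale, P = P, W = W),
    objective_trace = trace,
    objective_terms = attr(J, "terms"),
    n_iter = length(trace),
    converged = converged,
    config = list(n_clusters = Ct, public_clusters = D, lambda = lambda,
                  gamma = gamma, m = m, eps = eps,
                  max_iter = as.integer(max_iter), seed = seed,
                  normalize = normalize, scale = scale),
    call = match.call()
  ), class = "wmt_fcm")
}

# validate a multitask state's simplex constraints (tolerance 1e-6)
check_state <- function(state, T_, tol = 1e-6) {
  for (t in seq_len(T_)) {
    if (max(abs(colSums(state$U[[t]]) - 1)) > tol)
      stop("invalid state: private membership columns of task ", t,
           " do not sum to 1", call. = FALSE)
    if (max(abs(rowSums(state$P[[t]]) - 1)) > tol)
      stop("invalid state: public membership rows of task ", t,
           " do not sum to 1", call. = FALSE)
  }
  if (max(abs(rowSums(state$W) - 1)) > tol)
    stop("invalid state: task weights do not sum to 1 over tasks",
         call. = FALSE)
  invisible(TRUE)
}
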