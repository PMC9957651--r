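# Independent oracles, written as naive loops/enumerations so they share no
# code path with the package internals they check.

# triple-loop evaluation of the fuzzy C-means objective
oracle_fcm_objective <- function(x, U, v, m) {
  s <- 0
  for (i in seq_along(x))
    for (j in seq_along(v))
      s <- s + U[j, i]^m * (x[i] - v[j])^2
  s
}

# triple-loop evaluation of the full multitask objective
oracle_wmt_objective <- function(xs, U, V, P, Z, W, m, lambda, gamma) {
  s1 <- 0
  for (t in seq_along(xs))
    for (i in seq_along(xs[[t]]))
      for (j in seq_along(V[[t]]))
        s1 <- s1 + U[[t]][j, i]^m * (xs[[t]][i] - V[[t]][j])^2
  s2 <- 0
  for (t in seq_along(xs))
    for (d in seq_along(Z))
      for (j in seq_along(V[[t]]))
        s2 <- s2 + W[d, t] * P[[t]][j, d]^m * (V[[t]][j] - Z[d])^2
  s3 <- 0
  for (t in seq_along(xs))
    for (d in seq_along(Z))
      s3 <- s3 + W[d, t] * log(W[d, t])
  s1 + lambda * s2 + gamma * s3
}

# scalar grid minimizer over [lo, hi] at the given resolution
oracle_grid_min <- function(f, lo, hi, res = 1e-3) {
  grid <- seq(lo, hi, by = res)
  vals <- vapply(grid, f, numeric(1))
  list(x = grid[which.min(vals)], value = min(vals))
}

# simplex grid for one free coordinate (2-simplex): returns matrix of (a, 1-a)
oracle_simplex_grid <- function(res = 1e-3) {
  a <- seq(0, 1, by = res)
  cbind(a, 1 - a)
}

# counting-based Dice for one class
oracle_dice <- function(pred, truth, cl) {
  inter <- 0; np <- 0; nt <- 0
  for (i in seq_along(pred)) {
    p <- pred[i] == cl; t <- truth[i] == cl
    if (p && t) inter <- inter + 1
    if (p) np <- np + 1
    if (t) nt <- nt + 1
  }
  if (np + nt == 0) return(1)
  2 * inter / (np + nt)
}

oracle_dice_average <- function(pred, truth) {
  inter <- 0; size <- 0
  for (cl in 1:3) {
    for (i in seq_along(pred)) {
      p <- pred[i] == cl; t <- truth[i] == cl
      if (p && t) inter <- inter + 1
      if (p) size <- size + 1
      if (t) size <- size + 1
    }
  }
  if (size == 0) return(1)
  2 * inter / size
}

oracle_sa <- function(pred, truth) {
  ok <- 0
  for (i in seq_along(pred)) if (pred[i] == truth[i]) ok <- ok + 1
  ok / length(pred)
}

# recursive depth-first enumeration of all one-to-one cluster->class
# assignments, keeping the best total overlap (strict improvement)
oracle_best_assignment <- function(tab) {
  n <- nrow(tab)
  best <- list(score = -Inf, a = NULL)
  recurse <- function(row, used, a, score) {
    if (row > n) {
      if (score > best$score) best <<- list(score = score, a = a)
      return(invisible())
    }
    for (cl in seq_len(n)) {
      if (!used[cl])
        recurse(row + 1L, `[<-`(used, cl, TRUE), c(a, cl - 1L),
                score + tab[row, cl])
    }
  }
  recurse(1L, logical(n), integer(0), 0)
  best
}

# small reproducible multitask instance for solver-level tests
make_tiny_instance <- function(seed = 1, T_ = 2, N = 6, C = 2, D = 2) {
  set.seed(seed)
  xs <- lapply(seq_len(T_), function(t) runif(N))
  V <- lapply(seq_len(T_), function(t) runif(C))
  Z <- runif(D)
  W <- matrix(runif(D * T_), D, T_)
  W <- W / rowSums(W)
  U <- lapply(seq_len(T_), function(t) {
    u <- matrix(runif(C * N), C, N)
    sweep(u, 2, colSums(u), "/")
  })
  P <- lapply(seq_len(T_), function(t) {
    p <- matrix(runif(C * D), C, D)
    sweep(p, 1, rowSums(p), "/")
  })
  list(xs = xs, U = U, V = V, P = P, Z = Z, W = W)
}

# relative monotone-descent check on an objective trace
is_nonincreasing <- function(trace, rel_tol = 1e-8) {
  if (length(trace) < 2L) return(TRUE)
  d <- diff(trace)
  all(d <= rel_tol * pmax(1, abs(trace[-length(trace)])))
}
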