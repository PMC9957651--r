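test_that("multitask objective matches a brute-force triple-loop oracle", {
  inst <- make_tiny_instance(seed = 3, T_ = 2, N = 4, C = 2, D = 2)
  got <- wmt_objective(inst$xs, inst[c("U", "V", "P", "Z", "W")],
                       m = 2, lambda = 1.7, gamma = 0.4)
  want <- oracle_wmt_objective(inst$xs, inst$U, inst$V, inst$P, inst$Z,
                               inst$W, 2, 1.7, 0.4)
  expect_equal(as.numeric(got), want)
  # term decomposition is retrievable and consistent
  expect_equal(sum(attr(got, "terms")), as.numeric(got))
  # entropy term is never positive
  expect_lte(attr(got, "terms")[["entropy"]], 0)
})

test_that("objective with lambda = 0 reduces to the sum of per-task fits", {
  inst <- make_tiny_instance(seed = 5, T_ = 3, N = 5, C = 2, D = 2)
  got <- wmt_objective(inst$xs, inst[c("U", "V", "P", "Z", "W")],
                       m = 2, lambda = 0, gamma = 1)
  per_task <- sum(vapply(1:3, function(t)
    fcm_objective(inst$xs[[t]], inst$U[[t]], inst$V[[t]], 2), numeric(1)))
  expect_equal(attr(got, "terms")[["private"]], per_task)
  expect_equal(attr(got, "terms")[["public"]], 0)
})

test_that("single task with unit weight has zero entropy", {
  inst <- make_tiny_instance(seed = 2, T_ = 1, N = 4, C = 2, D = 2)
  inst$W <- matrix(1, 2, 1)
  got <- wmt_objective(inst$xs, inst[c("U", "V", "P", "Z", "W")],
                       m = 2, lambda = 1, gamma = 5)
  expect_equal(attr(got, "terms")[["entropy"]], 0)
})

test_that("objective rejects states violating the simplex constraints", {
  inst <- make_tiny_instance(seed = 1)
  inst$U[[1]][1, 1] <- inst$U[[1]][1, 1] + 0.01
  expect_error(wmt_objective(inst$xs, inst[c("U", "V", "P", "Z", "W")],
                             m = 2, lambda = 1, gamma = 1),
               "invalid state")
})

test_that("public membership update follows the weighted inverse-power form", {
  # uniform weights reduce to the classical membership form: 0.9 / 0.1
  p <- update_public_membership(0.25, c(0, 1), c(0.5, 0.5), m = 2)
  expect_equal(p[1, ], c(0.9, 0.1))
  # single public centroid: whole simplex on it
  expect_equal(update_public_membership(c(0.2, 0.7), 0.4, 1, 2),
               matrix(1, 2, 1))
  # equal distances, weights (0.9, 0.1): low-weight centroid favoured 9:1
  p <- update_public_membership(0.5, c(0, 1), c(0.9, 0.1), m = 2)
  expect_equal(p[1, ], c(0.1, 0.9))
  # private centroid coinciding with a public centroid: crisp limit
  p <- update_public_membership(c(0, 1), c(0, 1), c(0.5, 0.5), 2)
  expect_equal(p, matrix(c(1, 0, 0, 1), 2, 2))
  # rows always on the simplex
  inst <- make_tiny_instance(seed = 7, C = 3, D = 4)
  p <- update_public_membership(inst$V[[1]], runif(4), runif(4, 0.1, 1), 2.5)
  expect_lt(max(abs(rowSums(p) - 1)), 1e-12)
})

test_that("private centroid update blends pixels and public centroids", {
  x <- c(0, 0.25, 1)
  U <- fcm_membership_update(x, c(0, 1), 2)
  P <- matrix(c(1, 0, 0, 1), 2, 2)
  w <- c(0.5, 0.5)
  # lambda = 0 reduces exactly to the classical centroid update
  expect_equal(update_private_centroids(x, U, P, w, c(0.1, 0.9), 2, 0),
               fcm_centroid_update(x, U, 2))
  # huge lambda with a single public centroid pins the centroid there
  P1 <- matrix(1, 2, 1)
  v <- update_private_centroids(x, U, P1, 1, 7, 2, 1e9)
  expect_equal(v, c(7, 7), tolerance = 1e-3)
  # brute-force ratio-of-sums
  inst <- make_tiny_instance(seed = 11, T_ = 1, N = 6, C = 2, D = 2)
  v <- update_private_centroids(inst$xs[[1]], inst$U[[1]], inst$P[[1]],
                                inst$W[, 1], inst$Z, 2, 3.3)
  for (j in 1:2) {
    num <- sum(inst$U[[1]][j, ]^2 * inst$xs[[1]]) +
      3.3 * sum(inst$W[, 1] * inst$P[[1]][j, ]^2 * inst$Z)
    den <- sum(inst$U[[1]][j, ]^2) +
      3.3 * sum(inst$W[, 1] * inst$P[[1]][j, ]^2)
    expect_equal(v[j], num / den)
  }
})

test_that("public centroid update pools private centroids correctly", {
  # one task, one public centroid, crisp p: plain mean of private centroids
  z <- update_public_centroids(list(c(0.2, 0.8)), list(matrix(1, 2, 1)),
                               matrix(1, 1, 1), 2)
  expect_equal(z, 0.5)
  # identical private centroids across tasks: z independent of the weights
  V <- list(c(0.1, 0.9), c(0.1, 0.9))
  P <- list(matrix(c(1, 0, 0, 1), 2, 2), matrix(c(1, 0, 0, 1), 2, 2))
  z1 <- update_public_centroids(V, P, matrix(c(0.9, 0.2, 0.1, 0.8), 2, 2), 2)
  z2 <- update_public_centroids(V, P, matrix(0.5, 2, 2), 2)
  expect_equal(z1, z2)
  # asymmetric instance matches the weighted-mean oracle
  inst <- make_tiny_instance(seed = 13, T_ = 2, C = 2, D = 2)
  z <- update_public_centroids(inst$V, inst$P, inst$W, 2)
  for (d in 1:2) {
    num <- den <- 0
    for (t in 1:2) for (j in 1:2) {
      num <- num + inst$W[d, t] * inst$P[[t]][j, d]^2 * inst$V[[t]][j]
      den <- den + inst$W[d, t] * inst$P[[t]][j, d]^2
    }
    expect_equal(z[d], num / den)
  }
  # containment in the private-centroid range
  expect_true(all(z >= min(unlist(inst$V)) & z <= max(unlist(inst$V))))
})

test_that("weight update is the softmax of negative dispersions", {
  # single task: all weights one
  W <- update_weights(list(c(0.3, 0.6)), list(matrix(0.5, 2, 2)),
                      c(0.2, 0.7), 2, lambda = 2, gamma = 0.5)
  expect_equal(W, matrix(1, 2, 1))
  # identical tasks: uniform weights
  V <- list(c(0.1, 0.9), c(0.1, 0.9))
  P <- list(matrix(0.5, 2, 2), matrix(0.5, 2, 2))
  W <- update_weights(V, P, c(0.2, 0.8), 2, lambda = 3, gamma = 0.7)
  expect_true(all(abs(W - 0.5) < 1e-12))
  # softmax hand example: exponents (0, -log 9) give weights (0.9, 0.1)
  # task 1 sits exactly on z (dispersion 0); task 2 at distance sqrt(log 9)
  V <- list(1, 1 + sqrt(log(9)))
  P <- list(matrix(1, 1, 1), matrix(1, 1, 1))
  W <- update_weights(V, P, 1, 2, lambda = 1, gamma = 1)
  expect_equal(W[1, ], c(0.9, 0.1), tolerance = 1e-12)
  # no overflow for extreme dispersions
  W <- update_weights(list(0, 1e6), list(matrix(1, 1, 1), matrix(1, 1, 1)),
                      0, 2, lambda = 100, gamma = 1e-6)
  expect_equal(W[1, ], c(1, 0))
})

test_that("weight columns flatten as gamma grows and sharpen as it shrinks", {
  inst <- make_tiny_instance(seed = 17, T_ = 3, C = 2, D = 2)
  # entropy limit: gamma -> Inf flattens to 1/T
  W <- update_weights(inst$V, inst$P, inst$Z, 2, lambda = 50, gamma = 1e9)
  expect_lt(max(abs(W - 1 / 3)), 1e-6)
  # sharpening limit: gamma -> 0+ one-hot on the smallest dispersion
  disp <- sapply(1:3, function(t)
    sapply(seq_along(inst$Z), function(d)
      sum(inst$P[[t]][, d]^2 * (inst$V[[t]] - inst$Z[d])^2)))
  W <- update_weights(inst$V, inst$P, inst$Z, 2, lambda = 50, gamma = 1e-9)
  for (d in seq_along(inst$Z)) {
    onehot <- as.numeric(seq_len(3) == which.min(disp[d, ]))
    expect_equal(W[d, ], onehot)
  }
})

test_that("solver satisfies simplex constraints and monotone descent", {
  g <- generate_task_group(list(c(3, 0), c(5, 20)), shape = c(32, 32),
                           seed = 31)
  fit <- suppressWarnings(wmt_fcm(g, centers = 4, seed = 31, max_iter = 25))
  for (t in 1:2) {
    expect_lt(max(abs(colSums(fit$tasks[[t]]$memberships) - 1)), 1e-9)
    expect_lt(max(abs(rowSums(fit$public$P[[t]]) - 1)), 1e-9)
  }
  expect_lt(max(abs(rowSums(fit$public$W) - 1)), 1e-9)
  expect_true(all(fit$public$W >= 0 & fit$public$W <= 1))
  expect_true(is_nonincreasing(fit$objective_trace))
})

test_that("with lambda = 0 the solver reproduces standalone FCM per task", {
  g <- generate_task_group(list(c(3, 0), c(5, 0)), shape = c(32, 32),
                           seed = 41)
  # eps tiny and a fixed sweep count so both solvers run the same number of
  # updates (their objective traces live on different scales)
  fit <- wmt_fcm(g, centers = 3, lambda = 0, seed = 41, max_iter = 12,
                 eps = 1e-15)
  for (t in 1:2) {
    ref <- fcm(g[[t]]$image, centers = 3, seed = 41 + t - 1, max_iter = 12,
               eps = 1e-15)
    expect_equal(fit$tasks[[t]]$centroids, ref$centroids, tolerance = 1e-10)
    expect_equal(fit$tasks[[t]]$memberships, ref$memberships,
                 tolerance = 1e-10)
    expect_identical(fit$tasks[[t]]$labels, ref$labels)
  }
})

test_that("solver recovers shared class means across noisy tasks", {
  g <- generate_task_group(list(c(1, 0), c(3, 0), c(5, 0)),
                           shape = c(48, 48), seed = 7)
  fit <- wmt_fcm(g, centers = 4, seed = 8)
  expect_equal(sort(coef(fit)), c(0, 60, 120, 180), tolerance = 5)
  expect_identical(fit$config$public_clusters, 4L)
})

test_that("solver is reproducible per seed and validates input", {
  g <- generate_task_group(list(c(3, 0), c(3, 20)), shape = c(32, 32),
                           seed = 51)
  f1 <- wmt_fcm(g, centers = 4, seed = 5, max_iter = 15)
  f2 <- wmt_fcm(g, centers = 4, seed = 5, max_iter = 15)
  expect_identical(lapply(f1$tasks, `[[`, "labels"),
                   lapply(f2$tasks, `[[`, "labels"))
  expect_error(wmt_fcm(list(1:3), centers = 5), "C_t < N_t")
  expect_error(wmt_fcm(g, centers = 4, gamma = 0), "gamma > 0")
})

test_that("each closed-form block update beats a dense grid search", {
  for (s in 1:3) {
    inst <- make_tiny_instance(seed = s, T_ = 2, N = 8, C = 2, D = 2)
    m <- 2; lambda <- 1.3; gamma <- 0.6
    obj <- function(st) oracle_wmt_objective(inst$xs, st$U, st$V, st$P,
                                             st$Z, st$W, m, lambda, gamma)
    # U block (task 1, per-pixel simplex grid)
    st <- inst
    st$U[[1]] <- update_private_membership(inst$xs[[1]], inst$V[[1]], m)
    for (i in sample(seq_along(inst$xs[[1]]), 3)) {
      grid <- oracle_simplex_grid(1e-3)
      vals <- grid[, 1]^2 * (inst$xs[[1]][i] - inst$V[[1]][1])^2 +
              grid[, 2]^2 * (inst$xs[[1]][i] - inst$V[[1]][2])^2
      expect_lte(sum(st$U[[1]][, i]^2 * (inst$xs[[1]][i] - inst$V[[1]])^2),
                 min(vals) + 1e-6)
    }
    expect_lte(obj(st), obj(inst) + 1e-9)
    # P block (task 1, per-row simplex grid)
    st <- inst
    st$P[[1]] <- update_public_membership(inst$V[[1]], inst$Z, inst$W[, 1], m)
    for (j in 1:2) {
      grid <- oracle_simplex_grid(1e-3)
      vals <- inst$W[1, 1] * grid[, 1]^2 * (inst$V[[1]][j] - inst$Z[1])^2 +
              inst$W[2, 1] * grid[, 2]^2 * (inst$V[[1]][j] - inst$Z[2])^2
      expect_lte(sum(inst$W[, 1] * st$P[[1]][j, ]^2 *
                       (inst$V[[1]][j] - inst$Z)^2),
                 min(vals) + 1e-6)
    }
    expect_lte(obj(st), obj(inst) + 1e-9)
    # V block (scalar grid per private centroid)
    st <- inst
    st$V[[1]] <- update_private_centroids(inst$xs[[1]], inst$U[[1]],
                                          inst$P[[1]], inst$W[, 1], inst$Z,
                                          m, lambda)
    for (j in 1:2) {
      fj <- function(vj) {
        sum(inst$U[[1]][j, ]^2 * (inst$xs[[1]] - vj)^2) +
          lambda * sum(inst$W[, 1] * inst$P[[1]][j, ]^2 * (vj - inst$Z)^2)
      }
      g <- oracle_grid_min(fj, -0.5, 1.5)
      expect_lte(fj(st$V[[1]][j]), g$value + 1e-6)
    }
    expect_lte(obj(st), obj(inst) + 1e-9)
    # Z block (scalar grid per public centroid)
    st <- inst
    st$Z <- update_public_centroids(inst$V, inst$P, inst$W, m)
    for (d in 1:2) {
      fd <- function(zd) sum(vapply(1:2, function(t)
        sum(inst$W[d, t] * inst$P[[t]][, d]^2 * (inst$V[[t]] - zd)^2),
        numeric(1)))
      g <- oracle_grid_min(fd, -0.5, 1.5)
      expect_lte(fd(st$Z[d]), g$value + 1e-6)
    }
    expect_lte(obj(st), obj(inst) + 1e-9)
    # W block (per-public-cluster simplex grid incl. entropy term)
    st <- inst
    st$W <- update_weights(inst$V, inst$P, inst$Z, m, lambda, gamma)
    disp <- sapply(1:2, function(t) sapply(1:2, function(d)
      sum(inst$P[[t]][, d]^2 * (inst$V[[t]] - inst$Z[d])^2)))
    for (d in 1:2) {
      grid <- oracle_simplex_grid(1e-3)
      grid <- grid[grid[, 1] > 0 & grid[, 2] > 0, ]
      vals <- lambda * (grid[, 1] * disp[d, 1] + grid[, 2] * disp[d, 2]) +
        gamma * (grid[, 1] * log(grid[, 1]) + grid[, 2] * log(grid[, 2]))
      mine <- lambda * sum(st$W[d, ] * disp[d, ]) +
        gamma * sum(st$W[d, ] * log(st$W[d, ]))
      expect_lte(mine, min(vals) + 1e-6)
    }
    expect_lte(obj(st), obj(inst) + 1e-9)
  }
})

test_that("monotone descent holds on random small instances", {
  for (s in 1:20) {
    set.seed(s)
    T_ <- sample(1:3, 1)
    xs <- lapply(seq_len(T_), function(t) runif(sample(5:12, 1)))
    fit <- suppressWarnings(
      wmt_fcm(xs, centers = 2, public_centers = 2,
              lambda = runif(1, 0, 5), gamma = runif(1, 0.1, 2),
              seed = s, max_iter = 20, normalize = FALSE))
    expect_true(is_nonincreasing(fit$objective_trace))
  }
})

test_that("checkpoints round-trip the fitted state", {
  g <- generate_task_group(list(c(3, 0), c(5, 0)), shape = c(32, 32),
                           seed = 61)
  fit <- wmt_fcm(g, centers = 4, seed = 6, max_iter = 10)
  path <- tempfile(fileext = ".json")
  write_checkpoint(fit, path)
  ck <- read_checkpoint(path)
  expect_equal(ck$model, "wmt_fcm")
  expect_equal(ck$public_centroids, fit$public$Z)
  expect_equal(ck$config$lambda, fit$config$lambda)
  expect_equal(ck$config$seed, 6)
})
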