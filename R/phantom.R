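#' Generate a synthetic brain-like MRI phantom
#'
#' Builds a 2-D T1-weighted-style slice in the spirit of the BrainWeb
#' simulated MRI database: four classes (background, CSF, GM, WM) laid out
#' as nested concentric regions (background ring, CSF band, GM band, WM
#' core), corrupted first by a smooth multiplicative intensity-nonuniformity
#' (INU) field and then by additive noise, with the ground-truth label map
#' returned alongside.  Both corruption levels follow the BrainWeb
#' percentage conventions:
#' \itemize{
#'   \item noise: zero-mean Gaussian with standard deviation
#'     `noise_pct/100 * max(class_means)` (relative to the brightest
#'     tissue); a Rician option is available since magnitude MRI noise is
#'     Rician,
#'   \item INU: a smooth low-order random multiplicative field rescaled to
#'     span exactly `[1 - inu_pct/200, 1 + inu_pct/200]` (20\% INU means a
#'     field in \[0.9, 1.1\]).
#' }
#' Intensities are clipped at 0.  With both levels at 0 the image is
#' piecewise constant at `class_means` exactly.
#'
#' @param shape image dimensions (rows, cols), each >= 32.
#' @param class_means strictly increasing intensity means for
#'   background < CSF < GM < WM (T1 ordering).
#' @param noise_pct noise level in percent (>= 0).
#' @param inu_pct INU level in percent (>= 0).
#' @param seed integer seed; the same seed reproduces the phantom
#'   bit-identically.
#' @param geometry either a named list of region radii as fractions of the
#'   half-image (`brain`, `csf`, `gm`, defaults 0.92/0.76/0.55: outside
#'   `brain` is background, then a CSF ring, a GM ring, and the WM core), or
#'   a ready-made integer label map of dimension `shape`.  The geometry is
#'   deterministic: distinct seeds change only the noise and INU
#'   realizations, never the truth.
#' @param noise_model `"gaussian"` (default) or `"rician"`.
#' @return An object of class `phantom`: list with `image` (matrix),
#'   `truth` (integer matrix, labels 0:3), and `params` (all generating
#'   parameters).
#' @examples
#' ph <- generate_phantom(shape = c(64, 64), noise_pct = 3, inu_pct = 20,
#'                        seed = 1)
#' table(ph$truth)
#' @export
generate_phantom <- function(shape = c(128, 128),
                             class_means = c(0, 60, 120, 180),
                             noise_pct = 0, inu_pct = 0, seed = NULL,
                             geometry = NULL,
                             noise_model = c("gaussian", "rician")) {
  noise_model <- match.arg(noise_model)
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 32L))
    stop("generate_phantom: shape must be 2-D with sides >= 32", call. = FALSE)
  if (any(diff(class_means) <= 0))
    stop("generate_phantom: class means must be strictly increasing",
         call. = FALSE)
  if (noise_pct < 0 || inu_pct < 0)
    stop("generate_phantom: noise and INU percentages must be >= 0",
         call. = FALSE)

  truth <- phantom_truth(shape, geometry)
  n_cls <- length(class_means)
  if (max(truth) >= n_cls)
    stop("generate_phantom: label map needs more class means", call. = FALSE)
  clean <- matrix(class_means[truth + 1L], shape[1], shape[2])

  img <- with_seed(seed, {
    out <- clean
    if (inu_pct > 0) out <- out * inu_field(shape, inu_pct)
    if (noise_pct > 0) {
      sigma <- noise_pct / 100 * max(class_means)
      out <- if (noise_model == "gaussian") {
        out + matrix(stats::rnorm(prod(shape), 0, sigma), shape[1], shape[2])
      } else {
        sqrt((out + matrix(stats::rnorm(prod(shape), 0, sigma),
                           shape[1], shape[2]))^2 +
               matrix(stats::rnorm(prod(shape), 0, sigma),
                      shape[1], shape[2])^2)
      }
    }
    pmax(out, 0)
  })

  structure(list(
    image = img,
    truth = truth,
    params = list(shape = shape, class_means = class_means,
                  noise_pct = noise_pct, inu_pct = inu_pct, seed = seed,
                  geometry = if (is.matrix(geometry)) "supplied label map"
                             else geometry_radii(geometry),
                  noise_model = noise_model)
  ), class = "phantom")
}

#' Generate a group of related phantom tasks
#'
#' Creates one phantom per (noise %, INU %) setting, all sharing the same
#' class means and slice geometry — the common information a multitask
#' segmentation can exploit — while the noise and INU realizations differ
#' across tasks.
#'
#' @param settings list of `c(noise_pct, inu_pct)` pairs (or a 2-column
#'   matrix), one per task; see [brainweb_settings()] for the conventional
#'   nine.
#' @param class_means shared class means, as in [generate_phantom()].
#' @param seeds integer seeds, one per task; defaults to `seed + 0:(T-1)`.
#' @param seed master seed used when `seeds` is not given.
#' @param shape,geometry,noise_model passed to [generate_phantom()].
#' @return list of `phantom` objects, task ids `"task1"`, `"task2"`, ...
#' @export
generate_task_group <- function(settings, class_means = c(0, 60, 120, 180),
                                seeds = NULL, seed = 1L,
                                shape = c(128, 128), geometry = NULL,
                                noise_model = "gaussian") {
  if (is.matrix(settings))
    settings <- lapply(seq_len(nrow(settings)), function(i) settings[i, ])
  n <- length(settings)
  if (n < 1L)
    stop("generate_task_group: need at least one (noise, INU) setting",
         call. = FALSE)
  if (is.null(seeds)) seeds <- seed + seq_len(n) - 1L
  if (length(seeds) != n)
    stop("generate_task_group: need one seed per task", call. = FALSE)
  out <- lapply(seq_len(n), function(t) {
    s <- as.numeric(settings[[t]])
    ph <- generate_phantom(shape = shape, class_means = class_means,
                           noise_pct = s[1], inu_pct = s[2],
                           seed = seeds[t], geometry = geometry,
                           noise_model = noise_model)
    ph$params$task_id <- paste0("task", t)
    ph
  })
  names(out) <- paste0("task", seq_len(n))
  out
}

#' The nine conventional noise/INU settings
#'
#' The standard panel of simulated T1 images: nine combinations of noise
#' level (1–9\%) and intensity nonuniformity (0 or 20\%).
#'
#' @return data.frame with columns `image`, `noise_pct`, `inu_pct`.
#' @export
brainweb_settings <- function() {
  data.frame(image = 1:9,
             noise_pct = c(1, 5, 7, 1, 7, 9, 3, 3, 5),
             inu_pct = c(20, 20, 0, 0, 20, 20, 20, 0, 0))
}

#' @export
print.phantom <- function(x, ...) {
  p <- x$params
  cat("Synthetic MRI phantom ", p$shape[1], "x", p$shape[2],
      ", classes at {", paste(p$class_means, collapse = ", "), "}\n",
      "  noise ", p$noise_pct, "% (", p$noise_model, "), INU ", p$inu_pct,
      "%, seed ", if (is.null(p$seed)) "none" else p$seed, "\n", sep = "")
  tab <- table(factor(x$truth, levels = 0:(length(p$class_means) - 1L)))
  cat("  class pixel counts:", paste(tab, collapse = " / "), "\n")
  invisible(x)
}

#' @export
plot.phantom <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  img_show(x$image, main = "image", ...)
  img_show(x$truth, main = "truth", ...)
  invisible(x)
}

# nested elliptical geometry; deterministic in shape + radii
phantom_truth <- function(shape, geometry) {
  if (is.matrix(geometry)) {
    if (!all(dim(geometry) == shape))
      stop("generate_phantom: supplied label map does not match shape",
           call. = FALSE)
    return(matrix(as.integer(geometry), shape[1], shape[2]))
  }
  g <- geometry_radii(geometry)
  rows <- shape[1]; cols <- shape[2]
  ry <- (rows - 1) / 2; rx <- (cols - 1) / 2
  yy <- (seq_len(rows) - 1 - ry) / ry
  xx <- (seq_len(cols) - 1 - rx) / rx
  r <- sqrt(outer(yy^2, xx^2, "+"))
  truth <- matrix(0L, rows, cols)
  truth[r <= g["brain"]] <- 1L     # CSF ring
  truth[r <= g["csf"]] <- 2L       # GM ring
  truth[r <= g["gm"]] <- 3L        # WM core
  truth
}

geometry_radii <- function(geometry) {
  g <- c(brain = 0.92, csf = 0.76, gm = 0.55)
  if (!is.null(geometry)) g[names(geometry)] <- unlist(geometry)
  if (any(diff(g) >= 0))
    stop("generate_phantom: geometry radii must decrease brain > csf > gm",
         call. = FALSE)
  g
}

# Smooth multiplicative bias field: a low-order random surface (linear,
# bilinear, quadratic and half-cosine terms in coordinates scaled to [-1,1])
# rescaled linearly to span exactly [1 - s, 1 + s], s = inu_pct/200.
# Smoothness: the basis has O(1) gradients on the unit square, so after
# rescaling, neighbouring pixels differ by at most ~10 * 2s / min(shape).
inu_field <- function(shape, inu_pct) {
  rows <- shape[1]; cols <- shape[2]
  u <- seq(-1, 1, length.out = rows)
  v <- seq(-1, 1, length.out = cols)
  co <- stats::rnorm(6L)
  f <- co[1] * outer(u, rep(1, cols)) +
       co[2] * outer(rep(1, rows), v) +
       co[3] * outer(u, v) +
       co[4] * outer(u^2, rep(1, cols)) +
       co[5] * outer(rep(1, rows), v^2) +
       co[6] * outer(cos(pi * u / 2), cos(pi * v / 2))
  s <- inu_pct / 200
  rng <- range(f)
  if (rng[2] - rng[1] < .Machine$double.eps) return(matrix(1, rows, cols))
  (f - rng[1]) / (rng[2] - rng[1]) * 2 * s + (1 - s)
}

img_show <- function(m, main = "", ...) {
  graphics::image(t(m)[, nrow(m):1, drop = FALSE], axes = FALSE,
                  col = grDevices::gray.colors(256, start = 0, end = 1),
                  main = main, useRaster = TRUE, ...)
}
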