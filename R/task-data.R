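#' Construct a segmentation task from image intensities
#'
#' A task is one grayscale image to be segmented: its pixel intensities as a
#' flat numeric vector plus the original image dimensions, so label maps can
#' be folded back into image shape.  Matrices and arrays are flattened in
#' row-major order (last index fastest), which round-trips exactly with
#' [as_image()].
#'
#' @param x numeric vector of intensities, a matrix (2-D image), a 3-D array,
#'   or a [phantom] object (its noisy image is used).
#' @param shape integer vector of image dimensions; inferred from matrix or
#'   array input, optional for plain vectors.
#' @param task_id character label identifying the task.
#' @return An object of class `task_data` with fields `pixels`, `shape`,
#'   `task_id`.
#' @examples
#' td <- task_data(matrix(0:5, 2, 3), task_id = "toy")
#' all.equal(as_image(td), matrix(0:5, 2, 3))
#' @export
task_data <- function(x, shape = NULL, task_id = "task") {
  if (inherits(x, "task_data")) return(x)
  if (inherits(x, "phantom")) {
    if (missing(task_id) && !is.null(x$params$task_id))
      task_id <- x$params$task_id
    shape <- dim(x$image)
    x <- x$image
  }
  if (is.matrix(x) || is.array(x)) {
    shape <- dim(x)
    pixels <- flatten_rowmajor(x)
  } else {
    pixels <- as.numeric(x)
  }
  if (length(pixels) < 1L)
    stop("task_data: need at least one pixel", call. = FALSE)
  if (!all(is.finite(pixels)))
    stop("task_data: all intensities must be finite", call. = FALSE)
  if (!is.null(shape) && prod(shape) != length(pixels))
    stop("task_data: shape is inconsistent with the number of pixels",
         call. = FALSE)
  structure(list(pixels = pixels, shape = shape,
                 task_id = as.character(task_id)),
            class = "task_data")
}

#' Fold a flat pixel or label vector back into image shape
#'
#' @param x a `task_data` object, or a numeric vector together with `shape`.
#' @param shape target dimensions; taken from `x` when it is a `task_data`.
#' @return a matrix (2-D) or array (3-D); the vector itself if no shape is
#'   known.
#' @export
as_image <- function(x, shape = NULL) {
  if (inherits(x, "task_data")) {
    shape <- x$shape
    x <- x$pixels
  }
  if (is.null(shape)) return(x)
  unflatten_rowmajor(x, shape)
}

#' @export
print.task_data <- function(x, ...) {
  cat("Segmentation task '", x$task_id, "': ", length(x$pixels), " pixels",
      sep = "")
  if (!is.null(x$shape))
    cat(" (", paste(x$shape, collapse = " x "), ")", sep = "")
  cat("\n  intensity range [", format(min(x$pixels)), ", ",
      format(max(x$pixels)), "]\n", sep = "")
  invisible(x)
}

# row-major flatten: last index varies fastest
flatten_rowmajor <- function(a) {
  if (is.null(dim(a))) return(as.numeric(a))
  as.numeric(aperm(a, rev(seq_along(dim(a)))))
}

unflatten_rowmajor <- function(x, shape) {
  aperm(array(x, dim = rev(shape)), rev(seq_along(shape)))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# Deterministic per-trial seed derived from a master seed; trial k is
# reproducible in isolation.  Kept well below .Machine$integer.max.
trial_seed <- function(master, k) {
  as.integer((as.numeric(master) + 1009 * (k - 1)) %% 2147483647)
}
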