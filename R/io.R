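#' Read a grayscale image or volume as a segmentation task
#'
#' Supported formats: NIfTI (`.nii`, `.nii.gz`, via RNifti), PNG (8- or
#' 16-bit grayscale; intensities are returned on the integer scale of the
#' file's bit depth, e.g. 0–255 for 8-bit), and raw binary volumes
#' accompanied by a JSON sidecar `<path>.json` with fields `shape` (required),
#' `dtype` (`"uint8"`, `"int16"`, `"float32"`, `"float64"`; default
#' `"uint8"`), `order` (`"row"` or `"column"`-major; default `"row"`), and
#' `endian` (default `"little"`).  3-D volumes can be reduced to a 2-D slice
#' with `slice` (index along the third dimension, e.g. slice 90 of a
#' 181 x 217 x 181 volume gives 181 x 217 = 39277 pixels).
#'
#' @param path file to read.
#' @param format `"auto"` (by extension), `"nifti"`, `"png"`, or `"raw"`.
#' @param slice optional slice index along the third dimension.
#' @param task_id task label; defaults to the file name.
#' @return a [task_data] object.
#' @export
read_image <- function(path, format = c("auto", "nifti", "png", "raw"),
                       slice = NULL, task_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("read_image: file not found: ", path, call. = FALSE)
  if (format == "auto") format <- guess_format(path)
  a <- switch(format,
    nifti = {
      v <- RNifti::readNifti(path)
      array(as.numeric(v), dim = dim(v))
    },
    png = {
      im <- png::readPNG(path, info = TRUE)
      depth <- attr(im, "info")$bit.depth
      if (is.null(depth)) depth <- 8L
      if (length(dim(im)) == 3L) im <- im[, , 1L]   # first channel
      im * (2^depth - 1)
    },
    raw = read_raw_volume(path)
  )
  if (!is.null(slice)) {
    if (length(dim(a)) != 3L)
      stop("read_image: slice index given but ", path, " is not 3-D",
           call. = FALSE)
    if (slice < 1L || slice > dim(a)[3])
      stop("read_image: slice ", slice, " out of range for ", path,
           call. = FALSE)
    a <- a[, , slice]
  }
  task_data(a, task_id = if (is.null(task_id)) basename(path) else task_id)
}

#' Write an image, label map, or volume
#'
#' NIfTI output is lossless for floating-point intensities and is the
#' recommended interchange format; PNG output is 8-bit (values are clipped
#' to \[0, 255\] and rounded — exact for label maps and 8-bit images); raw
#' output writes the requested dtype plus the JSON sidecar that
#' [read_image()] understands.
#'
#' @param x matrix/array of intensities or labels, or a [task_data].
#' @param path destination file.
#' @param format `"auto"` (by extension), `"nifti"`, `"png"`, or `"raw"`.
#' @param dtype storage type for raw output.
#' @return `path`, invisibly.
#' @export
write_image <- function(x, path, format = c("auto", "nifti", "png", "raw"),
                        dtype = "float64") {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (inherits(x, "task_data")) x <- as_image(x)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  switch(format,
    nifti = RNifti::writeNifti(RNifti::asNifti(x * 1.0), path),
    png = png::writePNG(pmin(pmax(round(x), 0), 255) / 255, path),
    raw = write_raw_volume(x, path, dtype)
  )
  invisible(path)
}

guess_format <- function(path) {
  low <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", low)) "nifti"
  else if (grepl("\\.png$", low)) "png"
  else "raw"
}

raw_dtypes <- list(
  uint8   = list(what = "integer", size = 1L, signed = FALSE),
  int16   = list(what = "integer", size = 2L, signed = TRUE),
  float32 = list(what = "numeric", size = 4L, signed = TRUE),
  float64 = list(what = "numeric", size = 8L, signed = TRUE)
)

read_raw_volume <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("read_image: raw volume ", path, " needs a JSON sidecar ", sidecar,
         call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$shape))
    stop("read_image: sidecar ", sidecar, " lacks a shape field",
         call. = FALSE)
  shape <- as.integer(meta$shape)
  dtype <- if (is.null(meta$dtype)) "uint8" else meta$dtype
  ord <- if (is.null(meta$order)) "row" else meta$order
  endian <- if (is.null(meta$endian)) "little" else meta$endian
  spec <- raw_dtypes[[dtype]]
  if (is.null(spec))
    stop("read_image: unsupported dtype '", dtype, "' in ", sidecar,
         call. = FALSE)
  n <- prod(shape)
  vals <- readBin(path, what = spec$what, n = n, size = spec$size,
                  signed = spec$signed, endian = endian)
  if (length(vals) != n)
    stop("read_image: ", path, " holds ", length(vals),
         " values but the sidecar shape implies ", n, call. = FALSE)
  if (ord == "row") unflatten_rowmajor(as.numeric(vals), shape)
  else array(as.numeric(vals), dim = shape)
}

write_raw_volume <- function(x, path, dtype = "float64") {
  spec <- raw_dtypes[[dtype]]
  if (is.null(spec))
    stop("write_image: unsupported dtype '", dtype, "'", call. = FALSE)
  shape <- dim(x)
  vals <- flatten_rowmajor(x)
  if (spec$what == "integer") vals <- as.integer(round(vals))
  writeBin(vals, path, size = spec$size, endian = "little")
  jsonlite::write_json(list(shape = shape, dtype = dtype, order = "row",
                            endian = "little"),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Save a fitted model's state as a JSON checkpoint
#'
#' Stores centroids, public centroids, task weights, configuration, and the
#' seed — everything needed to reproduce or resume a fit — in plain JSON.
#'
#' @param fit an [fcm()] or [wmt_fcm()] fit.
#' @param path destination `.json` file.
#' @return `path`, invisibly.
#' @export
write_checkpoint <- function(fit, path) {
  ck <- if (inherits(fit, "wmt_fcm")) {
    list(model = "wmt_fcm",
         centroids = lapply(fit$tasks, `[[`, "centroids"),
         public_centroids = fit$public$Z,
         weights = fit$public$W,
         config = fit$config,
         objective = unname(utils::tail(fit$objective_trace, 1L)),
         n_iter = fit$n_iter, converged = fit$converged)
  } else if (inherits(fit, "fcm")) {
    list(model = "fcm", centroids = fit$centroids, config = fit$config,
         objective = unname(utils::tail(fit$objective_trace, 1L)),
         n_iter = fit$n_iter, converged = fit$converged)
  } else stop("write_checkpoint: not a fitted model", call. = FALSE)
  jsonlite::write_json(ck, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a JSON checkpoint written by [write_checkpoint()]
#'
#' @param path checkpoint file.
#' @return a list with the stored fields.
#' @export
read_checkpoint <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
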