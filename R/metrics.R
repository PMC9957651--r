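#' Align predicted clusters to ground-truth classes
#'
#' Clustering output is permutation-invariant, so before any evaluation the
#' predicted cluster indices must be matched to the named tissue classes.
#' The default rule is the one-to-one assignment maximizing total overlap on
#' the n x n contingency table, found by exact search over all assignments
#' (feasible for the small class counts of tissue segmentation; capped at 8
#' classes).  Permutations are scanned in lexicographic order with strict
#' improvement, so ties break deterministically toward the lowest class
#' index.  An intensity-ordering rule is available as an alternative: for
#' T1-weighted brain MRI the class means order as
#' background < CSF < GM < WM, so clusters can be ranked by centroid.
#'
#' @param pred integer label map (vector, matrix) with predicted cluster
#'   indices in `0:(n_classes-1)`.
#' @param truth integer label map of the same shape with true class indices.
#' @param n_classes number of classes/clusters (<= 8 for `"overlap"`).
#' @param method `"overlap"` (default, maximum-total-overlap assignment) or
#'   `"intensity"` (rank clusters by `centroids`).
#' @param centroids cluster centroids, required for `method = "intensity"`.
#' @return integer vector `a` of length `n_classes`, 0-based: predicted
#'   cluster `j` maps to class `a[j + 1]`.  Apply with
#'   [apply_alignment()].
#' @examples
#' p <- c(1L, 1L, 0L, 2L); tr <- c(0L, 0L, 1L, 2L)
#' a <- align_clusters(p, tr, 3)
#' apply_alignment(p, a)   # equals tr
#' @export
align_clusters <- function(pred = NULL, truth = NULL, n_classes,
                           method = c("overlap", "intensity"),
                           centroids = NULL) {
  method <- match.arg(method)
  n <- as.integer(n_classes)
  if (method == "intensity") {
    if (is.null(centroids) || length(centroids) != n)
      stop("align_clusters: intensity method needs one centroid per class",
           call. = FALSE)
    a <- integer(n)
    a[order(centroids)] <- 0:(n - 1L)
    return(a)
  }
  p <- check_labels(pred, n, "pred")
  tr <- check_labels(truth, n, "truth")
  if (length(p) != length(tr))
    stop("align_clusters: label maps differ in shape", call. = FALSE)
  if (n > 8L)
    stop("align_clusters: exact assignment supported for up to 8 classes",
         call. = FALSE)
  tab <- table(factor(p, levels = 0:(n - 1L)),
               factor(tr, levels = 0:(n - 1L)))
  perms <- permutations_lex(n)
  best <- -1
  a <- NULL
  for (r in seq_len(nrow(perms))) {
    s <- sum(tab[cbind(seq_len(n), perms[r, ])])
    if (s > best) {
      best <- s
      a <- perms[r, ] - 1L
    }
  }
  a
}

#' Relabel a predicted map through an alignment
#'
#' @param pred integer label map with cluster indices.
#' @param alignment 0-based alignment vector from [align_clusters()].
#' @return label map of the same shape with class indices.
#' @export
apply_alignment <- function(pred, alignment) {
  out <- alignment[as.integer(pred) + 1L]
  if (!is.null(dim(pred))) dim(out) <- dim(pred)
  out
}

#' Dice similarity coefficient of two binary masks
#'
#' \deqn{DSC = \frac{2 |S_1 \cap S_2|}{|S_1| + |S_2|}} measures the overlap
#' between a predicted and a true mask for one class; it is symmetric and
#' lies in \[0, 1\].  Two empty masks agree perfectly and score 1 by
#' convention; empty versus non-empty scores 0.
#'
#' @param pred_mask,truth_mask logical (or 0/1) arrays of identical shape.
#' @return a number in \[0, 1\].
#' @export
dice <- function(pred_mask, truth_mask) {
  a <- as.logical(pred_mask)
  b <- as.logical(truth_mask)
  if (length(a) != length(b))
    stop("dice: masks differ in shape", call. = FALSE)
  denom <- sum(a) + sum(b)
  if (denom == 0L) return(1)
  2 * sum(a & b) / denom
}

#' Pooled average Dice over the three brain tissues
#'
#' The tissue-averaged Dice pools the overlaps and sizes of CSF, GM and WM
#' (classes 1, 2, 3) into a single ratio
#' \deqn{DSC_{av} = \frac{2(|S_1^{CSF} \cap S_2^{CSF}| + |S_1^{GM} \cap S_2^{GM}|
#'   + |S_1^{WM} \cap S_2^{WM}|)}{\sum |S_1^c| + |S_2^c|},}
#' excluding the non-brain background class.  Note this is the pooled ratio,
#' not the arithmetic mean of the three per-tissue Dice values.
#'
#' @param pred integer label map (0 = background, 1 = CSF, 2 = GM, 3 = WM);
#'   pass raw cluster labels together with `alignment` to relabel first.
#' @param truth integer ground-truth label map of the same shape.
#' @param alignment optional 0-based alignment from [align_clusters()].
#' @param tissue_classes class indices pooled into the average (default
#'   `c(1, 2, 3)`).
#' @return a number in \[0, 1\].
#' @export
dice_average <- function(pred, truth, alignment = NULL,
                         tissue_classes = 1:3) {
  if (!is.null(alignment)) pred <- apply_alignment(pred, alignment)
  if (length(pred) != length(truth))
    stop("dice_average: label maps differ in shape", call. = FALSE)
  overlap <- 0L
  size <- 0L
  for (cl in tissue_classes) {
    overlap <- overlap + sum(pred == cl & truth == cl)
    size <- size + sum(pred == cl) + sum(truth == cl)
  }
  if (size == 0L) return(1)
  2 * overlap / size
}

#' Segmentation accuracy
#'
#' The fraction of pixels whose (aligned) predicted label matches the ground
#' truth, counted over all classes including background:
#' \deqn{SA = \sum_i |A_i \cap B_i| \big/ \sum_l |B_l|,} where \eqn{A_i} and
#' \eqn{B_i} are the predicted and true pixel sets of class i.
#'
#' @inheritParams dice_average
#' @return a number in \[0, 1\]; 1 iff the aligned segmentation equals the
#'   ground truth pixel-for-pixel.
#' @export
segmentation_accuracy <- function(pred, truth, alignment = NULL) {
  if (!is.null(alignment)) pred <- apply_alignment(pred, alignment)
  if (length(pred) != length(truth))
    stop("segmentation_accuracy: label maps differ in shape", call. = FALSE)
  mean(as.integer(pred) == as.integer(truth))
}

#' Evaluate a segmentation against ground truth
#'
#' Aligns predicted clusters to the true classes (maximum-overlap assignment
#' by default) and reports per-class Dice, the pooled tissue-average Dice,
#' and segmentation accuracy.
#'
#' @inheritParams dice_average
#' @param n_classes number of classes (default 4:
#'   background/CSF/GM/WM).
#' @param class_names names for the per-class Dice entries.
#' @return An object of class `seg_metrics`: list with `dsc` (named
#'   per-class Dice), `dsc_av`, `sa`, `alignment`.
#' @examples
#' ph <- generate_phantom(shape = c(48, 48), noise_pct = 1, seed = 1)
#' fit <- fcm(ph$image, centers = 4, seed = 1)
#' evaluate_segmentation(labels(fit), ph$truth)
#' @export
evaluate_segmentation <- function(pred, truth, n_classes = 4,
                                  alignment = NULL,
                                  class_names = c("background", "csf",
                                                  "gm", "wm")) {
  if (is.null(alignment))
    alignment <- align_clusters(pred, truth, n_classes)
  aligned <- apply_alignment(pred, alignment)
  cls <- 0:(n_classes - 1L)
  dsc <- vapply(cls, function(cl) dice(aligned == cl, truth == cl),
                numeric(1L))
  names(dsc) <- rep_len(class_names, n_classes)
  structure(list(
    dsc = dsc,
    dsc_av = dice_average(aligned, truth),
    sa = segmentation_accuracy(aligned, truth),
    alignment = alignment
  ), class = "seg_metrics")
}

#' @export
print.seg_metrics <- function(x, digits = 4, ...) {
  cat("Segmentation metrics\n")
  cat("  SA     :", format(x$sa, digits = digits), "\n")
  cat("  DSC_av :", format(x$dsc_av, digits = digits), "(pooled CSF/GM/WM)\n")
  cat("  DSC    :",
      paste(names(x$dsc), format(x$dsc, digits = digits), collapse = "  "),
      "\n")
  cat("  cluster -> class:",
      paste(seq_along(x$alignment) - 1L, "->", x$alignment, collapse = ", "),
      "\n")
  invisible(x)
}

check_labels <- function(lab, n, what) {
  l <- as.integer(lab)
  if (anyNA(l) || any(l < 0L) || any(l >= n))
    stop("align_clusters: ", what, " labels must lie in 0:(n_classes-1)",
         call. = FALSE)
  l
}

# all permutations of 1..n, one per row, in lexicographic order
permutations_lex <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_lex(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 0L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    for (r in seq_len(nrow(sub))) {
      row <- row + 1L
      out[row, ] <- c(first, rest[sub[r, ]])
    }
  }
  out
}
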