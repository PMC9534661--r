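# Voxel-count segmentation metrics and surface distances.
#
# All five quality indices are pure functions of the TP/FP/FN/TN tallies
# of a (prediction, gold) mask pair, computed in exact integer arithmetic
# with a single division at the end.  Conventions for degenerate masks:
# Dice and Jaccard of two empty masks are 1 (perfect agreement on
# absence); sensitivity and the balanced-accuracy AUC refuse undefined
# denominators rather than guessing.

check_binary_pair <- function(pred, gold) {
  if (!all(dim2(pred) == dim2(gold)))
    stop("prediction and gold masks have different grid shapes")
  pv <- as.vector(pred); gv <- as.vector(gold)
  if (!all(pv %in% c(0, 1)) || !all(gv %in% c(0, 1)))
    stop("masks must be binary (values 0/1)")
  list(p = pv != 0, g = gv != 0)
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' Confusion counts of a binary segmentation against its gold standard
#'
#' @param pred,gold Binary label masks (vectors, matrices or arrays of the
#'   same shape; values 0/1).
#' @return An object of class `confusion_counts`: a list with integer
#'   fields `tp`, `fp`, `fn`, `tn` summing to the number of voxels.
#' @export
confusion_counts <- function(pred, gold) {
  v <- check_binary_pair(pred, gold)
  tp <- sum(v$p & v$g)
  fp <- sum(v$p & !v$g)
  fn <- sum(!v$p & v$g)
  tn <- sum(!v$p & !v$g)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion counts: TP %d, FP %d, FN %d, TN %d (%d voxels)\n",
              x$tp, x$fp, x$fn, x$tn, x$tp + x$fp + x$fn + x$tn))
  invisible(x)
}

as_counts <- function(c) {
  if (inherits(c, "confusion_counts")) return(c)
  stopifnot(all(c(c$tp, c$fp, c$fn, c$tn) >= 0))
  c
}

#' Dice overlap coefficient
#'
#' `2 TP / (2 TP + FP + FN)`: the overlap rate between the segmented
#' region and the gold-standard region.  Two empty masks score 1.
#'
#' @param c A [confusion_counts()] (or list with `tp`, `fp`, `fn`, `tn`).
#' @return Fraction in `[0, 1]`.
#' @export
dice <- function(c) {
  c <- as_counts(c)
  den <- 2 * c$tp + c$fp + c$fn
  if (den == 0) return(1)
  2 * c$tp / den
}

#' Jaccard overlap index
#'
#' `TP / (TP + FP + FN)`.  Two empty masks score 1.
#' @inheritParams dice
#' @return Fraction in `[0, 1]`.
#' @export
jaccard <- function(c) {
  c <- as_counts(c)
  den <- c$tp + c$fp + c$fn
  if (den == 0) return(1)
  c$tp / den
}

#' Segmentation sensitivity (recall over gold voxels)
#'
#' `TP / (TP + FN)`; undefined (an error) when the gold standard is empty.
#' @inheritParams dice
#' @return Fraction in `[0, 1]`.
#' @export
sensitivity <- function(c) {
  c <- as_counts(c)
  if (c$tp + c$fn == 0) stop("sensitivity is undefined for an empty gold standard")
  c$tp / (c$tp + c$fn)
}

#' Balanced-accuracy AUC of a hard segmentation
#'
#' `1 - (FPR + FNR) / 2`, the count-based form used to score hard
#' (already thresholded) segmentations; this is not a threshold-sweep ROC
#' area.
#' @inheritParams dice
#' @return Fraction in `[0, 1]`.
#' @export
auc_paper <- function(c) {
  c <- as_counts(c)
  if (c$fp + c$tn == 0 || c$fn + c$tp == 0)
    stop("auc_paper is undefined when a class is absent from the gold standard")
  1 - 0.5 * (c$fp / (c$fp + c$tn) + c$fn / (c$fn + c$tp))
}

#' Signed relative volume difference ("AVD" as printed)
#'
#' `(|B| - |A|) / |A|` with `A` the predicted foreground and `B` the gold
#' foreground, by voxel count.  Despite the name it carries in parts of the
#' vascular-segmentation literature, this is a volume ratio, not a surface
#' distance; see [average_hausdorff()] for the conventional metric.
#'
#' @param pred,gold Binary label masks of identical shape.
#' @return Signed dimensionless ratio (0 for identical volumes; may be
#'   negative when the prediction is larger than the gold standard).
#' @export
avd_paper <- function(pred, gold) {
  v <- check_binary_pair(pred, gold)
  a <- sum(v$p)
  if (a == 0) stop("avd_paper is undefined for an empty prediction")
  (sum(v$g) - a) / a
}

# Foreground voxels that touch background through a face (6-connectivity),
# counting the outside of the grid as background.
surface_voxels <- function(mask) {
  d <- dim(mask)
  m <- mask != 0
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- m
  core <- pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)]
  nb <- pad[1:d[1], 2:(d[2] + 1L), 2:(d[3] + 1L)] &
    pad[3:(d[1] + 2L), 2:(d[2] + 1L), 2:(d[3] + 1L)] &
    pad[2:(d[1] + 1L), 1:d[2], 2:(d[3] + 1L)] &
    pad[2:(d[1] + 1L), 3:(d[2] + 2L), 2:(d[3] + 1L)] &
    pad[2:(d[1] + 1L), 2:(d[2] + 1L), 1:d[3]] &
    pad[2:(d[1] + 1L), 2:(d[2] + 1L), 3:(d[3] + 2L)]
  core & !nb
}

voxel_coords_mm <- function(idx, d, spacing) {
  idx <- idx - 1L
  i <- idx %% d[1]
  j <- (idx %/% d[1]) %% d[2]
  k <- idx %/% (d[1] * d[2])
  cbind((i + 0.5) * spacing[1], (j + 0.5) * spacing[2],
        (k + 0.5) * spacing[3])
}

min_dist_to_set <- function(a, b) {
  # nearest-neighbour distances from rows of a to rows of b, chunked to
  # bound the pairwise-distance memory
  out <- numeric(nrow(a))
  step <- max(1L, floor(2e6 / max(1L, nrow(b))))
  bb <- rowSums(b * b)
  for (s in seq(1L, nrow(a), by = step)) {
    ids <- s:min(s + step - 1L, nrow(a))
    aa <- a[ids, , drop = FALSE]
    d2 <- outer(rowSums(aa * aa), bb, "+") - 2 * tcrossprod(aa, b)
    out[ids] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' Average Hausdorff (mean surface) distance
#'
#' Symmetric mean of directed nearest-surface distances between the two
#' mask surfaces, in millimetres, spacing-aware: the mean over surface
#' voxels of A of the distance to the nearest surface voxel of B is
#' averaged with the reverse direction.
#'
#' @param pred,gold Binary 3-D label masks of identical shape (2-D
#'   matrices are treated as single-slice volumes).
#' @param spacing Voxel size per axis in mm.
#' @return Distance in mm (0 for identical masks).
#' @export
average_hausdorff <- function(pred, gold, spacing = c(1, 1, 1)) {
  if (length(dim(pred)) == 2L) {
    dim(pred) <- c(dim(pred), 1L)
    dim(gold) <- c(dim(gold), 1L)
  }
  v <- check_binary_pair(pred, gold)
  if (!any(v$p) || !any(v$g))
    stop("average_hausdorff is undefined for an empty mask")
  d <- dim(pred)
  spacing <- rep_len(spacing, 3L)
  sa <- which(as.vector(surface_voxels(pred)))
  sb <- which(as.vector(surface_voxels(gold)))
  pa <- voxel_coords_mm(sa, d, spacing)
  pb <- voxel_coords_mm(sb, d, spacing)
  (mean(min_dist_to_set(pa, pb)) + mean(min_dist_to_set(pb, pa))) / 2
}

#' Full metric report for one (prediction, gold) pair
#'
#' @param pred,gold Binary label masks of identical shape.
#' @param spacing Voxel size per axis in mm (used by the average Hausdorff
#'   distance only).
#' @param hausdorff Include the average Hausdorff surface distance (skipped
#'   when either mask is empty).
#' @return A one-row tibble with columns `dice`, `jaccard`, `sen`, `auc`,
#'   `avd` (and `avg_hausdorff_mm` when requested).
#' @export
seg_metrics <- function(pred, gold, spacing = c(1, 1, 1), hausdorff = FALSE) {
  cc <- confusion_counts(pred, gold)
  out <- tibble::tibble(
    dice = dice(cc), jaccard = jaccard(cc),
    sen = if (cc$tp + cc$fn > 0) sensitivity(cc) else NA_real_,
    auc = if (cc$fp + cc$tn > 0 && cc$fn + cc$tp > 0) auc_paper(cc)
    else NA_real_,
    avd = if (cc$tp + cc$fp > 0) avd_paper(pred, gold) else NA_real_)
  if (hausdorff) {
    out$avg_hausdorff_mm <-
      if (cc$tp + cc$fp > 0 && cc$tp + cc$fn > 0)
        average_hausdorff(pred, gold, spacing) else NA_real_
  }
  out
}
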