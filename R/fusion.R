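# Multi-view candidate fusion.
#
# Running slice-wise inference along the axial, coronal and sagittal
# directions of the same volume yields N candidate segmentations; the
# fusion model combines them per class as a weighted sum of class
# indicators plus a per-class bias, and labels each voxel by the arg-max
# class.  With uniform weights and zero bias this is majority voting.

#' Fuse candidate segmentations
#'
#' Per class k the fused score is `sum_n W[n, k] * c[n, k] + alpha[k]`,
#' where `c[n, k]` is the k-th class indicator of candidate n; the fused
#' label is the arg-max over classes (ties go to the lower class index).
#'
#' @param candidates List of integer label arrays on a common grid
#'   (values `0..num_classes-1`).
#' @param num_classes Number of classes (default: inferred).
#' @param weights `N x K` numeric matrix of scalar weights, or a list of
#'   `N` lists of voxelwise weight arrays; default uniform `1/N`.
#' @param bias Per-class bias vector `alpha` (default 0).
#' @return Integer label array of the common grid shape.
#' @export
fuse_candidates <- function(candidates, num_classes = NULL, weights = NULL,
                            bias = NULL) {
  stopifnot(length(candidates) >= 1L)
  d <- dim2(candidates[[1]])
  for (c in candidates)
    if (!all(dim2(c) == d)) stop("candidate shapes do not match")
  N <- length(candidates)
  K <- num_classes %||% (max(vapply(candidates, max, 0)) + 1L)
  if (is.null(weights)) weights <- matrix(1 / N, N, K)
  if (is.null(bias)) bias <- rep(0, K)
  nv <- prod(d)
  score <- matrix(rep(bias, each = nv), nv, K)
  for (n in seq_len(N)) {
    lab <- as.integer(candidates[[n]])
    for (k in seq_len(K)) {
      ind <- as.numeric(lab == (k - 1L))
      w <- if (is.matrix(weights)) weights[n, k]
      else as.vector(weights[[n]][[k]])
      score[, k] <- score[, k] + w * ind
    }
  }
  lab <- max.col(score, ties.method = "first") - 1L
  out <- array(as.integer(lab), if (length(d) > 1) d else NULL)
  out
}

#' Least-squares fit of fusion weights against gold masks
#'
#' The fusion weights are not identified by the forward model alone; when
#' gold masks for a validation set are available, per-(candidate, class)
#' scalar weights and per-class biases can be fitted by minimising the
#' squared error between the fused class score and the gold indicator.
#'
#' @param candidate_sets List of validation cases; each a list of N label
#'   arrays.
#' @param golds List of gold label arrays matching `candidate_sets`.
#' @param num_classes Number of classes.
#' @return List with `weights` (N x K matrix) and `bias` (length K).
#' @export
fit_fusion_weights <- function(candidate_sets, golds, num_classes = 2L) {
  N <- length(candidate_sets[[1]])
  K <- num_classes
  weights <- matrix(0, N, K)
  bias <- numeric(K)
  for (k in seq_len(K)) {
    X <- do.call(rbind, lapply(seq_along(candidate_sets), function(i)
      vapply(candidate_sets[[i]],
             function(c) as.numeric(as.integer(c) == (k - 1L)),
             numeric(length(candidate_sets[[i]][[1]])))))
    yv <- unlist(lapply(golds, function(g)
      as.numeric(as.integer(g) == (k - 1L))))
    fit <- stats::lm.fit(cbind(1, X), yv)
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    bias[k] <- cf[1]
    weights[, k] <- cf[-1]
  }
  list(weights = weights, bias = bias)
}

#' Multi-view candidate segmentation of a volume
#'
#' Applies a fitted slice network along the three orthogonal axes of the
#' volume, giving three candidate masks for [fuse_candidates()].
#'
#' @param fit A `daunet_fit` or slice-segmenter function.
#' @param volume 3-D intensity array.
#' @param axes Axes to slice along (default all three).
#' @return List of integer label arrays, one per axis.
#' @export
multiview_candidates <- function(fit, volume, axes = 1:3) {
  lapply(axes, function(a) predict_volume(fit, volume, axis = a))
}
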