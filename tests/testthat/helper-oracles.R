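# Fixtures and independent oracles used across the suite.

# Random binary mask pair on a small random grid; `correlated` draws the
# prediction as a corrupted copy of the gold so every TP/FP/FN/TN mix
# occurs.
random_mask_pair <- function(max_extent = 16L, correlated = TRUE) {
  d <- sample(2:max_extent, 3L, replace = TRUE)
  gold <- array(as.integer(stats::runif(prod(d)) < stats::runif(1, 0.05, 0.6)), d)
  pred <- if (correlated && stats::runif(1) < 0.7) {
    flip <- stats::runif(prod(d)) < stats::runif(1, 0, 0.3)
    array(as.integer(xor(gold == 1L, flip)), d)
  } else {
    array(as.integer(stats::runif(prod(d)) < stats::runif(1, 0.05, 0.6)), d)
  }
  list(pred = pred, gold = gold)
}

# Set-cardinality oracle for the five voxel-count metrics, computed from
# explicit voxel index sets rather than tallies.
oracle_metrics <- function(pred, gold) {
  A <- which(as.vector(pred) == 1L)
  B <- which(as.vector(gold) == 1L)
  U <- seq_along(as.vector(pred))
  inter <- length(intersect(A, B))
  uni <- length(union(A, B))
  notA <- setdiff(U, A)
  notB <- setdiff(U, B)
  list(
    dice = if (length(A) + length(B) == 0) 1 else
      2 * inter / (length(A) + length(B)),
    jaccard = if (uni == 0) 1 else inter / uni,
    sen = if (length(B) == 0) NA_real_ else inter / length(B),
    auc = if (length(notB) == 0 || length(B) == 0) NA_real_ else
      1 - 0.5 * (length(intersect(A, notB)) / length(notB) +
                   length(intersect(notA, B)) / length(B)),
    avd = if (length(A) == 0) NA_real_ else
      (length(B) - length(A)) / length(A))
}

# Literal per-voxel loop tallying the confusion counts.
oracle_counts_loop <- function(pred, gold) {
  p <- as.vector(pred); g <- as.vector(gold)
  tp <- 0L; fp <- 0L; fn <- 0L; tn <- 0L
  for (i in seq_along(p)) {
    if (p[i] == 1L && g[i] == 1L) tp <- tp + 1L
    else if (p[i] == 1L) fp <- fp + 1L
    else if (g[i] == 1L) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# Brute-force symmetric mean nearest-surface distance (same definition as
# the implementation, computed naively point-by-point).
oracle_avg_hausdorff <- function(pred, gold, spacing = c(1, 1, 1)) {
  surf <- function(m) {
    d <- dim(m)
    out <- NULL
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      if (m[i, j, k] == 0) next
      nb <- c(
        if (i > 1) m[i - 1, j, k] else 0, if (i < d[1]) m[i + 1, j, k] else 0,
        if (j > 1) m[i, j - 1, k] else 0, if (j < d[2]) m[i, j + 1, k] else 0,
        if (k > 1) m[i, j, k - 1] else 0, if (k < d[3]) m[i, j, k + 1] else 0)
      if (any(nb == 0)) out <- rbind(out, c(i, j, k))
    }
    out
  }
  pa <- sweep(surf(pred) - 0.5, 2, spacing, "*")
  pb <- sweep(surf(gold) - 0.5, 2, spacing, "*")
  dir <- function(a, b) {
    mean(apply(a, 1, function(p) min(sqrt(colSums((t(b) - p)^2)))))
  }
  (dir(pa, pb) + dir(pb, pa)) / 2
}

# Tiny slice dataset from quick phantoms, for smoke-scale training.
tiny_slice_data <- function(n_phantoms = 2L, n_slices = 24L, shape = 32L,
                            seed = 42L) {
  ds <- generate_phantom_dataset(n_phantoms, seed = seed,
                                 shape = rep(shape, 3L))
  phantom_slices(ds$phantoms, n_slices, seed = seed)
}
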