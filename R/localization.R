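# Perforator localization geometry and detection-concordance statistics.
#
# The clinical procedure anchors a 3-D coordinate frame on the
# iliac-patellar line (anterior superior iliac spine to lateral patellar
# border): the line's midpoint is the origin, the line itself the
# longitudinal axis, and the skin-surface normal completes the frame.
# Perforator exit points are projected onto the skin surface and compared
# between prediction and surgical reference by thresholded point matching.

#' Build the landmark-anchored anatomical coordinate frame
#'
#' @param iliac_point,patellar_point Distinct 3-D landmark positions (mm).
#' @param surface_normal_hint Vector indicating the skin-surface normal;
#'   orthogonalised against the landmark line (must not be parallel to it).
#' @return An object of class `anatomical_frame` with fields `origin`
#'   (midpoint of the landmark line) and orthonormal right-handed axes
#'   `axis_long`, `axis_surface`, `axis_third`.
#' @export
build_frame <- function(iliac_point, patellar_point,
                        surface_normal_hint = c(0, 0, 1)) {
  iliac_point <- as.numeric(iliac_point)
  patellar_point <- as.numeric(patellar_point)
  v <- patellar_point - iliac_point
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("landmark points coincide")
  axis_long <- v / nv
  h <- as.numeric(surface_normal_hint)
  h <- h - sum(h * axis_long) * axis_long
  nh <- sqrt(sum(h^2))
  if (nh < 1e-12) stop("surface normal hint is parallel to the landmark line")
  axis_surface <- h / nh
  axis_third <- c(axis_long[2] * axis_surface[3] - axis_long[3] * axis_surface[2],
                  axis_long[3] * axis_surface[1] - axis_long[1] * axis_surface[3],
                  axis_long[1] * axis_surface[2] - axis_long[2] * axis_surface[1])
  structure(list(origin = (iliac_point + patellar_point) / 2,
                 axis_long = axis_long, axis_surface = axis_surface,
                 axis_third = axis_third),
            class = "anatomical_frame")
}

#' Transform world-coordinate points into an anatomical frame
#' @param points n x 3 matrix (or length-3 vector) of mm positions.
#' @param frame An [build_frame()] result.
#' @return n x 3 matrix of frame coordinates (long, surface, third).
#' @export
world_to_frame <- function(points, frame) {
  p <- rbind2mat(points)
  sweep(p, 2, frame$origin) %*%
    cbind(frame$axis_long, frame$axis_surface, frame$axis_third)
}

#' Transform frame coordinates back to world coordinates
#' @inheritParams world_to_frame
#' @export
frame_to_world <- function(points, frame) {
  p <- rbind2mat(points)
  sweep(p %*% rbind(frame$axis_long, frame$axis_surface, frame$axis_third),
        2, frame$origin, "+")
}

rbind2mat <- function(points) {
  if (is.null(dim(points))) matrix(as.numeric(points), 1, 3)
  else as.matrix(points)
}

#' Orthogonal projection of a point onto the skin plane
#'
#' @param point 3-D mm position (or n x 3 matrix).
#' @param skin_plane List with `point` (any point on the plane) and
#'   `normal` (plane normal).
#' @return Projected position(s) on the plane, same shape as `point`.
#' @export
project_to_surface <- function(point, skin_plane) {
  p <- rbind2mat(point)
  n <- as.numeric(skin_plane$normal)
  n <- n / sqrt(sum(n^2))
  d <- drop(sweep(p, 2, as.numeric(skin_plane$point)) %*% n)
  out <- p - outer(d, n)
  if (is.null(dim(point))) drop(out) else out
}

#' Euclidean localization error between two mm positions
#' @param predicted,actual 3-D positions in the same frame.
#' @return Distance in mm.
#' @export
localization_error <- function(predicted, actual) {
  sqrt(sum((as.numeric(predicted) - as.numeric(actual))^2))
}

#' Match predicted and reference perforator points
#'
#' Pairs points greedily, closest pairs first, using each point at most
#' once and only pairs within `threshold` mm.  Matched pairs are true
#' positives, unmatched predictions false positives, unmatched references
#' false negatives.  A true-negative count requires an explicit
#' `candidate_sites` denominator (the number of examined sites); without
#' it specificity is unavailable.
#'
#' @param predicted,reference n x 3 / m x 3 matrices of mm positions
#'   (possibly 0-row).
#' @param threshold Maximum pairing distance in mm (> 0).
#' @param candidate_sites Optional total count of candidate sites, from
#'   which `tn = candidate_sites - tp - fp - fn`.
#' @param method `"greedy"` (default) or `"optimal"` (exhaustive best
#'   assignment, for small point sets).
#' @return An object of class `perforator_match`: counts `tp`, `fp`, `fn`,
#'   `tn` (NA without `candidate_sites`), the matched `pairs` (indices and
#'   mm distance), and the statistics `accordance`, `sensitivity`,
#'   `specificity`.
#' @export
match_perforators <- function(predicted, reference, threshold = 10,
                              candidate_sites = NULL,
                              method = c("greedy", "optimal")) {
  method <- match.arg(method)
  if (threshold <= 0) stop("match threshold must be positive")
  p <- if (is.null(predicted) || length(predicted) == 0)
    matrix(numeric(), 0, 3) else rbind2mat(predicted)
  r <- if (is.null(reference) || length(reference) == 0)
    matrix(numeric(), 0, 3) else rbind2mat(reference)
  np <- nrow(p); nr <- nrow(r)
  pairs <- NULL
  if (np > 0 && nr > 0) {
    dmat <- sqrt(outer(rowSums(p^2), rowSums(r^2), "+") - 2 * tcrossprod(p, r))
    dmat[is.nan(dmat)] <- 0
    pairs <- if (method == "greedy") greedy_match(dmat, threshold)
    else optimal_match(dmat, threshold)
  }
  tp <- if (is.null(pairs)) 0L else nrow(pairs)
  fp <- np - tp
  fn <- nr - tp
  tn <- NA_integer_
  if (!is.null(candidate_sites)) {
    tn <- as.integer(candidate_sites) - tp - fp - fn
    if (tn < 0) stop("candidate_sites smaller than the observed site count")
  }
  res <- list(tp = tp, fp = fp, fn = fn, tn = tn,
              pairs = pairs,
              distances = if (is.null(pairs)) numeric() else pairs[, "distance"],
              accordance = if (!is.na(tn)) (tp + tn) / (tp + fp + fn + tn)
              else if (nr > 0) tp / nr else NA_real_,
              sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
              specificity = if (!is.na(tn) && tn + fp > 0) tn / (tn + fp)
              else NA_real_)
  structure(res, class = "perforator_match")
}

greedy_match <- function(dmat, threshold) {
  ok <- which(dmat <= threshold, arr.ind = TRUE)
  if (nrow(ok) == 0) return(NULL)
  ok <- ok[order(dmat[ok]), , drop = FALSE]
  used_p <- logical(nrow(dmat)); used_r <- logical(ncol(dmat))
  rows <- list()
  for (s in seq_len(nrow(ok))) {
    i <- ok[s, 1]; j <- ok[s, 2]
    if (used_p[i] || used_r[j]) next
    used_p[i] <- TRUE; used_r[j] <- TRUE
    rows[[length(rows) + 1L]] <- c(i, j, dmat[i, j])
  }
  out <- do.call(rbind, rows)
  dimnames(out) <- list(NULL, c("predicted", "reference", "distance"))
  out
}

# Exhaustive optimal assignment (max matches, then min total distance);
# intended for the handful of perforators per thigh.
optimal_match <- function(dmat, threshold) {
  np <- nrow(dmat); nr <- ncol(dmat)
  if (min(np, nr) > 8L)
    stop("optimal matching is exhaustive; use method = 'greedy' for > 8 points")
  best <- list(n = -1L, cost = Inf, sel = NULL)
  recurse <- function(i, used_r, sel, cost) {
    if (i > np) {
      n <- if (is.null(sel)) 0L else nrow(sel)
      if (n > best$n || (n == best$n && cost < best$cost))
        best <<- list(n = n, cost = cost, sel = sel)
      return()
    }
    recurse(i + 1L, used_r, sel, cost)          # leave prediction i unmatched
    for (j in seq_len(nr)) {
      if (!used_r[j] && dmat[i, j] <= threshold) {
        used_r[j] <- TRUE
        row <- matrix(c(i, j, dmat[i, j]), 1,
                      dimnames = list(NULL, c("predicted", "reference",
                                              "distance")))
        recurse(i + 1L, used_r, rbind(sel, row), cost + dmat[i, j])
        used_r[j] <- FALSE
      }
    }
  }
  recurse(1L, logical(nr), NULL, 0)
  best$sel
}

#' @export
print.perforator_match <- function(x, ...) {
  cat(sprintf("perforator matching: TP %d, FP %d, FN %d, TN %s\n",
              x$tp, x$fp, x$fn, ifelse(is.na(x$tn), "n/a", x$tn)))
  cat(sprintf("  sensitivity %.3f, accordance %.3f, specificity %s\n",
              x$sensitivity, x$accordance,
              ifelse(is.na(x$specificity), "n/a",
                     sprintf("%.3f", x$specificity))))
  if (x$tp > 0)
    cat(sprintf("  matched distance %.2f +/- %.2f mm\n",
                mean(x$distances), stats::sd(x$distances)))
  invisible(x)
}

#' Extract perforator exit points from a segmentation mask
#'
#' Takes the mask voxels lying within `slab_vox` voxels of the skin plane,
#' clusters them into connected blobs (face connectivity within the slab),
#' and returns each blob's centroid projected onto the plane.
#'
#' @param mask Binary 3-D mask.
#' @param spacing Voxel size per axis in mm.
#' @param skin_plane Plane list (`point`, `normal`), as stored in phantom
#'   truth.
#' @param slab_vox Slab half-thickness in voxels.
#' @return k x 3 matrix of mm positions on the skin plane (0 rows when the
#'   mask does not reach the skin).
#' @export
extract_exit_points <- function(mask, spacing, skin_plane, slab_vox = 1.5) {
  d <- dim(mask)
  spacing <- rep_len(spacing, 3L)
  idx <- which(mask != 0)
  if (length(idx) == 0) return(matrix(numeric(), 0, 3))
  pts <- voxel_coords_mm(idx, d, spacing)
  n <- as.numeric(skin_plane$normal); n <- n / sqrt(sum(n^2))
  dist_pl <- abs(drop(sweep(pts, 2, as.numeric(skin_plane$point)) %*% n))
  keep <- dist_pl <= slab_vox * max(spacing)
  if (!any(keep)) return(matrix(numeric(), 0, 3))
  idx <- idx[keep]
  pts <- pts[keep, , drop = FALSE]
  comp <- label_components(idx, d)
  cents <- do.call(rbind, lapply(split(seq_along(idx), comp), function(s)
    colMeans(pts[s, , drop = FALSE])))
  project_to_surface(cents, skin_plane)
}

# Connected components (6-connectivity) of a sparse voxel index set.
label_components <- function(idx, d) {
  lookup <- new.env(parent = emptyenv(), size = length(idx) * 2L)
  for (s in seq_along(idx)) assign(as.character(idx[s]), s, lookup)
  comp <- integer(length(idx))
  cur <- 0L
  i <- (idx - 1L) %% d[1]
  j <- ((idx - 1L) %/% d[1]) %% d[2]
  k <- (idx - 1L) %/% (d[1] * d[2])
  for (s in seq_along(idx)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      for (dd in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                      c(0, 0, 1), c(0, 0, -1))) {
        ni <- i[v] + dd[1]; nj <- j[v] + dd[2]; nk <- k[v] + dd[3]
        if (ni < 0 || ni >= d[1] || nj < 0 || nj >= d[2] ||
            nk < 0 || nk >= d[3]) next
        nidx <- ni + d[1] * nj + d[1] * d[2] * nk + 1L
        t <- lookup[[as.character(nidx)]]
        if (!is.null(t) && comp[t] == 0L) {
          comp[t] <- cur
          queue <- c(queue, t)
        }
      }
    }
  }
  comp
}

#' Desk-scale perforator localization study on phantoms
#'
#' For each phantom: segment (with the supplied segmenter, or the gold
#' mask when `segmenter = NULL`), extract predicted exit points at the
#' skin plane, optionally jitter them with isotropic Gaussian noise, and
#' match them to the ground-truth exit points.
#'
#' @param phantoms List of `cta_phantom` objects.
#' @param segmenter `NULL` (oracle: gold mask pass-through), a
#'   `daunet_fit`, or a function from a 2-D slice to labels.
#' @param threshold Match threshold in mm.
#' @param jitter_sd Isotropic Gaussian noise SD (mm) added to each
#'   predicted point, emulating localization error.
#' @param candidate_sites Per-phantom candidate-site count for the
#'   specificity denominator (optional).
#' @param seed Seed for the jitter noise.
#' @return A list of class `localization_study`: `per_phantom` tibble
#'   (one row per phantom) and `summary` tibble (mean/sd distance and the
#'   pooled detection statistics).
#' @export
localization_study <- function(phantoms, segmenter = NULL, threshold = 10,
                               jitter_sd = 0, candidate_sites = NULL,
                               seed = 1L) {
  set.seed(seed)
  rows <- vector("list", length(phantoms))
  all_d <- numeric()
  tot <- c(tp = 0L, fp = 0L, fn = 0L, tn = 0L)
  have_tn <- !is.null(candidate_sites)
  for (i in seq_along(phantoms)) {
    ph <- phantoms[[i]]
    mask <- if (is.null(segmenter)) ph$truth$mask
    else predict_volume(segmenter, ph$volume)
    pred <- extract_exit_points(mask, ph$spec$spacing, ph$truth$skin_plane)
    if (jitter_sd > 0 && nrow(pred) > 0) {
      pred <- pred + matrix(stats::rnorm(length(pred), 0, jitter_sd),
                            nrow(pred), 3)
      pred <- project_to_surface(pred, ph$truth$skin_plane)
    }
    m <- match_perforators(pred, ph$truth$perforator_points, threshold,
                           candidate_sites = candidate_sites)
    tot["tp"] <- tot["tp"] + m$tp; tot["fp"] <- tot["fp"] + m$fp
    tot["fn"] <- tot["fn"] + m$fn
    if (have_tn) tot["tn"] <- tot["tn"] + m$tn
    all_d <- c(all_d, m$distances)
    rows[[i]] <- tibble::tibble(
      phantom = i, n_true = nrow(ph$truth$perforator_points),
      n_pred = nrow(pred), tp = m$tp, fp = m$fp, fn = m$fn,
      mean_distance_mm = if (m$tp > 0) mean(m$distances) else NA_real_,
      sensitivity = m$sensitivity)
  }
  denom <- sum(tot[c("tp", "fp", "fn")]) + if (have_tn) tot["tn"] else 0L
  summary <- tibble::tibble(
    n_phantoms = length(phantoms),
    mean_distance_mm = if (length(all_d)) mean(all_d) else NA_real_,
    sd_distance_mm = if (length(all_d) > 1) stats::sd(all_d) else NA_real_,
    sensitivity = unname(tot["tp"] / (tot["tp"] + tot["fn"])),
    accordance = unname(if (have_tn) (tot["tp"] + tot["tn"]) / denom
                        else tot["tp"] / (tot["tp"] + tot["fn"])),
    specificity = unname(if (have_tn) tot["tn"] / (tot["tn"] + tot["fp"])
                         else NA_real_))
  structure(list(per_phantom = do.call(rbind, rows), summary = summary,
                 threshold = threshold, jitter_sd = jitter_sd),
            class = "localization_study")
}

#' @export
print.localization_study <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "localization study on %d phantoms (threshold %.1f mm%s)\n",
    s$n_phantoms, x$threshold,
    if (x$jitter_sd > 0) sprintf(", jitter SD %.1f mm", x$jitter_sd) else ""))
  cat(sprintf("  distance %.2f +/- %.2f mm, sensitivity %.3f, accordance %.3f\n",
              s$mean_distance_mm, s$sd_distance_mm, s$sensitivity,
              s$accordance))
  invisible(x)
}
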