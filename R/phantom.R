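# Seeded synthetic CTA vessel phantoms.
#
# A phantom emulates a contrast-enhanced arterial tree in the thigh: a
# bright, gently curving main artery running along the volume's long axis
# (axis 3), with thinner perforator branches that leave the main vessel
# and rise along axis 1 until they pierce a flat "skin" plane.  Intensities
# are HU-like: soft-tissue background around 50, contrast-filled lumen
# around 300 (the arterial-phase trigger level of clinical CTA is 280 HU),
# plus additive Gaussian noise.  No scanner physics is simulated.

#' Parameters of a synthetic CTA vessel phantom
#'
#' @param shape Voxel extents per axis (default 64^3).
#' @param spacing Voxel size per axis in mm.
#' @param main_vessel_radius Main artery lumen radius in mm.
#' @param n_perforators Number of perforator branches.
#' @param perforator_radius Perforator lumen radius in mm.
#' @param lumen_intensity_mean,tissue_intensity_mean HU-like intensity
#'   means of contrast lumen and soft tissue.
#' @param noise_sd Additive Gaussian noise standard deviation (HU-like).
#'   Must satisfy `lumen > tissue + 3 * noise_sd` so the phantom is
#'   learnable by construction.
#' @param skin_offset_mm Position of the skin plane along axis 1
#'   (default: 3 mm below the axis-1 extent).
#' @param seed Integer seed; identical seeds give bit-identical phantoms.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64L, 64L, 64L), spacing = c(1, 1, 1),
                         main_vessel_radius = 3, n_perforators = 3L,
                         perforator_radius = 1.4,
                         lumen_intensity_mean = 300,
                         tissue_intensity_mean = 50, noise_sd = 15,
                         skin_offset_mm = NULL, seed = 1L) {
  shape <- as.integer(rep_len(shape, 3L))
  spacing <- rep_len(spacing, 3L)
  if (is.null(skin_offset_mm)) skin_offset_mm <- (shape[1] - 3) * spacing[1]
  if (lumen_intensity_mean <= tissue_intensity_mean + 3 * noise_sd)
    stop("lumen intensity must exceed tissue intensity by more than 3 noise SDs")
  ext <- shape * spacing
  if (skin_offset_mm <= 0 || skin_offset_mm >= ext[1])
    stop("skin plane lies outside the volume")
  if (main_vessel_radius >= min(ext) / 4)
    stop("main vessel radius too large for the volume")
  structure(list(shape = shape, spacing = spacing,
                 main_vessel_radius = main_vessel_radius,
                 n_perforators = as.integer(n_perforators),
                 perforator_radius = perforator_radius,
                 lumen_intensity_mean = lumen_intensity_mean,
                 tissue_intensity_mean = tissue_intensity_mean,
                 noise_sd = noise_sd, skin_offset_mm = skin_offset_mm,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Smooth, zero-mean lateral wander of bounded amplitude.
smooth_wander <- function(n, amplitude, window = 9L) {
  w <- cumsum(stats::rnorm(n))
  k <- rep(1 / window, window)
  w <- stats::filter(c(rep(w[1], window), w, rep(w[n], window)), k,
                     sides = 2)
  w <- as.numeric(w[(window + 1):(window + n)])
  w <- w - mean(w)
  if (max(abs(w)) > 0) w <- w * amplitude / max(abs(w))
  w
}

# Rasterise a polyline tube: voxels whose centre lies within `radius` mm
# of any segment of `line` (rows = mm points).
rasterise_tube <- function(mask, line, radius, spacing) {
  d <- dim(mask)
  lo <- pmax(floor((apply(line, 2, min) - radius) / spacing), 0)
  hi <- pmin(ceiling((apply(line, 2, max) + radius) / spacing), d)
  ii <- (lo[1] + 1):hi[1]; jj <- (lo[2] + 1):hi[2]; kk <- (lo[3] + 1):hi[3]
  ctr <- cbind(rep((ii - 0.5) * spacing[1], times = length(jj) * length(kk)),
               rep(rep((jj - 0.5) * spacing[2], each = length(ii)),
                   times = length(kk)),
               rep((kk - 0.5) * spacing[3], each = length(ii) * length(jj)))
  dmin <- rep(Inf, nrow(ctr))
  for (s in seq_len(nrow(line) - 1L)) {
    p <- line[s, ]; q <- line[s + 1L, ]
    v <- q - p
    vv <- sum(v * v)
    w <- sweep(ctr, 2, p)
    t <- if (vv == 0) rep(0, nrow(ctr)) else
      pmin(pmax((w %*% v) / vv, 0), 1)
    dd <- w - outer(as.vector(t), v)
    dmin <- pmin(dmin, rowSums(dd * dd))
  }
  hit <- sqrt(dmin) <= radius
  sub <- array(FALSE, c(length(ii), length(jj), length(kk)))
  sub[hit] <- TRUE
  mask[ii, jj, kk] <- mask[ii, jj, kk] | sub
  mask
}

#' Generate one synthetic CTA phantom
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `cta_phantom` with elements `volume` (HU-like
#'   intensity array), `truth` (list: binary `mask`, `perforator_points`
#'   as an n x 3 matrix of mm coordinates on the skin plane, `centerlines`,
#'   `skin_plane`), and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)
  d <- spec$shape
  sp <- spec$spacing
  ext <- d * sp
  rmain <- spec$main_vessel_radius
  # main artery: descending along axis 3, wandering in x and y
  z <- seq(0.5 * sp[3], ext[3] - 0.5 * sp[3], by = min(sp))
  nz <- length(z)
  x0 <- 0.35 * ext[1]
  y0 <- 0.5 * ext[2]
  main <- cbind(x0 + smooth_wander(nz, 0.04 * ext[1]),
                y0 + smooth_wander(nz, 0.06 * ext[2]), z)
  main[, 1] <- pmin(pmax(main[, 1], rmain + sp[1]),
                    spec$skin_offset_mm - 3 * rmain)
  main[, 2] <- pmin(pmax(main[, 2], rmain + sp[2]), ext[2] - rmain - sp[2])
  np <- spec$n_perforators
  lines <- list(main = main)
  # redraw the branch geometry until every skin-exit point is well
  # separated from the others, so each perforator pierces the surface as
  # its own distinct blob (count recovery stays well-posed)
  min_sep <- max(6, 4 * spec$perforator_radius)
  for (attempt in seq_len(40L)) {
    branch_t <- (seq_len(np) - 0.5) / np
    branch_t <- pmin(pmax(branch_t + stats::runif(np, -0.3, 0.3) / np,
                          0.08), 0.92)
    plines <- vector("list", np)
    exit_pts <- matrix(NA_real_, np, 3)
    for (b in seq_len(np)) {
      i0 <- max(1L, round(branch_t[b] * nz))
      start <- main[i0, ]
      nsteg <- 24L
      t <- seq(0, 1, length.out = nsteg)
      xs <- start[1] + t * (spec$skin_offset_mm - start[1])
      drift_y <- smooth_wander(nsteg, stats::runif(1, 1, 3))
      drift_z <- t * stats::runif(1, -6, 6)
      ys <- pmin(pmax(start[2] + drift_y - drift_y[1],
                      spec$perforator_radius + sp[2]),
                 ext[2] - spec$perforator_radius - sp[2])
      zs <- pmin(pmax(start[3] + drift_z,
                      spec$perforator_radius + sp[3]),
                 ext[3] - spec$perforator_radius - sp[3])
      plines[[b]] <- cbind(xs, ys, zs)
      exit_pts[b, ] <- plines[[b]][nsteg, ]
    }
    if (np < 2L || min(stats::dist(exit_pts)) >= min_sep) break
  }
  for (b in seq_len(np)) lines[[paste0("perforator", b)]] <- plines[[b]]
  mask <- array(FALSE, d)
  mask <- rasterise_tube(mask, main, rmain, sp)
  for (b in seq_len(np))
    mask <- rasterise_tube(mask, lines[[paste0("perforator", b)]],
                           spec$perforator_radius, sp)
  volume <- array(spec$tissue_intensity_mean, d) +
    array(stats::rnorm(prod(d), 0, spec$noise_sd), d)
  volume[mask] <- spec$lumen_intensity_mean +
    stats::rnorm(sum(mask), 0, spec$noise_sd)
  truth <- list(mask = array(as.integer(mask), d),
                perforator_points = exit_pts,
                centerlines = lines,
                skin_plane = list(point = c(spec$skin_offset_mm, 0, 0),
                                  normal = c(1, 0, 0),
                                  offset_mm = spec$skin_offset_mm))
  structure(list(volume = volume, truth = truth, spec = spec),
            class = "cta_phantom")
}

#' @export
print.cta_phantom <- function(x, ...) {
  cat(sprintf(
    "CTA phantom %s voxels, %d lumen voxels, %d perforator(s), seed %d\n",
    paste(x$spec$shape, collapse = "x"), sum(x$truth$mask),
    x$spec$n_perforators, x$spec$seed))
  invisible(x)
}

#' Generate a seeded phantom dataset with a train/val/test split
#'
#' Phantom parameters are drawn uniformly from `spec_ranges` under one
#' master seed; split membership is deterministic given the seed.
#'
#' @param n Number of phantoms.
#' @param spec_ranges Named list of `c(min, max)` ranges overriding
#'   [phantom_spec()] defaults (`main_vessel_radius`, `perforator_radius`,
#'   `noise_sd`, and integer `n_perforators`).
#' @param seed Master seed.
#' @param split Fractions for train/validation/test (rounded to counts).
#' @param ... Fixed arguments forwarded to [phantom_spec()].
#' @return A list of class `phantom_dataset`: `phantoms` (list of
#'   `cta_phantom`), `split` (factor of `"train"`, `"val"`, `"test"`),
#'   `seed`.
#' @export
generate_phantom_dataset <- function(n, spec_ranges = list(), seed = 1L,
                                     split = c(train = 0.7, val = 0.15,
                                               test = 0.15), ...) {
  stopifnot(n >= 1L)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  draw <- function(field, default) {
    r <- spec_ranges[[field]]
    if (is.null(r)) rep(default, n)
    else if (field == "n_perforators")
      sample(seq(r[1], r[2]), n, replace = TRUE)
    else stats::runif(n, r[1], r[2])
  }
  rad <- draw("main_vessel_radius", 3)
  prad <- draw("perforator_radius", 1.4)
  nsd <- draw("noise_sd", 15)
  nperf <- draw("n_perforators", 3L)
  phantoms <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- phantom_spec(main_vessel_radius = rad[i],
                       perforator_radius = prad[i], noise_sd = nsd[i],
                       n_perforators = nperf[i], seed = seeds[i], ...)
    phantoms[[i]] <- generate_phantom(sp)
  }
  counts <- round(split * n)
  counts[1] <- n - sum(counts[-1])
  membership <- factor(rep(names(split), counts), levels = names(split))
  membership <- membership[sample.int(n)]
  structure(list(phantoms = phantoms, split = membership, seed = seed),
            class = "phantom_dataset")
}

#' Extract 2-D training slices from phantoms
#'
#' Samples slices along `axis` from the given phantoms, preferring slices
#' that contain lumen voxels (`fg_bias` of the draws), and stacks them
#' into the array format expected by [train_daunet()].
#'
#' @param phantoms List of `cta_phantom` objects.
#' @param n_slices Total slices to draw.
#' @param axis Slice axis (default 3).
#' @param fg_bias Fraction of draws restricted to slices containing
#'   foreground.
#' @param seed Seed for the slice draw.
#' @return List with `x` (H x W x n intensities) and `y` (labels).
#' @export
phantom_slices <- function(phantoms, n_slices, axis = 3L, fg_bias = 0.9,
                           seed = 1L) {
  set.seed(seed)
  pool <- do.call(rbind, lapply(seq_along(phantoms), function(i) {
    m <- phantoms[[i]]$truth$mask
    nk <- dim(m)[axis]
    fg <- vapply(seq_len(nk), function(k)
      sum(slice_along(m, axis, k)) > 0, TRUE)
    cbind(i, seq_len(nk), fg)
  }))
  nfg <- round(fg_bias * n_slices)
  fg_pool <- which(pool[, 3] == 1)
  pick_fg <- fg_pool[sample.int(length(fg_pool), nfg, replace = TRUE)]
  pick_any <- sample.int(nrow(pool), n_slices - nfg, replace = TRUE)
  picks <- pool[c(pick_fg, pick_any), , drop = FALSE]
  s1 <- slice_along(phantoms[[1]]$volume, axis, 1L)
  x <- array(NA_real_, c(dim(s1), nrow(picks)))
  y <- array(NA_integer_, dim(x))
  for (r in seq_len(nrow(picks))) {
    ph <- phantoms[[picks[r, 1]]]
    x[, , r] <- slice_along(ph$volume, axis, picks[r, 2])
    y[, , r] <- slice_along(ph$truth$mask, axis, picks[r, 2])
  }
  list(x = x, y = y)
}

slice_along <- function(a, axis, k) {
  if (axis == 1L) a[k, , ] else if (axis == 2L) a[, k, ] else a[, , k]
}

#' Global-threshold slice segmenter
#'
#' Thresholding at the midpoint between tissue and lumen intensity is the
#' sanity floor for the phantom task; usable wherever a network is
#' expected (a function from a 2-D slice to integer labels).
#'
#' @param level Intensity threshold.
#' @return A function mapping a matrix to an integer 0/1 matrix.
#' @export
threshold_segmenter <- function(level) {
  function(slice) {
    out <- (slice >= level) * 1L
    storage.mode(out) <- "integer"
    out
  }
}
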