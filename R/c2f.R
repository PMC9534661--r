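# Two-stage coarse-to-fine segmentation: locate the artery at reduced
# resolution, crop the tightest bounding box (plus margin) around the
# coarse mask, segment finely inside the crop, and restore the fine mask
# to the original grid by zero padding.  Index conventions are 0-based,
# half-open [low, high) throughout the crop records.

# Block-average downsampling of an intensity volume by an integer factor
# per axis (extents must be divisible by the factor).
downsample_volume <- function(volume, factor) {
  if (all(factor == 1L)) return(volume)
  d <- dim(volume)
  f <- rep_len(as.integer(factor), 3L)
  if (any(d %% f != 0L))
    stop("volume extents must be divisible by the downsampling factor")
  dn <- d %/% f
  a <- array(volume, c(f[1], dn[1], f[2], dn[2], f[3], dn[3]))
  a <- aperm(a, c(1L, 3L, 5L, 2L, 4L, 6L))
  dim(a) <- c(prod(f), prod(dn))
  array(colMeans(a), dn)
}

# Nearest-neighbour upsampling of a label mask by an integer factor.
upsample_labels <- function(mask, factor) {
  if (all(factor == 1L)) return(mask)
  f <- rep_len(as.integer(factor), 3L)
  d <- dim(mask)
  mask[rep(seq_len(d[1]), each = f[1]),
       rep(seq_len(d[2]), each = f[2]),
       rep(seq_len(d[3]), each = f[3])]
}

#' Coarse artery localisation at reduced resolution
#'
#' Downsamples the volume by `down_factor` (block averaging), segments it
#' with the coarse network, and restores the labels to the original grid
#' with nearest-neighbour interpolation.
#'
#' @param volume 3-D intensity array.
#' @param coarse_net A `daunet_fit` or a function mapping a 2-D slice to an
#'   integer label matrix (test doubles are accepted).
#' @param down_factor Integer downsampling factor per axis.
#' @param axis Slice axis for the 2-D network.
#' @return Integer mask of `volume`'s shape.  When no artery voxel is
#'   found the mask is all zero and carries attribute `no_artery = TRUE`.
#' @export
coarse_segment <- function(volume, coarse_net, down_factor = 2L, axis = 3L) {
  stopifnot(down_factor >= 1L)
  lo <- downsample_volume(volume, down_factor)
  mlo <- predict_volume(coarse_net, lo, axis = axis)
  mask <- upsample_labels(mlo, down_factor)
  if (!any(mask != 0L)) attr(mask, "no_artery") <- TRUE
  mask
}

#' Crop a volume to the bounding box of a coarse mask
#'
#' The box is the tightest axis-aligned box containing all foreground,
#' expanded by `margin` voxels per side and clipped to the volume.
#'
#' @param volume 3-D array to crop.
#' @param coarse_mask Non-empty binary mask aligned with `volume`.
#' @param margin Context voxels added on every side.
#' @return List with the cropped sub-volume `volume` and a `crop_record`
#'   (fields `bbox_low`, `bbox_high` as 0-based half-open indices,
#'   `original_shape`, `margin`).
#' @export
crop_to_bbox <- function(volume, coarse_mask, margin = 8L) {
  d <- dim(volume)
  stopifnot(all(dim(coarse_mask) == d))
  fg <- which(coarse_mask != 0L, arr.ind = TRUE)
  if (nrow(fg) == 0L) stop("coarse mask is empty; no box to crop")
  low <- pmax(apply(fg, 2, min) - 1L - margin, 0L)
  high <- pmin(apply(fg, 2, max) + margin, d)
  rec <- structure(list(bbox_low = as.integer(low),
                        bbox_high = as.integer(high),
                        original_shape = as.integer(d),
                        margin = as.integer(margin)),
                   class = "crop_record")
  sub <- volume[(low[1] + 1L):high[1], (low[2] + 1L):high[2],
                (low[3] + 1L):high[3], drop = FALSE]
  list(volume = sub, record = rec)
}

#' @export
print.crop_record <- function(x, ...) {
  cat(sprintf("crop record: [%s) of %s, margin %d\n",
              paste(x$bbox_low, x$bbox_high, sep = ",", collapse = ") x ["),
              paste(x$original_shape, collapse = "x"), x$margin))
  invisible(x)
}

#' Restore a cropped mask to the original grid by zero padding
#'
#' @param fine_mask Mask with the crop's shape.
#' @param record A `crop_record` from [crop_to_bbox()].
#' @return Integer mask of the recorded original shape, zero outside the
#'   box.
#' @export
restore_to_grid <- function(fine_mask, record) {
  stopifnot(inherits(record, "crop_record"))
  want <- record$bbox_high - record$bbox_low
  if (!all(dim(fine_mask) == want))
    stop("fine mask shape does not match the crop record")
  out <- array(0L, record$original_shape)
  out[(record$bbox_low[1] + 1L):record$bbox_high[1],
      (record$bbox_low[2] + 1L):record$bbox_high[2],
      (record$bbox_low[3] + 1L):record$bbox_high[3]] <- fine_mask
  out
}

#' Coarse-to-fine artery segmentation
#'
#' Runs [coarse_segment()], crops the margin-expanded bounding box of the
#' coarse mask, segments the crop with the fine network, and restores the
#' result to the input grid.  The output foreground is therefore contained
#' in the expanded coarse box by construction.
#'
#' @param volume 3-D intensity array.
#' @param coarse_net,fine_net `daunet_fit` objects or slice-segmenter
#'   functions.
#' @param down_factor Coarse-stage downsampling factor.
#' @param margin Context voxels around the coarse box.
#' @param axis Slice axis for the 2-D networks.
#' @return Integer mask of `volume`'s shape with attributes `no_artery`
#'   (logical) and `crop_record` (when an artery was found).
#' @export
c2f_segment <- function(volume, coarse_net, fine_net, down_factor = 2L,
                        margin = 8L, axis = 3L) {
  coarse <- coarse_segment(volume, coarse_net, down_factor, axis = axis)
  if (isTRUE(attr(coarse, "no_artery"))) {
    out <- array(0L, dim(volume))
    attr(out, "no_artery") <- TRUE
    return(out)
  }
  cr <- crop_to_bbox(volume, coarse, margin = margin)
  fine <- predict_volume(fine_net, cr$volume, axis = axis)
  out <- restore_to_grid(fine, cr$record)
  attr(out, "no_artery") <- FALSE
  attr(out, "crop_record") <- cr$record
  out
}
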