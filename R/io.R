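# Volumetric NIfTI I/O and run configuration.

#' Read a 3-D volume from a NIfTI file
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @param mask Validate the volume as an integer label mask.
#' @return 3-D array with attribute `spacing` (mm per axis).
#' @export
read_volume <- function(path, mask = FALSE) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop("expected 3-D volume data, got ", length(dim(arr)), "-D: ", path)
  sp <- RNifti::pixdim(img)[seq_len(3)]
  if (mask) {
    if (any(arr != round(arr)))
      stop("mask volume has non-integer values: ", path)
    storage.mode(arr) <- "integer"
  }
  attr(arr, "spacing") <- sp
  arr
}

#' Write a 3-D volume to a NIfTI file
#'
#' Integer arrays are stored with an integer datatype so label masks
#' round-trip bit-identically; voxel spacing is taken from the `spacing`
#' attribute unless given.
#'
#' @param volume 3-D array (attribute `spacing` honoured).
#' @param path Output path.
#' @param spacing Voxel size per axis in mm.
#' @return The path, invisibly.
#' @export
write_volume <- function(volume, path, spacing = attr(volume, "spacing")) {
  stopifnot(length(dim(volume)) == 3L)
  if (is.null(spacing)) spacing <- c(1, 1, 1)
  arr <- volume
  attributes(arr) <- list(dim = dim(volume))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep_len(spacing, 3L)
  dtype <- if (is.integer(arr)) "int32" else "double"
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

#' Default run configuration
#'
#' One nested list collects every tunable of the pipeline: network
#' hyperparameters, coarse-to-fine settings, training schedule, phantom
#' parameters and localization thresholds.  It round-trips losslessly
#' through YAML.
#'
#' @return A named list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    network = list(depth = 4L, base_channels = 16L, se_reduction = 4L,
                   num_classes = 2L, supervision_levels = 4L,
                   use_se = TRUE, use_attention = TRUE),
    c2f = list(down_factor = 2L, margin = 8L),
    training = list(epochs = 5L, lr = 1e-3, batch_size = 8L,
                    optimizer = "adam", n_slices = 200L, seed = 1L),
    phantom = list(shape = c(64L, 64L, 64L), spacing = c(1, 1, 1),
                   main_vessel_radius = c(2.5, 3.5),
                   perforator_radius = c(1.2, 1.6),
                   n_perforators = c(2L, 4L), noise_sd = c(15, 15),
                   lumen_intensity_mean = 300, tissue_intensity_mean = 50),
    localization = list(threshold_mm = 10, candidate_sites = NULL),
    # optional scanner metadata, recorded but not used computationally
    scanner = list(voltage_kv = 120, current_ma = 300,
                   slice_thickness_mm = 0.5, slice_spacing_mm = 0.3)),
    class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file; missing fields fall back to
#'   [default_run_config()].
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    for (sec in names(user)) {
      for (key in names(user[[sec]])) {
        val <- user[[sec]][[key]]
        if (is.null(val)) cfg[[sec]][key] <- list(NULL)  # keep explicit nulls
        else cfg[[sec]][[key]] <- val
      }
    }
  }
  cfg
}

#' Write a run configuration to YAML
#' @param cfg A `run_config` list.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

config_network_spec <- function(cfg) {
  n <- cfg$network
  network_spec(depth = n$depth, base_channels = n$base_channels,
               se_reduction = n$se_reduction, num_classes = n$num_classes,
               supervision_levels = n$supervision_levels,
               use_se = n$use_se, use_attention = n$use_attention)
}
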