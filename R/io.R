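#' Write and read map images
#'
#' Maps (PSL, activity, distribution volumes, tHct) are stored as NIfTI
#' float volumes with NaN encoding masked pixels; label images and masks
#' as NIfTI integer volumes. Round-trips are lossless.
#'
#' @param mat Numeric or integer matrix.
#' @param path Output path (".nii" or ".nii.gz").
#' @return \code{write_map}/\code{write_labels} return \code{path}
#'   invisibly; \code{read_map} returns a numeric matrix,
#'   \code{read_labels} an integer matrix.
#' @export
write_map <- function(mat, path) {
  stopifnot(is.matrix(mat))
  RNifti::writeNifti(RNifti::asNifti(mat), path, datatype = "double")
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  a <- as.array(RNifti::readNifti(path))
  matrix(as.numeric(a), dim(a)[1], dim(a)[2])
}

#' @rdname write_map
#' @export
write_labels <- function(mat, path) {
  stopifnot(is.matrix(mat))
  storage.mode(mat) <- "integer"
  RNifti::writeNifti(RNifti::asNifti(mat), path, datatype = "int16")
  invisible(path)
}

#' @rdname write_map
#' @export
read_labels <- function(path) {
  a <- as.array(RNifti::readNifti(path))
  matrix(as.integer(a), dim(a)[1], dim(a)[2])
}

#' Read and write run configurations
#'
#' Configurations are JSON with a \code{schema_version} field; unknown
#' versions are an explicit error. \code{default_run_config} returns the
#' fully resolved default configuration (control-brain phantom, default
#' isotopes, windows, panel, layout and noise model).
#'
#' @return A named list (the configuration).
#' @export
default_run_config <- function() {
  list(
    schema_version = 1L,
    isotopes = list(i125 = list(half_life_h = 59.4 * 24),
                    tc99m = list(half_life_h = 6.0)),
    exposures = list(exp1 = list(start_h = 2, duration_h = 16),
                     exp2 = list(start_h = 170, duration_h = 168)),
    phantom = list(nrow = 160L, ncol = 160L, pixel_size_um = 50,
                   preset = "control_brain", lesion = FALSE,
                   lesion_vv_pct = 1.1, lesion_thct = 0.18),
    panel = list(dose_tc_mbq = 45.2, dose_i_mbq = 3.9,
                 blood_mass_g = 18.8, bhct = 0.401),
    layout = list(dilution = 50, gain_tc = 1.0e8, gain_i = 1.6e8,
                  thickness_um = 100, density_g_ml = 1.04,
                  pure_i_conc_mbq_g = 0.5, leak_i_frac = 0),
    noise = list(enabled = TRUE, psl_per_count = 0.05, read_sd = 0.2,
                 bg_offset = 1.0),
    offset = list(dx_px = 0, dy_px = 0, theta_deg = 0),
    vv_min = 0.5
  )
}

#' @rdname default_run_config
#' @param config A configuration list.
#' @export
validate_config <- function(config) {
  if (is.null(config$schema_version))
    stop("configuration has no schema_version")
  if (config$schema_version != 1L)
    stop("unknown configuration schema version: ", config$schema_version)
  p <- config$panel
  if (!is.null(p$bhct) && (p$bhct <= 0 || p$bhct >= 1))
    stop("panel bhct must be in (0, 1)")
  e <- config$exposures
  check_window_pair(exposure_window(e$exp1$start_h, e$exp1$duration_h),
                    exposure_window(e$exp2$start_h, e$exp2$duration_h))
  invisible(TRUE)
}

#' @rdname default_run_config
#' @param path Path of a JSON configuration file.
#' @export
read_run_config <- function(path) {
  config <- jsonlite::read_json(path, simplifyVector = TRUE)
  config <- utils::modifyList(default_run_config(), config)
  validate_config(config)
  config
}

#' @rdname default_run_config
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# encode the layout masks as one label image:
# 0 background, 1 tissue, 2 diluted-blood spot, 3 pure-125I spot
layout_label_image <- function(layout) {
  m <- matrix(0L, nrow(layout$tissue_mask), ncol(layout$tissue_mask))
  m[layout$tissue_mask] <- 1L
  m[layout$blood_mask] <- 2L
  m[layout$pure_i_mask] <- 3L
  m
}

masks_from_layout_labels <- function(labels) {
  list(tissue_mask = labels == 1L, blood_mask = labels == 2L,
       pure_i_mask = labels == 3L, bg_mask = labels == 0L)
}
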