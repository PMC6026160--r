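#' Build a simulated scene from a run configuration
#'
#' Resolves a configuration into the objects of one simulated animal:
#' ground-truth phantom, blood panel, scene layout, exposure windows and
#' isotope specs.
#'
#' @param config Configuration list (see \code{\link{default_run_config}}).
#' @param bhct Optional override of the panel hematocrit.
#' @return A list: \code{truth}, \code{panel}, \code{layout},
#'   \code{windows}, \code{isotopes}, \code{config}.
#' @export
build_scene <- function(config = default_run_config(), bhct = NULL) {
  validate_config(config)
  ph <- config$phantom
  regions <- switch(ph$preset,
    control_brain = control_brain_regions(lesion = isTRUE(ph$lesion),
                                          lesion_vv_pct = ph$lesion_vv_pct,
                                          lesion_thct = ph$lesion_thct),
    stop("unknown phantom preset: ", ph$preset))
  truth <- make_phantom(regions, nrow = ph$nrow, ncol = ph$ncol,
                        pixel_size_um = ph$pixel_size_um)
  pn <- config$panel
  panel <- blood_panel_from_doses(dose_tc_mbq = pn$dose_tc_mbq,
                                  dose_i_mbq = pn$dose_i_mbq,
                                  blood_mass_g = pn$blood_mass_g,
                                  bhct = if (is.null(bhct)) pn$bhct else bhct)
  ly <- config$layout
  layout <- scene_layout(truth, dilution = ly$dilution,
                         pure_i_conc_mbq_g = ly$pure_i_conc_mbq_g,
                         gain_tc = ly$gain_tc, gain_i = ly$gain_i,
                         thickness_um = ly$thickness_um,
                         density_g_ml = ly$density_g_ml,
                         noise = config$noise,
                         leak_i_frac = ly$leak_i_frac)
  e <- config$exposures
  windows <- list(exp1 = exposure_window(e$exp1$start_h, e$exp1$duration_h),
                  exp2 = exposure_window(e$exp2$start_h, e$exp2$duration_h))
  isotopes <- list(tc = iso_tc99m(config$isotopes$tc99m$half_life_h),
                   i = iso_i125(config$isotopes$i125$half_life_h))
  list(truth = truth, panel = panel, layout = layout, windows = windows,
       isotopes = isotopes, config = config)
}

#' Run one animal through the full analysis chain in memory
#'
#' Simulates the paired exposures (applying the configured rigid offset
#' to the second one), then runs the separation, calibration and
#' quantification exactly as the plate-analysis protocol prescribes:
#' background subtraction, pure-spot intensity correction,
#' co-registration, subtraction, PSL-to-MBq/g calibration against the
#' diluted-blood standard, distribution volumes, and map composition.
#'
#' @param scene A scene from \code{\link{build_scene}}.
#' @param seed Integer seed for the rendering noise.
#' @param register Run the rigid registration step; if \code{FALSE}
#'   (e.g. when the configured offset is zero) the identity transform is
#'   used.
#' @return A list: \code{exposures} (raw rendered images), \code{sep}
#'   (\code{\link{separation_result}}), \code{quant} (maps and activity
#'   images), \code{scene}.
#' @export
analyze_scene <- function(scene, seed = 1L, register = NULL) {
  off <- scene$config$offset
  has_offset <- off$dx_px != 0 || off$dy_px != 0 || off$theta_deg != 0
  if (is.null(register)) register <- has_offset
  rend <- render_exposures(scene$truth, scene$panel, scene$layout,
                           windows = scene$windows, seed = seed,
                           isotopes = scene$isotopes)
  exp2_raw <- if (has_offset)
    apply_rigid_offset(rend$exp2, off$dx_px, off$dy_px, off$theta_deg,
                       fill = scene$layout$noise$bg_offset)
  else rend$exp2
  b1 <- subtract_background(rend$exp1, scene$layout$bg_mask)
  b2 <- subtract_background(exp2_raw, scene$layout$bg_mask)
  # with a repositioned sheet the spot ROI is placed on each image and
  # eroded away from partially-sampled edge pixels
  mask1 <- scene$layout$pure_i_mask
  mask2 <- if (has_offset) {
    erode_mask(locate_mask(b2, mask1), 2L)
  } else mask1
  if (has_offset) mask1 <- erode_mask(mask1, 2L)
  f <- estimate_i125_correction(b1, b2, mask1, mask2)
  transform <- if (register)
    register_exposures(b1, b2, rotation = TRUE)
  else list(dx_px = 0, dy_px = 0, theta_deg = 0, score = NA_real_)
  sep <- separate_exposures(b1, b2, f, transform,
                            tissue_mask = scene$layout$tissue_mask)
  quant <- quantify_maps(sep, scene$panel, scene$layout,
                         vv_min = scene$config$vv_min)
  list(exposures = list(exp1 = rend$exp1, exp2 = exp2_raw,
                        expected1 = rend$expected1,
                        expected2 = rend$expected2),
       sep = sep, quant = quant, scene = scene)
}

#' Run the full pipeline and write a reproducible output directory
#'
#' Executes simulate, separate, quantify and report for one
#' configuration and writes every map, mask, table and derived scalar,
#' together with the resolved configuration and seed, so the directory
#' is fully reproducible from its own provenance record.
#'
#' @param config Configuration list or path to a JSON configuration.
#' @param seed Integer seed.
#' @param out_dir Output directory (created; must not contain a previous
#'   report).
#' @return Invisibly, the in-memory results of
#'   \code{\link{analyze_scene}} plus \code{roi} (data.frame).
#' @export
run_pipeline <- function(config = default_run_config(), seed = 1L,
                         out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  scene <- build_scene(config)   # validates before any output is written
  res <- analyze_scene(scene, seed = seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_map(res$exposures$exp1$psl, file.path(out_dir, "exp1.nii.gz"))
  write_map(res$exposures$exp2$psl, file.path(out_dir, "exp2.nii.gz"))
  write_labels(scene$truth$labels, file.path(out_dir, "labels.nii.gz"))
  write_labels(layout_label_image(scene$layout),
               file.path(out_dir, "layout_masks.nii.gz"))
  for (nm in c("vv_pct", "thct_frac", "vrbc_pct", "vp_pct"))
    write_map(scene$truth[[nm]],
              file.path(out_dir, paste0("truth_", sub("_.*", "", nm),
                                        ".nii.gz")))
  write_map(res$sep$psl_tc$psl, file.path(out_dir, "psl_tc.nii.gz"))
  write_map(res$sep$psl_i$psl, file.path(out_dir, "psl_i.nii.gz"))
  maps <- res$quant$maps
  write_map(maps$vp_pct, file.path(out_dir, "vp.nii.gz"))
  write_map(maps$vrbc_pct, file.path(out_dir, "vrbc.nii.gz"))
  write_map(maps$vv_pct, file.path(out_dir, "vv.nii.gz"))
  write_map(maps$thct_frac, file.path(out_dir, "thct.nii.gz"))
  region_names <- vapply(scene$truth$regions, function(r) r$name, "")
  names(region_names) <- vapply(scene$truth$regions,
                                function(r) as.character(r$label), "")
  roi <- roi_report(maps$thct_frac, scene$truth$labels, region_names)
  roi_vv <- roi_report(maps$vv_pct, scene$truth$labels, region_names)
  utils::write.csv(roi, file.path(out_dir, "roi_thct.csv"),
                   row.names = FALSE)
  utils::write.csv(roi_vv, file.path(out_dir, "roi_vv.csv"),
                   row.names = FALSE)
  panel <- scene$panel
  jsonlite::write_json(unclass(panel), file.path(out_dir, "panel.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(f_correction = res$sep$f_correction,
         transform = res$sep$transform[c("dx_px", "dy_px", "theta_deg")],
         negatives_clamped_fraction = res$sep$negatives_clamped_fraction),
    file.path(out_dir, "separation_report.json"), auto_unbox = TRUE,
    digits = NA)
  jsonlite::write_json(
    list(calib_tc_mbq_g_per_psl = res$quant$act_tc$calib_factor,
         calib_i_mbq_g_per_psl = res$quant$act_i$calib_factor,
         arg_bhct = arg_bhct(maps, scene$layout$blood_mask),
         capillary_bhct = panel$bhct_capillary),
    file.path(out_dir, "calib_report.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(config = config, seed = seed),
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(res, list(roi = roi, roi_vv = roi_vv)))
}

#' Simulate a multi-animal whole-blood hematocrit study
#'
#' The synthetic analogue of the three-group method-validation
#' experiment: animals in hemodilution, control and erythropoietin
#' groups (default group-mean hematocrits 0.34, 0.40 and 0.50, between-
#' animal SD 0.02) are each rendered and analysed, and their whole-blood
#' hematocrit is estimated three ways: the configured truth (the
#' capillary method), the autoradiographic blood-spot estimate
#' (\code{\link{arg_bhct}}), and gamma-well counting of a whole-blood
#' sample with multiplicative counting noise.
#'
#' @param n_per_group Animals per group.
#' @param group_bhct Named group-mean hematocrits.
#' @param sd_bhct Between-animal SD of true hematocrit.
#' @param config Run configuration.
#' @param seed Integer seed.
#' @param gwc_cv Coefficient of variation of the gamma-well counts.
#' @return A data.frame: \code{animal}, \code{group}, \code{bhct_true},
#'   \code{bhct_arg}, \code{bhct_gwc}.
#' @export
simulate_bhct_study <- function(n_per_group = 8,
                                group_bhct = c(hemodilution = 0.34,
                                               control = 0.40,
                                               epo = 0.50),
                                sd_bhct = 0.02,
                                config = default_run_config(),
                                seed = 1L, gwc_cv = 0.02) {
  set.seed(seed)
  groups <- rep(names(group_bhct), each = n_per_group)
  bhct_true <- pmin(0.65, pmax(0.15,
    stats::rnorm(length(groups), group_bhct[groups], sd_bhct)))
  animal_seeds <- sample.int(2^20, length(groups))
  out <- vector("list", length(groups))
  for (k in seq_along(groups)) {
    scene <- build_scene(config, bhct = bhct_true[k])
    res <- analyze_scene(scene, seed = animal_seeds[k], register = FALSE)
    b_arg <- arg_bhct(res$quant$maps, scene$layout$blood_mask)
    set.seed(animal_seeds[k] + 7L)
    samp <- gwc_sample("blood",
                       a_tc = scene$panel$c_tc_blood *
                         (1 + stats::rnorm(1, 0, gwc_cv)),
                       a_i = scene$panel$c_i_blood *
                         (1 + stats::rnorm(1, 0, gwc_cv)),
                       mass_g = 0.5)
    b_gwc <- gwc_hct(samp, scene$panel)
    out[[k]] <- data.frame(animal = k, group = groups[k],
                           bhct_true = bhct_true[k], bhct_arg = b_arg,
                           bhct_gwc = b_gwc)
  }
  do.call(rbind, out)
}

#' Gamma-well-counting table
#'
#' Applies the scalar quantification path to a table of counted samples:
#' per-sample RBC, plasma and vascular distribution volumes, hematocrit,
#' and percent injected dose per gram for both isotopes.
#'
#' @param samples A data.frame with columns \code{tissue_id},
#'   \code{mass_g}, \code{a_tc_mbq_g}, \code{a_i_mbq_g} (activities at
#'   t = 0).
#' @param panel A \code{\link{blood_panel}}.
#' @return The input with columns \code{vrbc_pct}, \code{vp_pct},
#'   \code{vv_pct}, \code{hct_pct}, \code{pid_g_tc}, \code{pid_g_i}
#'   appended.
#' @export
gwc_table <- function(samples, panel) {
  stopifnot(is.data.frame(samples), inherits(panel, "blood_panel"))
  need <- c("tissue_id", "mass_g", "a_tc_mbq_g", "a_i_mbq_g")
  if (!all(need %in% names(samples)))
    stop("samples must have columns: ", paste(need, collapse = ", "))
  vrbc <- 100 * samples$a_tc_mbq_g / panel$c_tc_rbc
  vp <- 100 * samples$a_i_mbq_g / panel$c_i_plasma
  samples$vrbc_pct <- vrbc
  samples$vp_pct <- vp
  samples$vv_pct <- vrbc + vp
  samples$hct_pct <- 100 * vrbc / (vrbc + vp)
  samples$pid_g_tc <- percent_id_per_g(samples$a_tc_mbq_g, panel$dose_tc_mbq)
  samples$pid_g_i <- percent_id_per_g(samples$a_i_mbq_g, panel$dose_i_mbq)
  samples
}
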