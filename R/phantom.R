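#' Photostimulated-luminescence image
#'
#' One phosphor-plate exposure: a 2-D matrix of PSL values per pixel plus
#' the exposure window it was collected in.
#'
#' @param psl Numeric matrix of PSL per pixel (rows x cols).
#' @param window The \code{\link{exposure_window}} of the exposure.
#' @return An object of class \code{psl_image}.
#' @export
psl_image <- function(psl, window) {
  stopifnot(is.matrix(psl), is.numeric(psl),
            inherits(window, "exposure_window"))
  structure(list(psl = psl, window = window), class = "psl_image")
}

#' @export
print.psl_image <- function(x, ...) {
  cat(sprintf("<psl_image %d x %d, window [%g, %g] h, mean %.3g PSL>\n",
              nrow(x$psl), ncol(x$psl), x$window$start_h,
              x$window$start_h + x$window$duration_h, mean(x$psl)))
  invisible(x)
}

#' Blood reference panel
#'
#' Isotope concentrations of the injected animal's blood at the reference
#' time t = 0: 99mTc (red-blood-cell bound) and 125I (plasma bound) in
#' whole blood, plus the concentrations of the centrifuged RBC and plasma
#' fractions and the capillary-tube whole-blood hematocrit. When built
#' from a whole-blood description the fractions follow from mass balance:
#' \code{c_tc_rbc = c_tc_blood / bhct} and
#' \code{c_i_plasma = c_i_blood / (1 - bhct)} (each tracer is confined to
#' its own blood compartment).
#'
#' @param c_tc_blood,c_i_blood Whole-blood concentrations, MBq/g at t = 0.
#' @param bhct_capillary Whole-blood hematocrit (fraction in (0, 1)).
#' @param c_tc_rbc,c_i_plasma Fraction concentrations, MBq/g at t = 0;
#'   derived from whole blood and \code{bhct_capillary} when omitted.
#' @param dose_tc_mbq,dose_i_mbq Injected doses in MBq (bookkeeping only;
#'   used by \code{\link{percent_id_per_g}}).
#' @return An object of class \code{blood_panel}.
#' @examples
#' make_blood_panel(c_tc_blood = 0.8, c_i_blood = 0.06, bhct = 0.40)
#' @export
blood_panel <- function(c_tc_blood, c_i_blood, bhct_capillary,
                        c_tc_rbc = c_tc_blood / bhct_capillary,
                        c_i_plasma = c_i_blood / (1 - bhct_capillary),
                        dose_tc_mbq = 45.2, dose_i_mbq = 3.9) {
  if (!is.numeric(bhct_capillary) || length(bhct_capillary) != 1L ||
      bhct_capillary <= 0 || bhct_capillary >= 1)
    stop("bhct_capillary must be in (0, 1)")
  conc <- c(c_tc_blood, c_i_blood, c_tc_rbc, c_i_plasma)
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("concentrations must be finite and non-negative")
  structure(list(c_tc_blood = c_tc_blood, c_i_blood = c_i_blood,
                 c_tc_rbc = c_tc_rbc, c_i_plasma = c_i_plasma,
                 bhct_capillary = bhct_capillary,
                 dose_tc_mbq = dose_tc_mbq, dose_i_mbq = dose_i_mbq),
            class = "blood_panel")
}

#' @rdname blood_panel
#' @param bhct Whole-blood hematocrit, alias of \code{bhct_capillary}.
#' @export
make_blood_panel <- function(c_tc_blood, c_i_blood, bhct, ...) {
  blood_panel(c_tc_blood, c_i_blood, bhct_capillary = bhct, ...)
}

#' Blood panel from injected doses
#'
#' Builds a whole-blood panel by diluting the injected doses into the
#' animal's blood pool (default 7\% of body weight, the usual rat value).
#' Default doses are 45.2 MBq 99mTc-RBC and 3.9 MBq 125I-albumin.
#'
#' @param dose_tc_mbq,dose_i_mbq Injected doses in MBq.
#' @param blood_mass_g Mass of the blood pool in grams.
#' @param bhct Whole-blood hematocrit (fraction).
#' @return A \code{\link{blood_panel}}.
#' @export
blood_panel_from_doses <- function(dose_tc_mbq = 45.2, dose_i_mbq = 3.9,
                                   blood_mass_g = 18.8, bhct = 0.401) {
  if (blood_mass_g <= 0) stop("blood_mass_g must be positive")
  if (dose_tc_mbq < 0 || dose_i_mbq < 0) stop("doses must be non-negative")
  blood_panel(c_tc_blood = dose_tc_mbq / blood_mass_g,
              c_i_blood = dose_i_mbq / blood_mass_g,
              bhct_capillary = bhct,
              dose_tc_mbq = dose_tc_mbq, dose_i_mbq = dose_i_mbq)
}

#' @export
print.blood_panel <- function(x, ...) {
  cat(sprintf(paste0("<blood_panel bHct %.3f; Tc blood %.4g, RBC %.4g MBq/g; ",
                     "I blood %.4g, plasma %.4g MBq/g>\n"),
              x$bhct_capillary, x$c_tc_blood, x$c_tc_rbc,
              x$c_i_blood, x$c_i_plasma))
  invisible(x)
}

# ---- phantom geometry ------------------------------------------------------

#' Define a phantom region
#'
#' Regions are painted onto the label image in list order. A region whose
#' footprint touches an already-labelled pixel is a configuration error
#' unless \code{overlay = TRUE}, in which case it replaces the underlying
#' label (used for vessel disks and lesions embedded in tissue).
#'
#' Shapes (pixel coordinates, row/col, 1-based):
#' \itemize{
#'   \item \code{"ellipse"}: centre (\code{cy}, \code{cx}), semi-axes
#'     \code{ry}, \code{rx}; optional inner semi-axes \code{ry_in},
#'     \code{rx_in} make it an elliptic annulus.
#'   \item \code{"disk"}: centre and radius \code{r}.
#'   \item \code{"rect"}: rows \code{r0..r1}, cols \code{c0..c1}.
#' }
#'
#' @param name Region name.
#' @param label Integer label code (> 0).
#' @param shape One of \code{"ellipse"}, \code{"disk"}, \code{"rect"}.
#' @param vv_pct Vascular volume of the region, mL/100 g (treated as \%).
#' @param thct_frac Tissue hematocrit of the region, fraction in [0, 1).
#' @param overlay Paint over previously labelled pixels instead of erroring.
#' @param ... Shape parameters (see above).
#' @return A \code{phantom_region} list.
#' @export
phantom_region <- function(name, label, shape, vv_pct, thct_frac,
                           overlay = FALSE, ...) {
  if (!(shape %in% c("ellipse", "disk", "rect")))
    stop("unknown shape: ", shape)
  if (thct_frac < 0 || thct_frac >= 1) stop("thct_frac must be in [0, 1)")
  if (vv_pct < 0) stop("vv_pct must be >= 0")
  if (label <= 0) stop("label must be a positive integer")
  structure(c(list(name = name, label = as.integer(label), shape = shape,
                   vv_pct = vv_pct, thct_frac = thct_frac, overlay = overlay),
              list(...)),
            class = "phantom_region")
}

region_footprint <- function(reg, nrow, ncol) {
  rr <- matrix(seq_len(nrow), nrow, ncol)
  cc <- matrix(seq_len(ncol), nrow, ncol, byrow = TRUE)
  switch(reg$shape,
    ellipse = {
      u <- ((rr - reg$cy) / reg$ry)^2 + ((cc - reg$cx) / reg$rx)^2
      inside <- u <= 1
      if (!is.null(reg$ry_in)) {
        v <- ((rr - reg$cy) / reg$ry_in)^2 + ((cc - reg$cx) / reg$rx_in)^2
        inside & v > 1
      } else inside
    },
    disk = (rr - reg$cy)^2 + (cc - reg$cx)^2 <= reg$r^2,
    rect = rr >= reg$r0 & rr <= reg$r1 & cc >= reg$c0 & cc <= reg$c1)
}

#' Default control-brain phantom regions
#'
#' A coronal-section-like phantom: a cortical rim, deep white matter, two
#' striatal disks, and three large-vessel disks whose vascular volume is
#' an order of magnitude above the surrounding tissue but whose
#' hematocrit matches it. Regional hematocrits are the control-brain
#' values: cortex 0.296, striatum 0.288, white matter 0.280; vascular
#' volumes are larger in cortex than striatum, as observed.
#'
#' @param lesion If \code{TRUE}, embed a low-hematocrit lesion disk
#'   (label 8) in the right striatum.
#' @param lesion_vv_pct,lesion_thct Lesion vascular volume and hematocrit.
#' @return A list of \code{\link{phantom_region}}s.
#' @export
control_brain_regions <- function(lesion = FALSE, lesion_vv_pct = 1.1,
                                  lesion_thct = 0.18) {
  regs <- list(
    phantom_region("cortex", 1L, "ellipse", vv_pct = 3.5, thct_frac = 0.296,
                   cy = 78, cx = 80, ry = 52, rx = 42,
                   ry_in = 38, rx_in = 28),
    phantom_region("white_matter", 3L, "ellipse", vv_pct = 2.0,
                   thct_frac = 0.280, cy = 78, cx = 80, ry = 38, rx = 28),
    phantom_region("striatum_l", 2L, "disk", vv_pct = 2.8, thct_frac = 0.288,
                   overlay = TRUE, cy = 78, cx = 66, r = 11),
    phantom_region("striatum_r", 2L, "disk", vv_pct = 2.8, thct_frac = 0.288,
                   overlay = TRUE, cy = 78, cx = 94, r = 11),
    phantom_region("vessel_1", 9L, "disk", vv_pct = 30, thct_frac = 0.296,
                   overlay = TRUE, cy = 44, cx = 70, r = 2),
    phantom_region("vessel_2", 9L, "disk", vv_pct = 30, thct_frac = 0.296,
                   overlay = TRUE, cy = 110, cx = 92, r = 2),
    phantom_region("vessel_3", 9L, "disk", vv_pct = 30, thct_frac = 0.280,
                   overlay = TRUE, cy = 78, cx = 80, r = 2))
  if (lesion)
    regs <- c(regs, list(
      phantom_region("lesion", 8L, "disk", vv_pct = lesion_vv_pct,
                     thct_frac = lesion_thct, overlay = TRUE,
                     cy = 78, cx = 94, r = 8)))
  regs
}

#' Build a ground-truth phantom
#'
#' Rasterises a list of regions into a label image and per-pixel truth
#' maps for vascular volume (Vv), tissue hematocrit (tHct), and the
#' derived red-blood-cell and plasma distribution volumes
#' \code{vrbc = thct * vv} and \code{vp = (1 - thct) * vv} (so
#' \code{vrbc + vp == vv} exactly). Background pixels (label 0) carry
#' zero volumes and undefined (NaN) hematocrit.
#'
#' @param regions List of \code{\link{phantom_region}}s; default the
#'   control brain of \code{\link{control_brain_regions}}.
#' @param nrow,ncol Grid size in pixels.
#' @param pixel_size_um Pixel edge length in micrometres.
#' @return An object of class \code{phantom_truth} with elements
#'   \code{labels} (integer matrix), \code{vv_pct}, \code{thct_frac},
#'   \code{vrbc_pct}, \code{vp_pct} (numeric matrices),
#'   \code{pixel_size_um}, and \code{regions}.
#' @examples
#' ph <- make_phantom(list(phantom_region("roi", 1, "rect", 3.0, 0.29,
#'                                        r0 = 2, r1 = 9, c0 = 2, c1 = 9)),
#'                    nrow = 12, ncol = 12)
#' unique(ph$vrbc_pct[ph$labels == 1])  # 0.29 * 3.0 = 0.87
#' @export
make_phantom <- function(regions = control_brain_regions(),
                         nrow = 160, ncol = 160, pixel_size_um = 50) {
  labels <- matrix(0L, nrow, ncol)
  vv <- matrix(0, nrow, ncol)
  thct <- matrix(NaN, nrow, ncol)
  for (reg in regions) {
    fp <- region_footprint(reg, nrow, ncol)
    if (!any(fp)) stop("region '", reg$name, "' is empty on this grid")
    if (!isTRUE(reg$overlay) && any(labels[fp] != 0L))
      stop("region '", reg$name, "' overlaps an existing region; ",
           "set overlay = TRUE to paint over")
    labels[fp] <- reg$label
    vv[fp] <- reg$vv_pct
    thct[fp] <- reg$thct_frac
  }
  vrbc <- ifelse(labels > 0L, thct * vv, 0)
  vp <- ifelse(labels > 0L, (1 - thct) * vv, 0)
  structure(list(labels = labels, vv_pct = vv, thct_frac = thct,
                 vrbc_pct = vrbc, vp_pct = vp,
                 pixel_size_um = pixel_size_um, regions = regions),
            class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth %d x %d, %d regions, %d labelled px>\n",
              nrow(x$labels), ncol(x$labels), length(x$regions),
              sum(x$labels > 0L)))
  invisible(x)
}

# ---- scene layout ----------------------------------------------------------

#' Scene layout: reference spots, plate gains, geometry, noise
#'
#' Places the internal references next to the tissue section, exactly as
#' on a real plate: a drop of pure 125I (inter-exposure intensity
#' correction) and a 1:50 diluted-blood cryosection (PSL-to-activity
#' calibration, carrying both isotopes). Holds the per-isotope plate
#' gains, the section geometry that converts concentration to activity
#' per pixel, and the noise model.
#'
#' Expected PSL per pixel and window is
#' \code{gain_iso * C_iso * mass_per_pixel * integrated_decay(iso, w)}
#' with \code{C_iso} in MBq/g at t = 0 and gains in PSL per decayed
#' MBq h. Noise (when enabled) is Poisson on photostimulated counts
#' (expected PSL divided by \code{psl_per_count}), plus additive Gaussian
#' read noise (\code{read_sd} PSL), plus a uniform background offset.
#'
#' @param truth A \code{\link{phantom_truth}} defining the grid and the
#'   tissue mask.
#' @param pure_i A \code{"disk"} or \code{"rect"} spec (list as accepted
#'   by \code{\link{phantom_region}} shape parameters) for the pure-125I
#'   drop.
#' @param blood_spot Same, for the diluted-blood spot.
#' @param dilution Blood-spot dilution factor (default 1:50).
#' @param pure_i_conc_mbq_g 125I concentration of the pure drop, MBq/g.
#' @param gain_tc,gain_i Plate gains, PSL per decayed MBq h per pixel
#'   mass; deliberately unequal by default so the pipeline must calibrate
#'   each isotope separately.
#' @param thickness_um Section thickness (default 100).
#' @param density_g_ml Section density (default 1.04); one value for the
#'   whole scene, as every cryosection is cut at the same thickness.
#' @param noise List: \code{enabled}, \code{psl_per_count} (PSL quantum
#'   per photostimulated count), \code{read_sd} (PSL), \code{bg_offset}
#'   (PSL).
#' @param leak_i_frac Optional fractional extravascular 125I accumulation
#'   in tissue (models albumin leakage; inflates Vp and depresses tHct).
#' @return An object of class \code{scene_layout} with logical masks
#'   \code{pure_i_mask}, \code{blood_mask}, \code{tissue_mask},
#'   \code{bg_mask} plus the physical parameters.
#' @export
scene_layout <- function(truth,
                         pure_i = list(shape = "disk", cy = 22, cx = 24,
                                       r = 8),
                         blood_spot = list(shape = "rect", r0 = 132,
                                           r1 = 150, c0 = 16, c1 = 56),
                         dilution = 50,
                         pure_i_conc_mbq_g = 0.5,
                         gain_tc = 1.0e8, gain_i = 1.6e8,
                         thickness_um = 100, density_g_ml = 1.04,
                         noise = list(enabled = TRUE, psl_per_count = 0.05,
                                      read_sd = 0.2, bg_offset = 1.0),
                         leak_i_frac = 0) {
  stopifnot(inherits(truth, "phantom_truth"))
  nr <- nrow(truth$labels); nc <- ncol(truth$labels)
  spot_mask <- function(sp) {
    reg <- do.call(phantom_region,
                   c(list(name = "spot", label = 1L, vv_pct = 0,
                          thct_frac = 0), sp))
    region_footprint(reg, nr, nc)
  }
  pure_i_mask <- spot_mask(pure_i)
  blood_mask <- spot_mask(blood_spot)
  tissue_mask <- truth$labels > 0L
  if (any(pure_i_mask & blood_mask) || any(pure_i_mask & tissue_mask) ||
      any(blood_mask & tissue_mask))
    stop("layout masks must be disjoint")
  if (dilution <= 0) stop("dilution must be positive")
  if (gain_tc <= 0 || gain_i <= 0) stop("plate gains must be positive")
  noise_def <- list(enabled = TRUE, psl_per_count = 0.05, read_sd = 0.2,
                    bg_offset = 1.0)
  noise <- utils::modifyList(noise_def, noise)
  px_cm <- truth$pixel_size_um * 1e-4
  mass_per_pixel_g <- px_cm^2 * (thickness_um * 1e-4) * density_g_ml
  structure(list(pure_i_mask = pure_i_mask, blood_mask = blood_mask,
                 tissue_mask = tissue_mask,
                 bg_mask = !(pure_i_mask | blood_mask | tissue_mask),
                 dilution = dilution, pure_i_conc_mbq_g = pure_i_conc_mbq_g,
                 gain_tc = gain_tc, gain_i = gain_i,
                 thickness_um = thickness_um, density_g_ml = density_g_ml,
                 mass_per_pixel_g = mass_per_pixel_g,
                 noise = noise, leak_i_frac = leak_i_frac),
            class = "scene_layout")
}

# per-isotope concentration images (MBq/g at t = 0) for a scene
scene_concentrations <- function(truth, panel, layout) {
  c_tc <- (truth$vrbc_pct / 100) * panel$c_tc_rbc
  c_i <- (truth$vp_pct / 100) * panel$c_i_plasma * (1 + layout$leak_i_frac)
  c_tc[!layout$tissue_mask] <- 0
  c_i[!layout$tissue_mask] <- 0
  c_tc[layout$blood_mask] <- panel$c_tc_blood / layout$dilution
  c_i[layout$blood_mask] <- panel$c_i_blood / layout$dilution
  c_i[layout$pure_i_mask] <- layout$pure_i_conc_mbq_g
  list(tc = c_tc, i = c_i)
}

#' Render the two phosphor-plate exposures of a scene
#'
#' Forward model of the dual-isotope experiment. The first exposure
#' collects decays from both isotopes; by the second exposure, a week
#' later, the short-lived 99mTc has decayed away (about 28 half-lives)
#' and only 125I contributes. Expected PSL per pixel is the sum over
#' isotopes of gain x concentration x pixel mass x decays integrated
#' over the window; noise per the layout's noise model.
#'
#' @param truth A \code{\link{phantom_truth}}.
#' @param panel A \code{\link{blood_panel}}.
#' @param layout A \code{\link{scene_layout}}.
#' @param windows List with \code{exp1}, \code{exp2}
#'   (\code{\link{exposure_window}}s); default \code{\link{default_windows}}.
#' @param seed Integer seed; rendering is deterministic given the seed.
#' @param isotopes List with elements \code{tc}, \code{i}
#'   (\code{\link{isotope_spec}}s); defaults to the built-in pair.
#' @return List with \code{exp1}, \code{exp2} (\code{\link{psl_image}}s)
#'   and \code{expected1}, \code{expected2} (noise-free PSL matrices
#'   without background offset, for diagnostics).
#' @export
render_exposures <- function(truth, panel, layout,
                             windows = default_windows(), seed = 1L,
                             isotopes = list(tc = iso_tc99m(),
                                             i = iso_i125())) {
  stopifnot(inherits(truth, "phantom_truth"), inherits(panel, "blood_panel"),
            inherits(layout, "scene_layout"))
  check_window_pair(windows$exp1, windows$exp2)
  conc <- scene_concentrations(truth, panel, layout)
  m <- layout$mass_per_pixel_g
  expected <- function(w) {
    layout$gain_tc * conc$tc * m * integrated_decay(isotopes$tc, w) +
      layout$gain_i * conc$i * m * integrated_decay(isotopes$i, w)
  }
  e1 <- expected(windows$exp1)
  e2 <- expected(windows$exp2)
  noisify <- function(e, subseed) {
    ns <- layout$noise
    if (!isTRUE(ns$enabled)) return(e + ns$bg_offset)
    set.seed(subseed)
    q <- ns$psl_per_count
    counts <- matrix(stats::rpois(length(e), e / q), nrow(e), ncol(e))
    counts * q +
      matrix(stats::rnorm(length(e), 0, ns$read_sd), nrow(e), ncol(e)) +
      ns$bg_offset
  }
  list(exp1 = psl_image(noisify(e1, seed * 2L + 1L), windows$exp1),
       exp2 = psl_image(noisify(e2, seed * 2L + 2L), windows$exp2),
       expected1 = e1, expected2 = e2)
}

# ---- rigid resampling ------------------------------------------------------

# Bilinear rigid resampler. Forward transform T maps source pixel
# positions to target positions: centred coords (x = col - cx, y = row - cy),
# x' = x cos(th) - y sin(th) + dx, y' = x sin(th) + y cos(th) + dy
# (theta in degrees, positive = counterclockwise in x-right / y-down axes).
# inverse = FALSE renders img under T (content moves by +dx cols, +dy rows);
# inverse = TRUE renders img under T^{-1}, undoing a previous forward pass.
resample_rigid <- function(mat, dx_px, dy_px, theta_deg, inverse = FALSE,
                           fill = 0) {
  if (dx_px == 0 && dy_px == 0 && theta_deg == 0) return(mat)
  nr <- nrow(mat); nc <- ncol(mat)
  # pure integer translation: exact shift, no interpolation
  if (theta_deg == 0 && dx_px == round(dx_px) && dy_px == round(dy_px)) {
    s <- if (inverse) -1 else 1
    out <- matrix(fill, nr, nc)
    r_src <- seq_len(nr) - s * dy_px
    c_src <- seq_len(nc) - s * dx_px
    rok <- r_src >= 1 & r_src <= nr
    cok <- c_src >= 1 & c_src <= nc
    out[rok, cok] <- mat[r_src[rok], c_src[cok]]
    return(out)
  }
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  th <- theta_deg * pi / 180
  rr <- matrix(seq_len(nr), nr, nc) - cy
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - cx
  if (!inverse) {
    # output(y) = img(T^{-1} y)
    xs <- cos(th) * (cc - dx_px) + sin(th) * (rr - dy_px)
    ys <- -sin(th) * (cc - dx_px) + cos(th) * (rr - dy_px)
  } else {
    # output(y) = img(T y)
    xs <- cos(th) * cc - sin(th) * rr + dx_px
    ys <- sin(th) * cc + cos(th) * rr + dy_px
  }
  cs <- xs + cx; rs <- ys + cy
  r0 <- floor(rs); c0 <- floor(cs)
  fr <- rs - r0; fc <- cs - c0
  out <- matrix(fill, nr, nc)
  ok <- r0 >= 1 & r0 + 1 <= nr & c0 >= 1 & c0 + 1 <= nc
  idx <- function(r, c) (c - 1) * nr + r
  g <- function(r, c) mat[idx(r, c)]
  o <- which(ok)
  out[o] <- (1 - fr[o]) * (1 - fc[o]) * g(r0[o], c0[o]) +
    (1 - fr[o]) * fc[o] * g(r0[o], c0[o] + 1) +
    fr[o] * (1 - fc[o]) * g(r0[o] + 1, c0[o]) +
    fr[o] * fc[o] * g(r0[o] + 1, c0[o] + 1)
  out
}

#' Apply a rigid offset to an exposure image
#'
#' Misaligns an image by a rigid transform (translation in pixels plus a
#' rotation about the image centre), emulating the repositioning of
#' sections between the two plate exposures that registration must later
#' undo. Bilinear interpolation; the zero transform returns the input
#' bit-identically and pure integer translations are exact.
#'
#' @param img A \code{\link{psl_image}} or numeric matrix.
#' @param dx_px,dy_px Translation in pixels (columns, rows);
#'   |dx|, |dy| <= 20.
#' @param theta_deg Rotation in degrees about the image centre;
#'   |theta| <= 5.
#' @param fill Value for pixels mapped from outside the image.
#' @return Same type as \code{img}.
#' @export
apply_rigid_offset <- function(img, dx_px, dy_px, theta_deg, fill = 0) {
  if (abs(dx_px) > 20 || abs(dy_px) > 20)
    stop("|dx_px|, |dy_px| must be <= 20")
  if (abs(theta_deg) > 5) stop("|theta_deg| must be <= 5")
  if (inherits(img, "psl_image")) {
    psl_image(resample_rigid(img$psl, dx_px, dy_px, theta_deg, fill = fill),
              img$window)
  } else {
    resample_rigid(img, dx_px, dy_px, theta_deg, fill = fill)
  }
}
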