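#' Calibrate a separated PSL image to activity concentration
#'
#' Converts PSL per pixel into MBq/g at the reference time using the
#' diluted-blood internal standard: the spot's true concentration is the
#' whole-blood concentration of the matching isotope divided by the
#' dilution factor, so
#' \code{calib_factor = (known_conc / dilution) / meanPSL(blood_mask)}
#' and every pixel is multiplied by it. Plate gain, section thickness,
#' density and exposure duration all cancel because the standard was cut
#' and exposed with the tissue.
#'
#' @param psl A background-subtracted, separated \code{\link{psl_image}}
#'   (or matrix) of one isotope.
#' @param blood_mask Logical mask of the diluted-blood spot.
#' @param known_conc Whole-blood concentration of the matching isotope at
#'   t = 0, MBq/g.
#' @param dilution Blood-spot dilution factor (default 50).
#' @param isotope The \code{\link{isotope_spec}} of the image (metadata).
#' @return An object of class \code{activity_map}: \code{values} (MBq/g
#'   matrix), \code{isotope}, \code{calib_factor}.
#' @examples
#' psl <- matrix(1000, 4, 4); psl[1, 1:2] <- 5000
#' mask <- matrix(FALSE, 4, 4); mask[1, 1:2] <- TRUE
#' calibrate(psl, mask, known_conc = 0.06, dilution = 50)$calib_factor
#' # (0.06 / 50) / 5000 = 2.4e-7
#' @export
calibrate <- function(psl, blood_mask, known_conc, dilution = 50,
                      isotope = NULL) {
  m <- if (inherits(psl, "psl_image")) psl$psl else psl
  stopifnot(is.logical(blood_mask), any(blood_mask))
  if (known_conc < 0) stop("known_conc must be non-negative")
  if (dilution <= 0) stop("dilution must be positive")
  mu <- mean(m[blood_mask])
  if (!is.finite(mu) || mu <= 0)
    stop("non-positive mean PSL over the blood spot; cannot calibrate")
  cf <- (known_conc / dilution) / mu
  structure(list(values = m * cf, isotope = isotope, calib_factor = cf),
            class = "activity_map")
}

#' @export
print.activity_map <- function(x, ...) {
  cat(sprintf("<activity_map %d x %d, calib %.4g MBq/g per PSL>\n",
              nrow(x$values), ncol(x$values), x$calib_factor))
  invisible(x)
}

#' Tracer distribution volume per pixel
#'
#' The distribution volume of a blood-compartment tracer is the tissue
#' concentration divided by the concentration of the blood fraction that
#' carries it, as a percentage: Vrbc uses the RBC-fraction 99mTc
#' concentration, Vp the plasma-fraction 125I concentration. Units of
#' mL/100 g are treated as \% (blood-fraction density taken as 1 g/mL).
#'
#' @param c_tissue An \code{\link{activity_map}} or MBq/g matrix.
#' @param c_reference_fraction Concentration of the matching blood
#'   fraction, MBq/g at the same reference time (> 0).
#' @return Matrix of per-pixel distribution volume in \%.
#' @examples
#' distribution_volume(matrix(0.018), 2.0)   # 0.9 %
#' distribution_volume(matrix(0.0021), 0.1)  # 2.1 %
#' @export
distribution_volume <- function(c_tissue, c_reference_fraction) {
  m <- if (inherits(c_tissue, "activity_map")) c_tissue$values else c_tissue
  if (!is.numeric(c_reference_fraction) || length(c_reference_fraction) != 1L ||
      c_reference_fraction <= 0)
    stop("c_reference_fraction must be a positive scalar")
  100 * m / c_reference_fraction
}

#' Compose vascular volume and tissue hematocrit maps
#'
#' The vascular volume is the sum of the plasma and red-blood-cell
#' distribution volumes, \code{vv = vp + vrbc}; the tissue hematocrit is
#' the RBC share of it, \code{thct = vrbc / vv}, defined only where
#' \code{vv >= vv_min} (default 0.5\%) to avoid 0/0 in avascular
#' background; elsewhere it is NaN (masked).
#'
#' @param vp_pct,vrbc_pct Same-shape matrices of plasma and RBC
#'   distribution volume (\%).
#' @param vv_min Minimum vascular volume (\%) for tHct to be defined.
#' @return An object of class \code{volume_maps} with matrices
#'   \code{vp_pct}, \code{vrbc_pct}, \code{vv_pct}, \code{thct_frac} and
#'   the \code{vv_min} used.
#' @export
compose_maps <- function(vp_pct, vrbc_pct, vv_min = 0.5) {
  stopifnot(is.matrix(vp_pct), is.matrix(vrbc_pct),
            all(dim(vp_pct) == dim(vrbc_pct)))
  vv <- vp_pct + vrbc_pct
  thct <- vrbc_pct / vv
  thct[!is.finite(thct) | vv < vv_min] <- NaN
  structure(list(vp_pct = vp_pct, vrbc_pct = vrbc_pct, vv_pct = vv,
                 thct_frac = thct, vv_min = vv_min),
            class = "volume_maps")
}

#' @export
print.volume_maps <- function(x, ...) {
  cat(sprintf("<volume_maps %d x %d, tHct defined on %d px (vv >= %g%%)>\n",
              nrow(x$vv_pct), ncol(x$vv_pct), sum(is.finite(x$thct_frac)),
              x$vv_min))
  invisible(x)
}

#' Gamma-well-counting sample
#'
#' One weighed tissue sample with its per-isotope activity
#' concentrations decay-corrected to t = 0.
#'
#' @param tissue_id Sample label.
#' @param a_tc,a_i 99mTc and 125I activity concentrations, MBq/g at t = 0.
#' @param mass_g Sample mass in grams (> 0).
#' @return An object of class \code{gwc_sample}.
#' @export
gwc_sample <- function(tissue_id, a_tc, a_i, mass_g) {
  if (a_tc < 0 || a_i < 0) stop("activities must be non-negative")
  if (mass_g <= 0) stop("mass_g must be positive")
  structure(list(tissue_id = tissue_id, a_tc = a_tc, a_i = a_i,
                 mass_g = mass_g), class = "gwc_sample")
}

#' Hematocrit of a counted sample
#'
#' Scalar analogue of the map pipeline: the sample's RBC and plasma
#' distribution volumes are its isotope concentrations over the matching
#' blood-fraction concentrations, and the hematocrit is the RBC share,
#' \code{vrbc / (vrbc + vp)}. A whole-blood sample returns the panel's
#' capillary hematocrit exactly when the panel is internally consistent.
#'
#' @param sample A \code{\link{gwc_sample}} (or list with \code{a_tc},
#'   \code{a_i}).
#' @param panel A \code{\link{blood_panel}}.
#' @return Hematocrit fraction in [0, 1].
#' @examples
#' p <- make_blood_panel(0.8, 0.06, bhct = 0.40)
#' gwc_hct(gwc_sample("brain", 0.018, 0.0021, 1), p)  # 0.30
#' @export
gwc_hct <- function(sample, panel) {
  stopifnot(inherits(panel, "blood_panel"))
  if (panel$c_tc_rbc <= 0 || panel$c_i_plasma <= 0)
    stop("panel fraction concentrations must be positive")
  vrbc <- sample$a_tc / panel$c_tc_rbc
  vp <- sample$a_i / panel$c_i_plasma
  if (vrbc + vp <= 0)
    stop("sample carries no activity; hematocrit undefined")
  vrbc / (vrbc + vp)
}

#' Whole-blood hematocrit from the autoradiographic maps
#'
#' The diluted-blood reference spot is whole blood, so its tissue-
#' hematocrit reading estimates the systemic (large-vessel) hematocrit:
#' the dilution factor cancels in the RBC/total ratio. Returns the mean
#' tHct over defined spot pixels.
#'
#' @param maps A \code{\link{volume_maps}}.
#' @param blood_mask Logical mask of the diluted-blood spot.
#' @return Estimated whole-blood hematocrit (fraction).
#' @export
arg_bhct <- function(maps, blood_mask) {
  stopifnot(inherits(maps, "volume_maps"), is.logical(blood_mask))
  if (!any(blood_mask)) stop("empty blood-spot mask")
  v <- maps$thct_frac[blood_mask]
  v <- v[is.finite(v)]
  if (length(v) == 0L) stop("no defined tHct pixels in the blood spot")
  mean(v)
}

#' Percent injected dose per gram
#'
#' @param a Activity concentration, MBq/g.
#' @param dose_mbq Injected dose in MBq (> 0).
#' @return \code{100 * a / dose_mbq}, \%ID/g (vectorised in \code{a}).
#' @export
percent_id_per_g <- function(a, dose_mbq) {
  if (!is.numeric(dose_mbq) || length(dose_mbq) != 1L || dose_mbq <= 0)
    stop("dose_mbq must be a positive scalar")
  100 * a / dose_mbq
}

#' Full quantification of separated exposures
#'
#' Convenience wrapper running calibration of both isotope images
#' against the diluted-blood standard, per-pixel distribution volumes,
#' and map composition.
#'
#' @param sep A \code{\link{separation_result}}.
#' @param panel A \code{\link{blood_panel}}.
#' @param layout A \code{\link{scene_layout}} (for the blood-spot mask
#'   and dilution).
#' @param vv_min Minimum Vv (\%) for tHct definition.
#' @return A list: \code{maps} (\code{\link{volume_maps}}), \code{act_tc},
#'   \code{act_i} (\code{\link{activity_map}}s).
#' @export
quantify_maps <- function(sep, panel, layout, vv_min = 0.5) {
  stopifnot(inherits(sep, "separation_result"),
            inherits(panel, "blood_panel"),
            inherits(layout, "scene_layout"))
  act_tc <- calibrate(sep$psl_tc, layout$blood_mask, panel$c_tc_blood,
                      layout$dilution, isotope = iso_tc99m())
  act_i <- calibrate(sep$psl_i, layout$blood_mask, panel$c_i_blood,
                     layout$dilution, isotope = iso_i125())
  vrbc <- distribution_volume(act_tc, panel$c_tc_rbc)
  vp <- distribution_volume(act_i, panel$c_i_plasma)
  list(maps = compose_maps(vp, vrbc, vv_min = vv_min),
       act_tc = act_tc, act_i = act_i)
}
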