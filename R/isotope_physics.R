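#' Isotope specification
#'
#' Describes a radioisotope by its physical half-life. Two built-in specs
#' cover the tracers used for dual-isotope hematocrit mapping:
#' \code{iso_i125()} (125I-albumin, half-life 59.4 days) and
#' \code{iso_tc99m()} (99mTc-labelled red blood cells, half-life 6 hours).
#'
#' @param name Text label for the isotope.
#' @param half_life_h Physical half-life in hours; must be positive.
#' @return An object of class \code{isotope_spec}.
#' @examples
#' iso <- isotope_spec("99mTc", 6)
#' decay_factor(iso, 6)  # 0.5 after one half-life
#' @export
isotope_spec <- function(name, half_life_h) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(half_life_h) || length(half_life_h) != 1L ||
      !is.finite(half_life_h) || half_life_h <= 0)
    stop("half_life_h must be a single positive number")
  structure(list(name = name, half_life_h = as.numeric(half_life_h)),
            class = "isotope_spec")
}

#' @rdname isotope_spec
#' @export
iso_i125 <- function(half_life_h = 59.4 * 24) isotope_spec("125I", half_life_h)

#' @rdname isotope_spec
#' @export
iso_tc99m <- function(half_life_h = 6.0) isotope_spec("99mTc", half_life_h)

#' @export
print.isotope_spec <- function(x, ...) {
  cat(sprintf("<isotope %s, half-life %.4g h>\n", x$name, x$half_life_h))
  invisible(x)
}

#' Phosphor-plate exposure window
#'
#' A contiguous time interval during which a section is exposed on the
#' phosphor plate. Times are hours after the reference time t = 0
#' (euthanasia / tissue freezing); all activity concentrations are stated
#' at t = 0.
#'
#' @param start_h Start of the exposure, hours after t = 0 (>= 0).
#' @param duration_h Exposure duration in hours (> 0).
#' @return An object of class \code{exposure_window}.
#' @examples
#' exposure_window(2, 16)     # an overnight first exposure
#' exposure_window(170, 168)  # a one-week exposure starting a week later
#' @export
exposure_window <- function(start_h, duration_h) {
  if (!is.numeric(start_h) || length(start_h) != 1L || !is.finite(start_h) ||
      start_h < 0)
    stop("start_h must be a single non-negative number")
  if (!is.numeric(duration_h) || length(duration_h) != 1L ||
      !is.finite(duration_h) || duration_h <= 0)
    stop("duration_h must be a single positive number")
  structure(list(start_h = as.numeric(start_h),
                 duration_h = as.numeric(duration_h)),
            class = "exposure_window")
}

#' @export
print.exposure_window <- function(x, ...) {
  cat(sprintf("<exposure window [%g, %g] h>\n", x$start_h,
              x$start_h + x$duration_h))
  invisible(x)
}

#' Default exposure windows
#'
#' The first ("overnight") exposure starts 2 h after euthanasia and lasts
#' 16 h; the second starts a week later and lasts one week. Both are
#' configurable; only the qualitative durations are dictated by the
#' protocol.
#'
#' @return A list with elements \code{exp1} and \code{exp2}.
#' @export
default_windows <- function() {
  list(exp1 = exposure_window(2, 16),
       exp2 = exposure_window(170, 168))
}

#' Radioactive decay factor
#'
#' Fraction of activity remaining after \code{dt_h} hours:
#' \eqn{2^{-dt/T_{1/2}}}.
#'
#' @param iso An \code{\link{isotope_spec}}.
#' @param dt_h Elapsed time in hours; must be >= 0 (vectorised).
#' @return Remaining activity fraction(s) in (0, 1].
#' @export
decay_factor <- function(iso, dt_h) {
  stopifnot(inherits(iso, "isotope_spec"))
  if (any(!is.finite(dt_h)) || any(dt_h < 0))
    stop("dt_h must be non-negative and finite")
  2^(-dt_h / iso$half_life_h)
}

#' Decay-correct an activity to an earlier reference time
#'
#' Converts an activity concentration measured \code{dt_h} hours after the
#' reference time back to its value at t = 0.
#'
#' @param a Measured activity (any consistent unit), vectorised.
#' @inheritParams decay_factor
#' @return Activity at t = 0.
#' @export
decay_correct <- function(a, iso, dt_h) a / decay_factor(iso, dt_h)

#' Decays accumulated over an exposure window, in effective hours
#'
#' Integral of the decay curve over the window,
#' \deqn{\int_{s}^{s+d} 2^{-t/T_{1/2}}\,dt =
#'   \frac{T_{1/2}}{\ln 2}\left(2^{-s/T_{1/2}} - 2^{-(s+d)/T_{1/2}}\right),}
#' so that the photostimulated luminescence collected in the window is
#' proportional to (activity at t = 0) x \code{integrated_decay}. In the
#' no-decay limit (half-life much longer than the window) this equals the
#' window duration. Computed via \code{expm1} for numerical stability at
#' long half-lives.
#'
#' @param iso An \code{\link{isotope_spec}}.
#' @param window An \code{\link{exposure_window}}.
#' @return Effective exposure hours (scalar, > 0).
#' @export
integrated_decay <- function(iso, window) {
  stopifnot(inherits(iso, "isotope_spec"), inherits(window, "exposure_window"))
  Th <- iso$half_life_h
  s <- window$start_h
  d <- window$duration_h
  # (Th/ln2) * 2^(-s/Th) * (1 - 2^(-d/Th)), with 1 - 2^-x = -expm1(-x ln2)
  2^(-s / Th) * (-Th / log(2)) * expm1(-d * log(2) / Th)
}

#' Theoretical inter-exposure intensity ratio for one isotope
#'
#' Ratio of decays accumulated in window \code{w2} to those in \code{w1}.
#' For a long-lived isotope imaged in a later, longer window the ratio
#' exceeds one; for a short-lived isotope whose activity is exhausted
#' before \code{w2} the ratio is essentially zero. This is the theoretical
#' value of the empirical pure-spot correction factor estimated by
#' \code{\link{estimate_i125_correction}}.
#'
#' @param iso An \code{\link{isotope_spec}}.
#' @param w1,w2 \code{\link{exposure_window}} objects.
#' @return \code{integrated_decay(iso, w2) / integrated_decay(iso, w1)}.
#' @export
window_ratio <- function(iso, w1, w2) {
  integrated_decay(iso, w2) / integrated_decay(iso, w1)
}

#' Validate a pair of sequential exposure windows
#'
#' The first and second exposures of the same sections must not overlap
#' and the second must start after the first ends.
#'
#' @param w1,w2 \code{\link{exposure_window}} objects.
#' @return Invisibly \code{TRUE}; errors otherwise.
#' @export
check_window_pair <- function(w1, w2) {
  stopifnot(inherits(w1, "exposure_window"), inherits(w2, "exposure_window"))
  if (w2$start_h < w1$start_h + w1$duration_h)
    stop("second exposure must start after the first ends")
  invisible(TRUE)
}
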