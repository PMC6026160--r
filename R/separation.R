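#' Estimate and subtract the plate background (fog) level
#'
#' Phosphor plates carry a non-zero fog level; the background is
#' estimated as the median PSL over the background mask and subtracted
#' before any inter-exposure ratio or calibration.
#'
#' @param img A \code{\link{psl_image}} or numeric matrix.
#' @param bg_mask Logical matrix marking background pixels.
#' @return Same type as \code{img}, background-subtracted.
#' @export
subtract_background <- function(img, bg_mask) {
  m <- if (inherits(img, "psl_image")) img$psl else img
  stopifnot(is.logical(bg_mask), any(bg_mask))
  out <- m - stats::median(m[bg_mask])
  if (inherits(img, "psl_image")) psl_image(out, img$window) else out
}

#' Inter-exposure 125I intensity correction factor
#'
#' The pure-125I reference drop has no 99mTc, so its signal ratio between
#' the two exposures is purely the 125I decay-and-duration ratio. The
#' factor is the mean background-subtracted PSL of Exp2 over the spot
#' divided by that of Exp1; dividing Exp2 by it brings the 125I signal
#' onto Exp1's intensity scale. Its theoretical value is
#' \code{\link{window_ratio}} of 125I over the two windows.
#'
#' @param exp1,exp2 Background-subtracted \code{\link{psl_image}}s (or
#'   matrices) of the two exposures.
#' @param pure_i_mask Logical mask of the pure-125I drop in Exp1's frame
#'   (>= 25 pixels).
#' @param pure_i_mask2 Mask of the drop in Exp2's frame; defaults to
#'   \code{pure_i_mask}, but when the section sheet was repositioned
#'   between exposures the spot ROI must be placed on each image (see
#'   \code{\link{locate_mask}}).
#' @return Scalar correction factor (> 0).
#' @export
estimate_i125_correction <- function(exp1, exp2, pure_i_mask,
                                     pure_i_mask2 = pure_i_mask) {
  m1 <- if (inherits(exp1, "psl_image")) exp1$psl else exp1
  m2 <- if (inherits(exp2, "psl_image")) exp2$psl else exp2
  stopifnot(is.logical(pure_i_mask), is.logical(pure_i_mask2))
  if (sum(pure_i_mask) < 25 || sum(pure_i_mask2) < 25)
    stop("pure-125I mask must contain at least 25 pixels")
  mu1 <- mean(m1[pure_i_mask])
  if (!is.finite(mu1) || mu1 <= 0)
    stop("non-positive Exp1 mean over the pure-125I spot; ",
         "check background subtraction and mask placement")
  mean(m2[pure_i_mask2]) / mu1
}

#' Locate a reference-spot mask in an image
#'
#' Finds the integer translation of a spot ROI that maximises the summed
#' signal under it, via spectral cross-correlation of the image with the
#' mask. Used to place the pure-125I ROI on an exposure whose sheet was
#' repositioned.
#'
#' @param img A \code{\link{psl_image}} or matrix.
#' @param mask Logical ROI mask.
#' @return The translated logical mask.
#' @export
locate_mask <- function(img, mask) {
  m <- if (inherits(img, "psl_image")) img$psl else img
  stopifnot(is.logical(mask), all(dim(m) == dim(mask)))
  pk <- xcorr_peak(xcorr_fft(m, mask * 1.0))
  dy <- round(unname(pk["dy"])); dx <- round(unname(pk["dx"]))
  resample_rigid(mask * 1.0, dx, dy, 0) > 0.5
}

# n rounds of 4-neighbour binary erosion (keeps spot ROIs away from
# partially-sampled edge pixels after resampling)
erode_mask <- function(mask, n = 1L) {
  for (i in seq_len(n)) {
    nr <- nrow(mask); nc <- ncol(mask)
    p <- matrix(FALSE, nr + 2, nc + 2)
    p[2:(nr + 1), 2:(nc + 1)] <- mask
    mask <- p[2:(nr + 1), 2:(nc + 1)] & p[1:nr, 2:(nc + 1)] &
      p[3:(nr + 2), 2:(nc + 1)] & p[2:(nr + 1), 1:nc] &
      p[2:(nr + 1), 3:(nc + 2)]
  }
  mask
}

# circular Gaussian blur via FFT (registration pre-filter: band-limits
# the images so bilinear resampling is close to exact and the
# correlation optimum is unbiased by edge aliasing)
gaussian_blur_fft <- function(mat, sigma) {
  nr <- nrow(mat); nc <- ncol(mat)
  gy <- stats::dnorm(pmin(0:(nr - 1), nr - 0:(nr - 1)), 0, sigma)
  gx <- stats::dnorm(pmin(0:(nc - 1), nc - 0:(nc - 1)), 0, sigma)
  k <- outer(gy, gx)
  k <- k / sum(k)
  Re(stats::fft(stats::fft(mat) * stats::fft(k), inverse = TRUE)) /
    length(mat)
}

# cross-correlation surface between two equal-size matrices via FFT;
# returns the (wrapped) surface with zero shift at [1, 1]
xcorr_fft <- function(a, b) {
  Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE)) /
    length(a)
}

# integer + quadratic sub-pixel peak of a cross-correlation surface;
# returns c(dy, dx, peak)
xcorr_peak <- function(cc) {
  nr <- nrow(cc); nc <- ncol(cc)
  i <- which.max(cc)
  pr <- (i - 1) %% nr + 1
  pc <- (i - 1) %/% nr + 1
  wrap <- function(p, n) if (p - 1 > n / 2) p - 1 - n else p - 1
  subpix <- function(cm, c0, cp) {
    den <- cm - 2 * c0 + cp
    if (den >= 0) 0 else max(-0.5, min(0.5, 0.5 * (cm - cp) / den))
  }
  at <- function(r, c) cc[(r - 1) %% nr + 1, (c - 1) %% nc + 1]
  ddy <- subpix(at(pr - 1, pc), at(pr, pc), at(pr + 1, pc))
  ddx <- subpix(at(pr, pc - 1), at(pr, pc), at(pr, pc + 1))
  c(dy = wrap(pr, nr) + ddy, dx = wrap(pc, nc) + ddx, peak = cc[pr, pc])
}

register_translation <- function(ref, mov) {
  # peak of ifft(F(ref) conj(F(mov))) sits at minus the displacement of
  # mov relative to ref, so negate to report the forward shift
  pk <- xcorr_peak(xcorr_fft(ref, mov))
  list(dx = -unname(pk["dx"]), dy = -unname(pk["dy"]),
       score = unname(pk["peak"]) /
         (sqrt(sum(ref^2)) * sqrt(sum(mov^2)) + .Machine$double.eps))
}

#' Register the second exposure onto the first
#'
#' Estimates the rigid transform (dx, dy, theta) that maps Exp2 onto
#' Exp1's frame. Translation is found by spectral cross-correlation with
#' quadratic sub-pixel interpolation of the correlation peak; rotation by
#' a coarse-to-fine grid search (default +/-5 degrees, step 0.25 then
#' 0.05), de-rotating Exp2 at each candidate angle and scoring the
#' normalised correlation peak. Deterministic.
#'
#' @param exp1,exp2 Background-subtracted \code{\link{psl_image}}s or
#'   matrices of identical shape.
#' @param rotation Search over rotations; set \code{FALSE} for a pure
#'   translation fit.
#' @param theta_max_deg Rotation search half-range in degrees.
#' @param coarse_step_deg,fine_step_deg Grid steps of the two passes.
#' @param smooth_sigma Gaussian pre-filter SD in pixels applied to both
#'   images before matching (0 disables); band-limiting removes the
#'   aliasing bias that sharp edges otherwise induce in the correlation
#'   optimum. The transform is estimated on the filtered images but
#'   applied downstream to the unfiltered data.
#' @param min_score Minimum acceptable normalised correlation; below it a
#'   registration-failure error is raised with diagnostics.
#' @return List with \code{dx_px}, \code{dy_px}, \code{theta_deg},
#'   \code{score}.
#' @export
register_exposures <- function(exp1, exp2, rotation = TRUE,
                               theta_max_deg = 5, coarse_step_deg = 0.25,
                               fine_step_deg = 0.05, smooth_sigma = 1.2,
                               min_score = 0.1) {
  a <- if (inherits(exp1, "psl_image")) exp1$psl else exp1
  b <- if (inherits(exp2, "psl_image")) exp2$psl else exp2
  if (!all(dim(a) == dim(b))) stop("exposures must have identical shape")
  if (smooth_sigma > 0) {
    a <- gaussian_blur_fft(a, smooth_sigma)
    b <- gaussian_blur_fft(b, smooth_sigma)
  }
  # fixed central evaluation window: wider than any admissible offset,
  # so neither circular wrap-around in the spectral correlation nor
  # content clipped at the frame edge can bias candidate comparisons
  margin <- 16L
  ctr <- matrix(FALSE, nrow(a), ncol(a))
  ctr[(margin + 1):(nrow(a) - margin), (margin + 1):(ncol(a) - margin)] <-
    TRUE
  if (stats::sd(a[ctr]) == 0 || stats::sd(b[ctr]) == 0)
    stop("registration failed: an exposure has no image contrast")
  score_at <- function(dx, dy, th) {
    aligned <- resample_rigid(b, dx, dy, th, inverse = TRUE)
    stats::cor(a[ctr], aligned[ctr])
  }
  eval_theta <- function(th) {
    bb <- if (th == 0) b else resample_rigid(b, 0, 0, th, inverse = TRUE)
    tr <- register_translation(a, bb)
    # the residual shift is measured after de-rotation; rotate it back
    # into the composed forward transform x' = R x + t
    thr <- th * pi / 180
    dx <- cos(thr) * tr$dx - sin(thr) * tr$dy
    dy <- sin(thr) * tr$dx + cos(thr) * tr$dy
    list(theta = th, dx = dx, dy = dy, score = score_at(dx, dy, th))
  }
  best <- eval_theta(0)
  if (rotation) {
    for (th in seq(-theta_max_deg, theta_max_deg, by = coarse_step_deg)) {
      cand <- eval_theta(th)
      if (cand$score > best$score) best <- cand
    }
    fine <- seq(best$theta - coarse_step_deg, best$theta + coarse_step_deg,
                by = fine_step_deg)
    fine <- fine[abs(fine) <= theta_max_deg]
    for (th in fine) {
      cand <- eval_theta(th)
      if (cand$score > best$score) best <- cand
    }
    # joint sub-pixel polish of (dx, dy, theta) on the alignment score
    opt <- stats::optim(c(best$dx, best$dy, best$theta),
                        function(p) -score_at(p[1], p[2], p[3]),
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-10, maxit = 200))
    if (-opt$value > best$score)
      best <- list(theta = opt$par[3], dx = opt$par[1], dy = opt$par[2],
                   score = -opt$value)
  }
  if (best$score < min_score)
    stop(sprintf(paste0("registration failed: best correlation %.3g < %.3g ",
                        "(theta %.2f deg, shift %.1f, %.1f px)"),
                 best$score, min_score, best$theta, best$dx, best$dy))
  list(dx_px = best$dx, dy_px = best$dy, theta_deg = best$theta,
       score = best$score)
}

#' Separate the 99mTc and 125I signals from the two exposures
#'
#' Implements the subtraction step of the dual-isotope protocol: Exp2
#' (125I only) is brought onto Exp1's intensity scale with the pure-spot
#' correction factor, resampled into Exp1's frame with the registration
#' transform, and subtracted from Exp1 (both isotopes) to leave the
#' 99mTc-only image. Pixels driven negative by noise are clamped to zero
#' and the clamped fraction over the tissue is reported. Residual 99mTc
#' in Exp2 is ignored; with default timing it is below 1e-6 of its Exp1
#' level.
#'
#' @param exp1,exp2 Background-subtracted \code{\link{psl_image}}s.
#' @param f Correction factor from \code{\link{estimate_i125_correction}}.
#' @param transform Rigid transform from \code{\link{register_exposures}}
#'   (list with \code{dx_px}, \code{dy_px}, \code{theta_deg}); identity
#'   by default.
#' @param tissue_mask Optional logical mask over which the clamped
#'   fraction is computed (defaults to all pixels).
#' @return An object of class \code{separation_result}: \code{psl_tc} and
#'   \code{psl_i} (\code{\link{psl_image}}s on Exp1's scale),
#'   \code{f_correction}, \code{transform},
#'   \code{negatives_clamped_fraction}.
#' @export
separate_exposures <- function(exp1, exp2, f,
                               transform = list(dx_px = 0, dy_px = 0,
                                                theta_deg = 0),
                               tissue_mask = NULL) {
  stopifnot(inherits(exp1, "psl_image"), inherits(exp2, "psl_image"))
  if (!is.numeric(f) || length(f) != 1L || !is.finite(f) || f <= 0)
    stop("correction factor f must be a positive scalar")
  aligned <- resample_rigid(exp2$psl, transform$dx_px, transform$dy_px,
                            transform$theta_deg, inverse = TRUE)
  psl_i <- aligned / f
  psl_tc <- exp1$psl - psl_i
  if (is.null(tissue_mask)) tissue_mask <- matrix(TRUE, nrow(psl_tc),
                                                  ncol(psl_tc))
  clamped <- mean(psl_tc[tissue_mask] < 0)
  psl_tc[psl_tc < 0] <- 0
  psl_i[psl_i < 0] <- 0
  structure(list(psl_tc = psl_image(psl_tc, exp1$window),
                 psl_i = psl_image(psl_i, exp1$window),
                 f_correction = f, transform = transform,
                 negatives_clamped_fraction = clamped),
            class = "separation_result")
}

#' @export
print.separation_result <- function(x, ...) {
  cat(sprintf(paste0("<separation_result f = %.4g, shift (%.2f, %.2f) px, ",
                     "theta %.2f deg, %.1f%% clamped>\n"),
              x$f_correction, x$transform$dx_px, x$transform$dy_px,
              x$transform$theta_deg, 100 * x$negatives_clamped_fraction))
  invisible(x)
}
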