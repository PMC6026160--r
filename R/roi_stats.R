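#' Summarise a map over a region of interest
#'
#' Mean, sample standard deviation (n - 1 denominator) and pixel count
#' of a map over a labelled region, excluding masked (NaN/NA) pixels;
#' the fraction of region pixels that were masked is reported alongside.
#'
#' @param map Numeric matrix; NaN/NA marks undefined pixels.
#' @param mask Logical matrix selecting the region.
#' @param region_id Label carried into the result.
#' @return A one-row data.frame: \code{region_id}, \code{mean}, \code{sd},
#'   \code{n_pixels}, \code{fraction_masked}.
#' @export
roi_summary <- function(map, mask, region_id = NA) {
  stopifnot(is.matrix(map), is.logical(mask), all(dim(map) == dim(mask)))
  if (!any(mask)) stop("empty region mask")
  v <- map[mask]
  ok <- is.finite(v)
  if (!any(ok)) stop("region '", region_id, "' is fully masked")
  v <- v[ok]
  data.frame(region_id = region_id, mean = mean(v),
             sd = if (length(v) > 1L) stats::sd(v) else 0,
             n_pixels = length(v),
             fraction_masked = 1 - length(v) / sum(mask))
}

#' Summarise a map over every labelled region
#'
#' @param map Numeric matrix (NaN/NA = masked).
#' @param labels Integer label matrix (0 = background, skipped).
#' @param region_names Optional named translation, e.g.
#'   \code{c("1" = "cortex")}.
#' @return A data.frame with one row per label present.
#' @export
roi_report <- function(map, labels, region_names = NULL) {
  ids <- sort(setdiff(unique(as.vector(labels)), 0L))
  out <- do.call(rbind, lapply(ids, function(id)
    roi_summary(map, labels == id, region_id = id)))
  if (!is.null(region_names))
    out$region <- unname(region_names[as.character(out$region_id)])
  out
}

#' Percent change relative to a reference
#'
#' @param x Observed value.
#' @param ref Reference value (non-zero).
#' @return \code{100 * (x - ref) / ref}.
#' @examples
#' percent_change(29.0, 40.1)  # brain vs whole-blood Hct: -27.7 %
#' @export
percent_change <- function(x, ref) {
  if (any(ref == 0)) stop("reference must be non-zero")
  100 * (x - ref) / ref
}

#' Organ-to-blood hematocrit ratio
#'
#' @param organ_hct Organ (tissue) hematocrit.
#' @param blood_hct Whole-blood hematocrit (> 0).
#' @return \code{organ_hct / blood_hct}.
#' @examples
#' hct_ratio(29.0, 40.1)  # brain: 0.72
#' hct_ratio(19.1, 40.1)  # liver: 0.48
#' @export
hct_ratio <- function(organ_hct, blood_hct) {
  if (any(blood_hct <= 0)) stop("blood_hct must be positive")
  organ_hct / blood_hct
}

#' Pooled (arithmetic) mean of group means
#'
#' @param values Non-empty numeric vector.
#' @return The arithmetic mean.
#' @examples
#' pooled_mean(c(19.5, 18.5, 16.1))  # mean lesion tHct across models: 18.0
#' @export
pooled_mean <- function(values) {
  if (length(values) == 0L) stop("empty value list")
  mean(values)
}

#' Agreement between two estimators
#'
#' Pearson correlation and ordinary least-squares fit of \code{ys} on
#' \code{xs}, the analysis used to compare hematocrit estimates from
#' autoradiography, gamma-well counting and the capillary method.
#'
#' @param xs,ys Equal-length numeric vectors, n >= 3.
#' @return An object of class \code{agreement_fit}: \code{r}, \code{r2},
#'   \code{slope}, \code{intercept}, \code{n}.
#' @export
agreement_fit <- function(xs, ys) {
  if (length(xs) != length(ys)) stop("xs and ys must have equal length")
  if (length(xs) < 3L) stop("need at least 3 points")
  if (stats::var(xs) == 0) stop("zero variance in xs")
  r <- stats::cor(xs, ys)
  fit <- stats::lm(ys ~ xs)
  structure(list(r = r, r2 = r^2,
                 slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 n = length(xs)),
            class = "agreement_fit")
}

#' @export
print.agreement_fit <- function(x, ...) {
  cat(sprintf("<agreement_fit n = %d, r = %.3f, r2 = %.3f, y = %.3f x %+.3f>\n",
              x$n, x$r, x$r2, x$slope, x$intercept))
  invisible(x)
}

#' Conspicuity of a structure against its surround
#'
#' Contrast of a structure (e.g. a large-vessel disk) over a surrounding
#' region, in surround standard deviations:
#' \code{(mean_structure - mean_surround) / sd_surround}. Large vessels
#' stand out sharply on the vascular-volume map but are barely
#' distinguishable on the tissue-hematocrit map. In a noiseless
#' simulation a perfectly uniform surround has zero SD; if the mean
#' difference is also at floating-point level (relative to the surround
#' mean) the contrast is defined as 0, and as \code{Inf} when a genuine
#' difference meets a zero SD.
#'
#' @param map Numeric matrix (NaN/NA = masked).
#' @param structure_mask,surround_mask Disjoint logical masks.
#' @return Signed contrast in surround-SD units.
#' @export
vessel_contrast <- function(map, structure_mask, surround_mask) {
  s <- roi_summary(map, structure_mask, "structure")
  b <- roi_summary(map, surround_mask, "surround")
  d <- s$mean - b$mean
  scale <- max(abs(b$mean), .Machine$double.eps)
  if (abs(d) <= 1e-8 * scale) return(0)
  if (b$sd == 0) return(sign(d) * Inf)
  d / b$sd
}

#' Histogram of tissue hematocrit over a region
#'
#' Normalised histogram of tHct values (expressed in Hct \%) over the
#' defined pixels of a region, on fixed bin edges (default 1-point bins
#' from 0 to 60 \%). Values outside the range are counted in the end
#' bins so frequencies always sum to one over defined pixels.
#'
#' @param map tHct matrix as a fraction (NaN/NA = masked).
#' @param mask Logical region mask.
#' @param bin_width Bin width in Hct percentage points.
#' @param range Histogram range in \%, default \code{c(0, 60)}.
#' @return A list: \code{edges} (\% bin edges, length nbins + 1),
#'   \code{mid} (bin centres), \code{freq} (normalised frequencies
#'   summing to 1), \code{n} (defined pixels).
#' @export
thct_histogram <- function(map, mask, bin_width = 1, range = c(0, 60)) {
  stopifnot(is.matrix(map), is.logical(mask))
  if (!any(mask)) stop("empty region mask")
  if (bin_width <= 0) stop("bin_width must be positive")
  v <- map[mask]
  v <- 100 * v[is.finite(v)]
  if (length(v) == 0L) stop("no defined pixels in the region")
  edges <- seq(range[1], range[2], by = bin_width)
  if (edges[length(edges)] < range[2]) edges <- c(edges, range[2])
  v <- pmin(pmax(v, range[1]), range[2])
  cnt <- graphics::hist(v, breaks = edges, plot = FALSE,
                        include.lowest = TRUE, right = FALSE)$counts
  list(edges = edges, mid = (edges[-1] + edges[-length(edges)]) / 2,
       freq = cnt / length(v), n = length(v))
}
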