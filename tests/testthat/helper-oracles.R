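# Independent oracles, kept deliberately separate from the package's own
# computation paths.

# adaptive-quadrature oracle for the decays integrated over a window
quad_integrated_decay <- function(half_life_h, start_h, duration_h) {
  stats::integrate(function(t) 2^(-t / half_life_h),
                   lower = start_h, upper = start_h + duration_h,
                   rel.tol = 1e-12, abs.tol = 0)$value
}

# brute-force per-pixel ROI summary (loop, no vectorised shortcuts)
brute_roi_summary <- function(map, mask) {
  vals <- c()
  n_masked <- 0L
  for (r in seq_len(nrow(map))) {
    for (c in seq_len(ncol(map))) {
      if (mask[r, c]) {
        v <- map[r, c]
        if (is.finite(v)) vals <- c(vals, v) else n_masked <- n_masked + 1L
      }
    }
  }
  m <- sum(vals) / length(vals)
  ss <- sum((vals - m)^2)
  list(mean = m,
       sd = if (length(vals) > 1) sqrt(ss / (length(vals) - 1)) else 0,
       n_pixels = length(vals),
       fraction_masked = n_masked / (length(vals) + n_masked))
}

# closed-form least squares and Pearson r
closed_form_fit <- function(xs, ys) {
  n <- length(xs)
  sxy <- sum((xs - mean(xs)) * (ys - mean(ys)))
  sxx <- sum((xs - mean(xs))^2)
  syy <- sum((ys - mean(ys))^2)
  slope <- sxy / sxx
  list(r = sxy / sqrt(sxx * syy), slope = slope,
       intercept = mean(ys) - slope * mean(xs))
}

# small scene configurations for fast tests
fast_config <- function(noise = FALSE) {
  cfg <- default_run_config()
  cfg$noise$enabled <- noise
  cfg
}
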