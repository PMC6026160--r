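test_that("calibration against the diluted-blood standard follows the
           hand arithmetic", {
  psl <- matrix(1000, 10, 10)
  mask <- matrix(FALSE, 10, 10); mask[1:5, 1:6] <- TRUE
  psl[mask] <- 5000
  act <- calibrate(psl, mask, known_conc = 0.06, dilution = 50)
  expect_equal(act$calib_factor, 2.4e-7)
  expect_equal(act$values[10, 10], 2.4e-4)
  # all-zero image stays zero
  z <- matrix(0, 10, 10); z[mask] <- 1
  expect_true(all(calibrate(z, mask, 0.06, 50)$values[!mask] == 0))
  expect_error(calibrate(matrix(0, 10, 10), mask, 0.06, 50),
               "non-positive")
})

test_that("calibration cancels the plate gain: recovered concentrations
           equal the rendered ones for any gain", {
  for (gain in c(2e7, 1e8, 9e8)) {
    cfg <- fast_config(noise = FALSE)
    cfg$layout$gain_tc <- gain
    cfg$layout$gain_i <- gain * 1.7
    scene <- build_scene(cfg)
    res <- analyze_scene(scene, seed = 1, register = FALSE)
    conc <- duohct:::scene_concentrations(scene$truth, scene$panel,
                                          scene$layout)
    tis <- scene$layout$tissue_mask & conc$tc > 0
    expect_lt(max(abs(res$quant$act_tc$values[tis] - conc$tc[tis]) /
                    conc$tc[tis]), 1e-6)
    expect_lt(max(abs(res$quant$act_i$values[tis] - conc$i[tis]) /
                    conc$i[tis]), 1e-6)
  }
})

test_that("distribution volumes follow the tissue-over-fraction ratio", {
  expect_equal(distribution_volume(matrix(0.018), 2.0)[1], 0.9)
  expect_equal(distribution_volume(matrix(0.0021), 0.1)[1], 2.1)
  expect_equal(distribution_volume(matrix(0), 5)[1], 0)
  expect_error(distribution_volume(matrix(1), 0), "positive")
})

test_that("map composition: vv = vp + vrbc, thct = vrbc / vv with masking
           below the vascular-volume floor", {
  vp <- matrix(c(2.1, 0.2, 1.0, 1.0), 2, 2)
  vrbc <- matrix(c(0.9, 0.1, 0, 1.0), 2, 2)
  maps <- compose_maps(vp, vrbc, vv_min = 0.5)
  expect_identical(maps$vv_pct, vp + vrbc)
  expect_equal(maps$thct_frac[1, 1], 0.30)
  expect_true(is.nan(maps$thct_frac[2, 1]))  # vv = 0.3 < 0.5 -> masked
  expect_equal(maps$thct_frac[1, 2], 0)      # zero vrbc, defined vv
  expect_equal(maps$thct_frac[2, 2], 0.5)    # vp = vrbc
})

test_that("gamma-well hematocrit follows the two-volume ratio and returns
           the capillary value on whole blood", {
  p <- make_blood_panel(0.8, 0.06, bhct = 0.40)
  expect_equal(gwc_hct(gwc_sample("brain", 0.018, 0.0021, 1.2), p), 0.30)
  expect_equal(gwc_hct(gwc_sample("rbc_only", 0.5, 0, 1), p), 1.0)
  expect_equal(gwc_hct(gwc_sample("plasma_only", 0, 0.5, 1), p), 0.0)
  expect_error(gwc_hct(gwc_sample("empty", 0, 0, 1), p), "no activity")
  # algebraic identity: a whole-blood sample returns bHct exactly
  for (bh in c(0.25, 0.40, 0.55)) {
    pp <- make_blood_panel(0.9, 0.05, bhct = bh)
    expect_equal(gwc_hct(gwc_sample("blood", pp$c_tc_blood, pp$c_i_blood,
                                    0.5), pp),
                 bh, tolerance = 1e-12)
  }
})

test_that("percent injected dose per gram", {
  expect_equal(percent_id_per_g(0.045, 45), 0.1)
  expect_equal(percent_id_per_g(0, 45.2), 0)
  expect_equal(percent_id_per_g(0.2, 45.2), 2 * percent_id_per_g(0.2, 90.4))
  expect_error(percent_id_per_g(1, 0), "positive")
})

test_that("noiseless end-to-end analysis recovers the truth maps for
           random gains, geometry, windows and hematocrits", {
  set.seed(2024)
  for (k in 1:10) {
    cfg <- fast_config(noise = FALSE)
    cfg$layout$gain_tc <- 10^runif(1, 7.5, 8.5)
    cfg$layout$gain_i <- 10^runif(1, 7.5, 8.5)
    cfg$layout$thickness_um <- runif(1, 50, 200)
    cfg$layout$density_g_ml <- runif(1, 0.95, 1.10)
    cfg$panel$bhct <- runif(1, 0.25, 0.55)
    e1s <- runif(1, 1, 4); e1d <- runif(1, 12, 20)
    cfg$exposures$exp1 <- list(start_h = e1s, duration_h = e1d)
    cfg$exposures$exp2 <- list(start_h = runif(1, 150, 250),
                               duration_h = runif(1, 120, 200))
    scene <- build_scene(cfg)
    res <- analyze_scene(scene, seed = k, register = FALSE)
    maps <- res$quant$maps
    t <- scene$truth
    tis <- scene$layout$tissue_mask
    expect_lt(max(abs(maps$vrbc_pct[tis] - t$vrbc_pct[tis]) /
                    t$vrbc_pct[tis]), 1e-6)
    expect_lt(max(abs(maps$vp_pct[tis] - t$vp_pct[tis]) /
                    t$vp_pct[tis]), 1e-6)
    expect_lt(max(abs(maps$vv_pct[tis] - t$vv_pct[tis]) /
                    t$vv_pct[tis]), 1e-6)
    ok <- tis & is.finite(maps$thct_frac)
    expect_lt(max(abs(maps$thct_frac[ok] - t$thct_frac[ok]) /
                    t$thct_frac[ok]), 1e-6)
  }
})

test_that("distribution volumes are independent of the reference time the
           concentrations are decay-corrected to", {
  a <- matrix(runif(16, 0.001, 0.05), 4, 4)
  ref <- 2.0
  base <- distribution_volume(a, ref)
  for (t_h in c(1, 24, 500)) {
    for (iso in list(iso_tc99m(), iso_i125())) {
      k <- 1 / decay_factor(iso, t_h)
      expect_equal(distribution_volume(a * k, ref * k), base,
                   tolerance = 1e-12)
    }
  }
})

test_that("the blood-spot hematocrit estimate equals the configured bHct
           exactly in noiseless runs", {
  for (bh in c(0.25, 0.40, 0.55)) {
    cfg <- fast_config(noise = FALSE)
    cfg$panel$bhct <- bh
    scene <- build_scene(cfg)
    res <- analyze_scene(scene, seed = 1, register = FALSE)
    expect_equal(arg_bhct(res$quant$maps, scene$layout$blood_mask), bh,
                 tolerance = 1e-9)
  }
  expect_error(arg_bhct(compose_maps(matrix(1), matrix(1)),
                        matrix(FALSE)), "empty")
})

test_that("vessel disks are invisible on the hematocrit map but prominent
           on the vascular-volume map (noiseless)", {
  cfg <- fast_config(noise = FALSE)
  scene <- build_scene(cfg)
  res <- analyze_scene(scene, seed = 1, register = FALSE)
  maps <- res$quant$maps
  lab <- scene$truth$labels
  vessels_cortex <- lab == 9L & scene$truth$thct_frac == 0.296
  cortex <- lab == 1L
  # exact invariance of tHct to the Vv hotspot
  expect_lt(max(abs(maps$thct_frac[vessels_cortex] - 0.296)), 1e-9)
  # Vv contrast is enormous, tHct contrast is nil
  expect_gt(vessel_contrast(maps$vv_pct, vessels_cortex, cortex), 3)
  expect_lt(abs(vessel_contrast(maps$thct_frac, vessels_cortex, cortex)),
            0.5)
})

test_that("with default noise the group-mean regional hematocrit is
           recovered within one percentage point", {
  cfg <- fast_config(noise = TRUE)
  scene <- build_scene(cfg)
  means <- matrix(NA_real_, 8, 3)
  for (animal in 1:8) {
    res <- analyze_scene(scene, seed = 1000 + animal, register = FALSE)
    for (reg in 1:3)
      means[animal, reg] <- roi_summary(res$quant$maps$thct_frac,
                                        scene$truth$labels == reg)$mean
  }
  truth <- c(0.296, 0.288, 0.280)
  expect_true(all(abs(colMeans(means) - truth) < 0.01))
})

test_that("albumin leakage inflates Vp and depresses the hematocrit
           estimate", {
  cfg <- fast_config(noise = FALSE)
  cfg$layout$leak_i_frac <- 0.15
  res <- analyze_scene(build_scene(cfg), seed = 1, register = FALSE)
  cfg0 <- fast_config(noise = FALSE)
  res0 <- analyze_scene(build_scene(cfg0), seed = 1, register = FALSE)
  cortex <- res0$scene$truth$labels == 1L
  expect_gt(mean(res$quant$maps$vp_pct[cortex]),
            mean(res0$quant$maps$vp_pct[cortex]))
  expect_lt(mean(res$quant$maps$thct_frac[cortex]), 0.296)
})
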