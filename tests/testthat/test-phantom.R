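test_that("phantom truth maps satisfy vrbc + vp = vv with the configured
           regional values", {
  ph <- make_phantom(list(phantom_region("roi", 1, "rect", vv_pct = 3.0,
                                         thct_frac = 0.29,
                                         r0 = 2, r1 = 9, c0 = 2, c1 = 9)),
                     nrow = 12, ncol = 12)
  in_roi <- ph$labels == 1L
  expect_equal(unique(ph$vrbc_pct[in_roi]), 0.87)   # 0.29 * 3.0
  expect_equal(unique(ph$vp_pct[in_roi]), 2.13)     # 0.71 * 3.0
  expect_identical(ph$vrbc_pct + ph$vp_pct, ph$vv_pct)
  expect_true(all(ph$vv_pct[!in_roi] == 0))
  expect_true(all(is.nan(ph$thct_frac[!in_roi])))
})

test_that("an empty region list yields an all-background phantom", {
  ph <- make_phantom(list(), nrow = 8, ncol = 8)
  expect_true(all(ph$labels == 0L))
  expect_true(all(ph$vv_pct == 0) && all(ph$vrbc_pct == 0))
})

test_that("overlapping regions error unless marked as overlays", {
  r1 <- phantom_region("a", 1, "rect", 3, 0.3, r0 = 1, r1 = 5, c0 = 1, c1 = 5)
  r2 <- phantom_region("b", 2, "rect", 2, 0.2, r0 = 4, r1 = 8, c0 = 4, c1 = 8)
  expect_error(make_phantom(list(r1, r2), nrow = 10, ncol = 10), "overlap")
  r2o <- phantom_region("b", 2, "rect", 2, 0.2, overlay = TRUE,
                        r0 = 4, r1 = 8, c0 = 4, c1 = 8)
  ph <- make_phantom(list(r1, r2o), nrow = 10, ncol = 10)
  expect_identical(ph$labels[5, 5], 2L)
})

test_that("the default control brain carries the reported regional
           hematocrit ordering (cortex > striatum > white matter)", {
  ph <- make_phantom()
  t_cortex <- unique(ph$thct_frac[ph$labels == 1L])
  t_striatum <- unique(ph$thct_frac[ph$labels == 2L])
  t_wm <- unique(ph$thct_frac[ph$labels == 3L])
  expect_equal(t_cortex, 0.296)
  expect_equal(t_striatum, 0.288)
  expect_equal(t_wm, 0.280)
  expect_true(t_cortex > t_striatum && t_striatum > t_wm)
  # vessel disks: high vascular volume, hematocrit of the surroundings
  expect_true(all(ph$vv_pct[ph$labels == 9L] == 30))
  expect_true(all(ph$thct_frac[ph$labels == 9L] %in% c(0.296, 0.280)))
})

test_that("blood panels derived from whole blood are internally
           consistent", {
  p <- make_blood_panel(c_tc_blood = 0.8, c_i_blood = 0.06, bhct = 0.40)
  expect_equal(p$c_tc_rbc, 2.0)
  expect_equal(p$c_i_plasma, 0.1)
  # symmetric case
  p2 <- make_blood_panel(1, 1, bhct = 0.5)
  expect_equal(p2$c_tc_rbc, 2)
  expect_equal(p2$c_i_plasma, 2)
  expect_error(make_blood_panel(1, 1, bhct = 1.2), "\\(0, 1\\)")
  # dose-based panel scales linearly with dose
  pa <- blood_panel_from_doses(45.2, 3.9, blood_mass_g = 18.8, bhct = 0.4)
  pb <- blood_panel_from_doses(2 * 45.2, 2 * 3.9, blood_mass_g = 18.8,
                               bhct = 0.4)
  expect_equal(pb$c_tc_blood, 2 * pa$c_tc_blood)
  expect_equal(pb$c_i_plasma, 2 * pa$c_i_plasma)
})

test_that("rendered exposures follow the forward model", {
  cfg <- fast_config(noise = FALSE)
  scene <- build_scene(cfg)
  rend <- render_exposures(scene$truth, scene$panel, scene$layout,
                          scene$windows, seed = 1)
  bg <- scene$layout$noise$bg_offset
  # background pixels carry exactly the offset
  expect_true(all(rend$exp1$psl[scene$layout$bg_mask] == bg))
  # pure-125I spot: exp2/exp1 ratio is constant and equals the
  # theoretical window ratio
  m <- scene$layout$pure_i_mask
  ratio <- (rend$exp2$psl[m] - bg) / (rend$exp1$psl[m] - bg)
  expect_equal(max(ratio) - min(ratio), 0, tolerance = 1e-12)
  expect_equal(mean(ratio),
               window_ratio(iso_i125(), scene$windows$exp1,
                            scene$windows$exp2),
               tolerance = 1e-9)
  # linearity: doubling all panel concentrations doubles expected PSL
  p2 <- blood_panel(2 * scene$panel$c_tc_blood, 2 * scene$panel$c_i_blood,
                    scene$panel$bhct_capillary)
  layout2 <- scene$layout
  layout2$pure_i_conc_mbq_g <- 2 * layout2$pure_i_conc_mbq_g
  rend2 <- render_exposures(scene$truth, p2, layout2, scene$windows,
                            seed = 1)
  expect_equal(rend2$expected1, 2 * rend$expected1, tolerance = 1e-12)
  expect_equal(rend2$expected2, 2 * rend$expected2, tolerance = 1e-12)
})

test_that("an all-zero scene renders to a flat background offset", {
  ph <- make_phantom(list(phantom_region("roi", 1, "rect", 0, 0,
                                         r0 = 60, r1 = 90, c0 = 60,
                                         c1 = 90)),
                     nrow = 160, ncol = 160)
  layout <- scene_layout(ph, pure_i_conc_mbq_g = 0,
                         noise = list(enabled = FALSE))
  panel <- blood_panel(0, 0, 0.4)
  rend <- render_exposures(ph, panel, layout, seed = 1)
  expect_true(all(rend$exp1$psl == layout$noise$bg_offset))
  expect_true(all(rend$exp2$psl == layout$noise$bg_offset))
})

test_that("99mTc contributes less than 1e-6 of its first-exposure signal
           to the second exposure", {
  cfg <- fast_config(noise = FALSE)
  scene <- build_scene(cfg)
  # Tc-only scene: silence every 125I source
  panel_tc <- blood_panel(scene$panel$c_tc_blood, 0,
                          scene$panel$bhct_capillary)
  layout_tc <- scene$layout
  layout_tc$pure_i_conc_mbq_g <- 0
  rend <- render_exposures(scene$truth, panel_tc, layout_tc,
                           scene$windows, seed = 1)
  hot <- rend$expected1 > 0
  expect_true(any(hot))
  expect_lt(max(rend$expected2[hot] / rend$expected1[hot]), 1e-6)
})

test_that("rendering is deterministic given the seed", {
  cfg <- fast_config(noise = TRUE)
  scene <- build_scene(cfg)
  r1 <- render_exposures(scene$truth, scene$panel, scene$layout,
                         scene$windows, seed = 42)
  r2 <- render_exposures(scene$truth, scene$panel, scene$layout,
                         scene$windows, seed = 42)
  expect_identical(r1$exp1$psl, r2$exp1$psl)
  expect_identical(r1$exp2$psl, r2$exp2$psl)
})

test_that("rigid offsets: identity is bit-exact, integer shifts are exact,
           and round trips recover the image", {
  cfg <- fast_config(noise = FALSE)
  scene <- build_scene(cfg)
  img <- render_exposures(scene$truth, scene$panel, scene$layout,
                          scene$windows, seed = 1)$exp1
  expect_identical(apply_rigid_offset(img, 0, 0, 0)$psl, img$psl)
  # integer translation is exact
  sh <- apply_rigid_offset(img, 3, -2, 0)
  expect_identical(sh$psl[11:100, 11:100], img$psl[13:102, 8:97])
  # round trip within interpolation tolerance (< 1% of dynamic range) on
  # band-limited content, where bilinear resampling is near-exact
  rr <- matrix(1:160, 160, 160); cc <- t(rr)
  smooth <- 100 * exp(-((rr - 70)^2 + (cc - 90)^2) / (2 * 18^2)) +
    60 * exp(-((rr - 110)^2 + (cc - 50)^2) / (2 * 12^2))
  rt <- duohct:::resample_rigid(
    duohct:::resample_rigid(smooth, 4.3, -2.7, 1.5),
    4.3, -2.7, 1.5, inverse = TRUE)
  interior <- matrix(FALSE, 160, 160)
  interior[21:140, 21:140] <- TRUE
  dr <- diff(range(smooth))
  expect_lt(max(abs(rt[interior] - smooth[interior])), 0.01 * dr)
  expect_error(apply_rigid_offset(img, 30, 0, 0), "<= 20")
  expect_error(apply_rigid_offset(img, 0, 0, 8), "<= 5")
})
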