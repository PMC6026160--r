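---
title: "Mapping tissue hematocrit by dual-isotope autoradiography: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping tissue hematocrit by dual-isotope autoradiography: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duohct)
```

## The measurement problem

Tissue hematocrit (tHct) — the red-blood-cell volume fraction of the blood
actually residing in the microvasculature — is lower than the hematocrit of
a large-vessel blood sample (the Fahraeus effect) and can change locally in
stroke and tumours. Mapping it in a single animal requires measuring, in the
same tissue section, two tracer distribution volumes:

* **Vrbc**, the red-blood-cell distribution volume, from RBCs labelled with
  a short-lived emitter (99mTc, half-life 6 h), and
* **Vp**, the plasma distribution volume, from albumin labelled with a
  long-lived emitter (125I, half-life 59.4 days).

Both tracers are injected together; after a short equilibration the animal
is euthanised (t = 0 for all decay corrections) and cryosections are exposed
twice on a phosphor-imager plate:

* **Exp1**, overnight, records both isotopes;
* **Exp2**, a week later and a week long, records essentially pure 125I —
  after ~28 half-lives the 99mTc signal is below 1e-6 of its Exp1 level.

Subtracting a properly rescaled Exp2 from Exp1 yields the 99mTc-only image.
Each separated image is converted to activity concentration (MBq/g) against
a 1:50 diluted-blood standard cut and exposed with the tissue, and the maps
follow as

$$V_{rbc} = 100\,\frac{C^{tissue}_{Tc}}{C^{RBC}_{Tc}},\qquad
  V_{p} = 100\,\frac{C^{tissue}_{I}}{C^{plasma}_{I}},\qquad
  V_v = V_p + V_{rbc},\qquad
  tHct = \frac{V_{rbc}}{V_{rbc}+V_p}.$$

The composition rules for $V_v$ and $tHct$ are the only forms consistent
with the definition of a distribution volume and with the requirement that
whole blood analysed this way returns the large-vessel hematocrit; we adopt
them as the package's definitions. No small-vessel/large-vessel correction
factor is applied: reported values are direct ratios.

The reference concentrations $C^{RBC}_{Tc}$ and $C^{plasma}_{I}$ are the
centrifuged-fraction concentrations of the blood panel. When only whole-blood
concentrations and the capillary hematocrit are available they are derived by
mass balance, $C^{RBC}_{Tc} = C^{blood}_{Tc}/bHct$ and
$C^{plasma}_{I} = C^{blood}_{I}/(1-bHct)$ — each tracer is confined to its
own compartment. The fraction-based default avoids circularity when the
autoradiographic hematocrit estimate is compared with the capillary method.

## Decay physics and timing conventions

All concentrations are stated at t = 0 (euthanasia); exposure windows are
hours after t = 0. The signal collected in a window is proportional to the
decays accumulated in it,

$$\int_{s}^{s+d} 2^{-t/T_{1/2}}\,dt
  = \frac{T_{1/2}}{\ln 2}\,2^{-s/T_{1/2}}\left(1-2^{-d/T_{1/2}}\right),$$

computed with `expm1` so the long-half-life limit degrades gracefully to the
window duration. The theoretical Exp2/Exp1 intensity ratio of 125I
(`window_ratio`) is ~9.33 for the default windows; the pipeline never uses
the theoretical value, instead estimating the factor empirically from the
pure-125I drop, exactly as the plate protocol prescribes — the theoretical
value serves as an oracle in the tests.

Default windows are Exp1 = [2, 18] h and Exp2 = [170, 338] h. The protocol
only states "overnight" and "one week later, one week long"; the start delay
of 2 h covers tissue handling and is configurable, and none of the
quantification depends on the choice because calibration is internal.

## The synthetic phantom and what it does (and does not) emulate

`make_phantom()` rasterises a coronal-section-like scene: a cortical rim
(tHct 0.296), two striatal disks (0.288), deep white matter (0.280) — the
regional values reported for control animals — plus large-vessel disks
(vascular volume 30%, hematocrit equal to their surround) and an optional
low-hematocrit lesion. Vascular volumes are higher in cortex (3.5%) than
striatum (2.8%) and white matter (2.0%), reproducing the observed regional
contrast in Vv but not in tHct. The default grid is 160 x 160 pixels at
50 µm — the plate reader's pixel size is not documented, so 50 µm is a
configurable assumption; every size here was chosen once as a realistic
desk-scale study condition.

`render_exposures()` is the forward model: expected PSL per pixel and window
is the sum over isotopes of

$$\mathrm{gain}_{iso}\cdot C_{iso}\cdot m_{px}\cdot
  \mathrm{integrated\_decay}(iso, w),$$

with $m_{px}$ the section mass per pixel (thickness 100 µm x density
1.04 g/mL x pixel area). One thickness/density applies to the whole scene —
tissue and reference spots are cut on the same cryostat — which is what
makes the diluted-blood calibration cancel gain, geometry and exposure
duration exactly. The per-isotope plate gains are deliberately unequal by
default (1.0e8 vs 1.6e8 PSL per decayed MBq·h) so that any code path that
failed to calibrate each isotope separately would fail the recovery tests.

Noise is Poisson on photostimulated counts (expected PSL divided by a
0.05 PSL quantum, giving a few hundred counts per overnight tissue pixel),
plus Gaussian read noise (SD 0.2 PSL) and a uniform plate fog offset
(1 PSL), all seeded. The blood panel defaults derive whole-blood
concentrations from the nominal injected doses (45.2 MBq 99mTc-RBC, 3.9 MBq
125I-albumin) diluted into a 7%-of-body-weight rat blood pool (18.8 g),
capillary bHct 0.401.

Not emulated: plate fading between exposure and scan, dead time, scatter,
chemography, 3-D sectioning artefacts, and partial RBC/plasma labelling
specificity. Tracer leakage is off by default but available
(`leak_i_frac`) to demonstrate how albumin extravasation inflates Vp and
depresses the hematocrit estimate. Passing the recovery tests therefore
shows the analysis chain is exact under the stated physics, not that real
plates are free of these effects.

## Separation, registration, calibration

Order of operations matches the plate protocol: background subtraction
(median over the background mask — plates have a non-zero fog level),
intensity correction of Exp2 to Exp1 using the pure-125I drop, rigid
co-registration, subtraction, clamping of noise-driven negatives to zero
(fraction reported). The correction factor is a scalar: a single reference
drop supports nothing finer. Residual 99mTc in Exp2 is ignored (bounded
below 1e-6 by the default timing). When the sheet was repositioned between
exposures the pure-spot ROI is relocated on Exp2 by cross-correlating the
image with the ROI mask, and both spot ROIs are eroded by 2 pixels so
partially-sampled edge pixels cannot bias the ratio.

Registration estimates translation by spectral cross-correlation with
quadratic sub-pixel peak interpolation, and rotation by a coarse-to-fine
grid search over ±5° (0.25° then 0.05°) followed by a joint Nelder–Mead
polish of (dx, dy, θ) on the alignment correlation. Three numerical
choices matter:

* both images are pre-filtered with a Gaussian (SD 1.2 px) for matching
  only — band-limiting removes the bias that sharp region edges otherwise
  induce in the correlation optimum under bilinear resampling;
* candidates are scored on the correlation of the *fully aligned* image
  over a fixed central window (16-px margin), so the zero-rotation
  candidate enjoys no interpolation advantage and neither circular
  wrap-around nor content clipped at the frame edge distorts the
  comparison;
* the coordinate convention is fixed: row-major grid, origin top-left,
  x = columns, y = rows, rotation about the image centre; the transform
  maps Exp2 coordinates into Exp1's frame.

With these choices the estimator recovers offsets up to ±10 px / ±2°
within 0.2 px and 0.2° on the default phantom, against a 0.5 px / 0.25°
contract. Degenerate inputs (contrast-free images, correlation below 0.1)
raise a registration-failure error with diagnostics rather than returning
a silent identity.

## Hematocrit estimators and statistics

The diluted-blood spot is whole blood, so the mean tHct over it estimates
the systemic hematocrit (`arg_bhct`) — the dilution cancels in the ratio.
A noiseless round trip returns the configured bHct to machine precision;
`simulate_bhct_study()` renders a hemodilution/control/EPO cohort (group
means 0.34/0.40/0.50, between-animal SD 0.02, 8 animals per group — the
published validation used 24 animals across those three challenges) and the
agreement fit of estimated on true bHct gives slope ≈ 1, r² ≈ 1. The
gamma-well path (`gwc_hct`, `gwc_table`) applies the same two-volume
arithmetic to counted samples; a whole-blood sample returns the capillary
value identically when the panel is internally consistent.

ROI statistics use the sample SD (n − 1) and report mean ± SD, matching the
study's convention; masked (NaN) pixels are excluded and their fraction
reported. tHct is undefined (NaN) where Vv < 0.5% — below that floor the
ratio is numerically meaningless in avascular background. Histograms use
1-percentage-point bins on [0, 60]% by default; out-of-range values are
clamped into the end bins so frequencies always sum to one.
`vessel_contrast` expresses structure conspicuity in surround-SD units; in
the noiseless limit a uniform surround has zero SD, so a mean difference at
floating-point level (≤ 1e-8 relative) is defined as zero contrast and a
genuine difference over zero SD as infinite — the noiseless vessel check
("bright in Vv, invisible in tHct") is exactly this dichotomy.

## File formats

Maps are float NIfTI volumes (NaN = masked), masks and labels integer
NIfTI, tables CSV, configuration and reports JSON carrying a
`schema_version` and the resolved configuration + seed, so every run
directory is reproducible from its own provenance record. NIfTI is the
standard lossless float container for brain maps in R; the layout masks are
encoded in one label image (0 background, 1 tissue, 2 blood spot, 3
pure-125I spot).

## Problem sizes and limitations

The validation suite runs on the 160 x 160 default scene: 10 random
configurations for noiseless recovery, 20 seeded trials for registration,
24 simulated animals for the hematocrit agreement study, 8 per group for
noisy regional recovery — sizes chosen so the whole suite completes in
about half a minute while leaving each property statistically
unambiguous. Known limitations: a scalar inter-exposure correction (one
reference drop), rigid-only registration (no elastic ARG-to-MRI
coregistration, which is out of scope — ROI masks are supplied), no
partial-volume correction, and equilibration treated as achieved at t = 0.
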