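---
title: "LED-based wavelength-scanning hyperspectral imaging: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{LED-based wavelength-scanning hyperspectral imaging: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ledhsi)
```

## The measurement principle

A wavelength-scanning hyperspectral imager built from an LED array and a
monochrome camera acquires one spectral band at a time: each of the Λ
narrowband LEDs is pulsed in turn (pulse width PW, inter-channel delay DT,
both in camera frame periods) while the camera records a frame, and the Λ
frames are stacked into a hypercube I(x, y, λ). Compared with
filter-wheel or tunable-filter scanning, LED switching is fast and
low-power, which is what makes endoscopic and capsule-scale hyperspectral
imaging plausible. The price is strongly inhomogeneous illumination — one
discrete emitter per band, each with its own spectral width, viewing angle
and position — which the flat-field calibration must remove.

`ledhsi` implements the full chain as a simulator plus processing pipeline:
a parametric instrument model, a phantom-scene forward model with a
realistic noise stack, flat-field calibration, hyperintense
background/glare segmentation, rigid alignment with mask-overlap ROI
construction, spectral-signature extraction and normalization, SNR
measurement, and per-band group testing. Because every input is synthetic
with known ground truth, each stage's correctness is demonstrated by
recovery rather than by eye.

## Instrument model

The default 18-channel array spans 405–910 nm; per channel the data-sheet
peak wavelength, spectral half width (FWHM) and full viewing angle are
built in (`led_array_default()`, also available as a YAML config in
`inst/extdata/`). Emission lines are modeled as unit-peak Gaussians with
the data-sheet FWHM — only FWHM-type information is published for these
parts, and a Gaussian keeps every downstream integral analytically
checkable. The default camera is a 1280 × 720 monochrome sensor, 120 fps
maximum, 90° diagonal field of view, 10-bit digitization.

Closed-form calculators cover the acquisition bookkeeping:

* `hypercube_rate(fps, Λ, timing)` = fps / (Λ·(PW + DT)). At 120 fps with
  18 channels and PW = DT = 1 frame this gives 3.33 hps; at 600 fps with 30
  channels and DT = 0 it gives 20 hps, the conventional real-time floor.
  The two operating points assume different DT — the timing is
  configuration, not code path.
* `transfer_rate(link, rows, cols, Λ, bit_depth)`: a 400 Mbps link moves a
  10-bit, 30-channel, 256 × 256 cube at 21.33 hps under the binary
  (2²⁰ bits/Mbit) reading, which is the package default because it is the
  reading consistent with the rate quoted for that configuration; the
  decimal reading (20.35 hps) is selectable.
* `pixel_pitch()` and `fov_extent()` give the target-plane sampling: 91 mm
  across 1280 pixels is a 71 µm pitch; 102 mm across 2048 pixels is 50 µm.

## Scene and camera forward model

Phantoms (`make_phantom()`) are elliptical "tissue" regions with smooth
parametric reflectance spectra (baseline + Gaussian bumps, widths ≥ 10 nm,
clipped to [0, 1]) on a bright dish of flat reflectance 0.95, with small
saturating glare spots. The built-in presets are qualitative tissue-like
shapes; the kidney-like/tumor-like pair is constructed with clear contrast
at the 505 and 660 nm bands so that planted group differences sit at known
bands.

Each captured frame is

> counts = full_well · exposure · illumination(x, y) · g(band) · R_eff(x, y)
> \+ dark (+ noise), quantized to the bit depth,

where g(band) is the emission-weighted sensor spectral response and R_eff
the emission-and-response-weighted scene reflectance over a 1 nm wavelength
grid (380–1000 nm, trapezoid weights). Two modeling choices deserve
explanation:

* **Band-effective reflectance as ground truth.** Because an LED line has
  finite width (up to 75 nm FWHM at 890 nm), the calibrated measurement
  converges to the spectrum averaged over the emission line, not to the
  value at the center wavelength; for a smooth spectrum with 30–50 nm
  features the two can differ by several percent — far more than a
  quantization step. `phantom_band_truth(effective = TRUE)` computes the
  weighted truth used in recovery tests; the center-wavelength samples are
  kept alongside (`effective = FALSE`) for interpretation.
* **Illumination with a stray-light floor.** Each LED paints a Gaussian
  footprint centered at its lateral offset, FWHM diameter
  2·d·tan(viewing angle/2), peak equal to its relative power: the 14°
  parts starve the corners while the 102° part floods the field, which is
  exactly the inhomogeneity calibration must cancel. On top of the
  footprint a uniform 2% stray-light term models diffuse scatter inside
  the imaging enclosure; it keeps white-reference counts above the dark
  level across the frame at the default 70 mm working distance. Since
  calibration divides out the illumination whatever its shape, this floor
  changes nothing about recovery; tests that specifically exercise
  denominator masking set `stray_fraction = 0`.

The noise stack is the minimal one that makes SNR measurement meaningful:
Poisson shot noise on the signal, Gaussian read noise, and a constant dark
offset with a fixed-pattern spatial component shared by all captures from
the same camera. Quantization is round-half-up with clipping. Glare is
modeled as forced saturation rather than a specular BRDF — sufficient to
exercise hyperintense-region removal. All randomness flows from explicit
seeds; noiseless captures are seed-independent by construction.

## Calibration

`flat_field_calibrate()` applies, per pixel and band,

> Î = (I − I_D) / (I_W − I_D),

with a dark capture I_D and a white-reference stack I_W (flat reflectance
0.99). Pixel-bands whose denominator is at or below ε × full scale
(default ε = 10⁻³) are masked invalid rather than clamped or in-painted:
below that level the denominator is noise-dominated and residual
illumination artifacts should be flagged, not amplified. Values above 1
are preserved — glare must stay hyperintense for segmentation to find it.
Recovery is exact by construction: in a noiseless simulation the
calibrated cube matches the band-effective phantom reflectance ÷ 0.99
within one quantization step at every valid pixel-band, and white-reference
self-calibration is exactly 1.

## Segmentation, alignment, ROI

Segmentation thresholds a per-pixel aggregate (default: maximum across
valid bands, since glare saturates in some bands only) by histogram
analysis (Otsu; percentile selectable). The aggregate is capped at 1.5
before the histogram is formed: where the white denominator is small,
saturated glare can calibrate to tens of units, and letting those few
outliers stretch the histogram would push the threshold above the dish
mode. Beyond full reflectance, everything is equally hyperintense. An
optional morphological opening (radius in pixels) removes speckle.

Cross-system alignment uses rigid (similarity) transforms — translation,
rotation, isotropic scale about the image center — applied with bilinear
interpolation for images and nearest-neighbor for masks, with out-of-bounds
pixels reported invalid. `estimate_rigid()` is an automated convenience
(the procedure it replaces is manual): grid search maximizing normalized
cross-correlation, with a deterministic smallest-transform tie-break and a
reported confidence (NCC) so that structureless pairs are flagged rather
than silently mis-registered. The common ROI of two systems is the logical
intersection of their masks (`mask_overlap()`).

## Signatures and statistics

`extract_signature()` averages valid ROI pixels per band; min–max
normalization Ŝ = (S − S_min)/(S_max − S_min) across bands removes
brightness differences between systems and specimens. SNR is
20·log₁₀(μ/σ) in dB; a pure shot-noise field of mean N counts measures
10·log₁₀(N) dB, which anchors the simulator's noise calibration (30 dB at
N = 1000).

`compare_groups()` runs per-band two-sample t-tests (pooled-variance
Student by default, Welch selectable) with one-tailed p-values in a
direction that must be declared a priori; deriving the direction from the
data inflates the type-I error and is only available behind an explicit
warning. The sampling unit is one specimen's ROI-mean signature, not
pixels — pixel-level testing pseudo-replicates thousands of correlated
samples. No multiple-testing correction is applied by default (per-band
α = 0.05 across 18 bands); Bonferroni and Benjamini–Hochberg are
selectable, and exact set recovery of planted effects is only a
well-posed expectation under family-wise control.

Two properties pin the statistics down. Under the null (both groups drawn
from the same per-band normal distribution, direction fixed a priori, 10
specimens per group), the per-band flag rate over 2000 replicates matches
α within two Monte-Carlo standard errors; this check runs on raw
signatures, where the pooled t is exact — min–max normalization couples
bands through the shared extrema and is the pipeline default for real
comparisons, not the right null model for a size check. With effects of
3σ planted at the 505 and 660 nm bands, power exceeds 0.9 at the planted
bands while other bands stay at the α level.

## Problem sizes, tolerances, and reproducibility

Simulated scenes in the tests are 32–64 px square with the full 18-band
array — small enough to iterate quickly, large enough that segmentation,
registration and ROI statistics are non-trivial. The statistical
calibration uses 2000 null replicates and 200 power replicates. Numerical
tolerances are stated next to their source: 1 quantization step for
recovery (the rounding bound of numerator and denominator), 2% of range
for rigid round-trips judged away from the frame border (bilinear
resampling blends background into a border ring, which is out-of-bounds
contamination rather than interpolation error), 0.5 dB for Monte-Carlo
SNR, two MC standard errors for the flag rate.

Everything an acquisition produces can be written and re-read: ENVI
(header + BSQ; bit-exact for integer counts and float64 reflectance, with
the validity mask as a companion file), multi-page TIFF with a JSON band
sidecar (bit-exact counts; reflectance as scaled float32, since TIFF float
pages are clamped to [0, 1] on read), PNG masks, JSON transforms, CSV
signatures and comparisons. `generate_fixtures()` writes a complete
session (dark, white stack, noiseless and noisy phantom cubes, ground
truth, manifest) that is byte-identical under a fixed seed, and the
`ledhsi` command-line interface (`inst/cli/ledhsi.R`) chains
simulate → calibrate → segment → signature → compare plus the timing
calculators.

## What the synthetic tests do and do not show

The phantom world is deliberately simple: flat, axis-normal targets;
Gaussian emission lines and footprints; no tissue optics (absorption and
scattering), no surface relief or shadows, no lens distortion or
vignetting, no LED thermal drift, no deformable motion between systems.
Passing tests therefore demonstrate that the *processing chain* is correct
— calibration inverts the forward model it claims to invert, segmentation
and statistics recover what was planted — not that any particular real
tissue is separable at particular bands. Real-tissue signature contrast,
and how many bands reach significance, depend on the specimens; in this
package those appear only as planted, configurable effects.
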