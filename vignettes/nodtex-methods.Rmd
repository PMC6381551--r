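---
title: "Simulation model, feature definitions and statistical conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulation model, feature definitions and statistical conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nodtex)
```

`nodtex` studies how CT scan parameters — slice thickness, tube current
and reconstruction kernel — move radiomic feature values, on a fully
synthetic stand-in for a physical thorax-phantom experiment. This
vignette records the model, every tunable that matters, and the design
decisions that were genuinely open, so that results can be read with
the right amount of trust.

## The phantom and the renderer

The scene is a homogeneous lung-like box (default −850 HU; the real
aerated lung parenchyma sits near −800 to −900 HU) holding four
spherical nodules: 10 and 12 mm diameters at +100 HU (solid) and
−630 HU (ground-glass). No vasculature, airways or body wall are
modelled; the background attenuation of the physical phantom is not
public, so −850 HU is this package's choice.

Rendering one scan proceeds in four steps:

1. **Supersampled rasterization.** Each sphere is sampled on a grid of
   at most 0.25 mm per axis and block-averaged to the protocol grid
   (in-plane 0.7 mm — typical of a thorax field of view on a 512
   matrix — and z spacing equal to the slice thickness). Thick slices
   therefore dilute edge voxels more: the partial-volume effect falls
   out of the averaging rather than being modelled separately. A
   slice-sensitivity profile would be more faithful to a helical
   scanner but adds parameters this study cannot constrain.
2. **Interior heterogeneity.** Real nodule inserts are not perfectly
   uniform, and perfectly uniform spheres give degenerate texture
   matrices. Each nodule receives a Gaussian random field of SD 5 HU
   and correlation length 2 mm, generated on a fixed 1 mm physical
   lattice and sampled at the supersample points — so a 5 mm slice
   genuinely averages fine texture down instead of seeing a
   grid-resolution copy of it. Amplitude is configurable; 0 disables.
3. **Reconstruction-kernel point spread.** In-plane Gaussian blur:
   σ = 0.45 mm for the standard kernel (≈1.05 mm FWHM) and σ = 0.25 mm
   plus an unsharp-mask edge term (boost 0.3, σ 0.7 mm) for the lung
   kernel. The widths sit in the range of published resolution
   measurements for smooth vs sharp thorax kernels, and the edge boost
   is kept small enough that the interior of a 12 mm nodule stays
   within ±10 HU of its nominal density on a noise-free render.
4. **Noise.** Zero-mean Gaussian noise with
   σ = 12 HU · √(120/mAs) · √(5.0/T) · k(kernel), k(lung) = 2,
   k(standard) = 1. The 1/√mAs and 1/√T laws are standard quantum-noise
   scalings; the reference value 12 HU and the kernel factor 2 are
   calibrated only to reproduce the qualitative orderings expected of
   CT reconstructions (noise falls with dose and thickness, sharp
   kernels are noisier), not any measured scanner. Noise is added after
   the blur, so the protocol's σ is exactly what a uniform region
   measures.

Ground-truth masks mark voxels with at least 50 % subsample occupancy.
The design crosses 12 protocols with 10 repetitions; each repetition
relocates every nodule by an independent uniform jitter of ±2 mm per
axis (the amplitude of repositioning is not documented for the physical
experiment; 2 mm is a plausible manual-placement scatter). A master
seed deterministically derives one child seed per scan, so any single
scan reproduces in isolation.

The simulation emulates: partial volume versus slice thickness,
dose- and kernel-dependent noise, kernel sharpness, and repositioning
variability. It does **not** emulate: sinogram-domain physics, beam
hardening, iterative-reconstruction nonlinearity, vessel attachment, or
respiratory/cardiac motion. Tests passing on this generator therefore
validate the *pipeline arithmetic and its sensitivity logic*, not
scanner realism.

## Segmentation

Seeded region growing over 26-connected neighbours with a **frozen**
inclusion interval — either fixed HU bounds ([−200, 400] for solid,
[−800, −400] for ground-glass nodules) or an interval m ± k·s taken
from the 3×3×3 neighbourhood of the seed before growth. Freezing makes
the result a pure function of (volume, criterion, seed component):
drifting intervals would be growth-order-dependent and untestable. The
seed itself is placed automatically at the maximum-HU voxel within
5 mm of the nominal centre, ties broken by lowest (i, j, k).

The original workflow had a radiologist review and edit contours. That
is replaced by automation in two ways: the pipeline grows on a working
copy smoothed by a 0.8 mm Gaussian (without it, the worst protocol —
1.25 mm / 30 mAs / lung, σ = 96 HU — lets the inclusion interval
percolate through background noise), and every mask passes QC
(voxel count, volume, voxel-face sphericity flagged at ≤ 0.6, border
contact, Dice against ground truth). Masks are flagged, never edited;
ground truth is substituted, and flagged, only if growing fails
outright. No hole filling or morphological smoothing is applied, so
the mask remains a pure function of the criterion.

## Quantization and features

Gray levels come from the fixed global window: g = ⌊(HU + 1024)/16⌋,
exactly 16 raw levels per bin, 256 bins. A per-ROI min–max window
would inflate apparent differences between protocols by moving the
quantization itself; the fixed window keeps gray levels comparable.

Histogram moments are **population** moments of the per-voxel
quantized values, with excess kurtosis (Gaussian → 0) and skewness and
kurtosis defined as 0 for zero variance; energy and entropy act on the
256-bin normalized histogram, entropy in the standard Shannon form.
Whether the original implementation took moments on raw HU or
quantized values is not recoverable; quantized values are used, and
because the regression consumes min–max-scaled features, the affine
part of that choice washes out.

Co-occurrence matrices accumulate single-direction (asymmetric)
counts — that is what makes the worked toy-grid count come out at 2 —
with a symmetric option behind a flag. Run-length matrices count each
maximal run once; features use run-count-normalized probabilities
(unnormalized nonuniformities would scale with ROI size) and 1-based
gray weighting in the low/high-gray emphases, since gray level 0 would
otherwise divide by zero.

Both matrix families are computed in the 13 unique directions of the
26-neighbourhood at distance 1 and the features averaged arithmetically
over directions. Directions with no voxel pair or no run (possible for
thin ROIs at 5 mm slices) are excluded from the mean rather than
zero-filled — zero is not a neutral value for any of these features.
One consequence worth stating: energy = √ASM is an exact per-direction
identity, but the direction-*averaged* energy is not the square root of
the direction-averaged ASM; the identity is tested where it is defined.

## Statistics

Each density stratum (240 observations = 12 protocols × 10 repetitions
× 2 diameters; both diameters pooled, matching one regression table
per density) is analysed as:

* **Min–max scaling** per feature across the stratum. The published
  coefficient tables this package bundles have constants and
  coefficients confined to roughly [−0.7, 1.0], which is only
  consistent with normalized features; the scaling constants are
  recorded in the output metadata.
* **OLS with dummy coding**, reference levels 5.0 mm / 30 mAs / lung.
  Pairwise contrasts are linear contrasts of the fitted coefficients
  (2.5 vs 1.25 mm = β(1.25) − β(2.5)), with two-sided t tests.
* **|RC| summaries** use the *lower* median (10th of 20 ordered
  absolute values). Three of the four verifiable published summary
  columns match the lower median exactly; the fourth matches the upper
  median and is treated as a transcription slip rather than a reason
  to mix conventions.
* **Cohen's d** pools all observations at one factor level against all
  at another (one d per factor contrast), with the pooled-SD
  denominator and 0.20/0.50/0.80 class bounds; the direction symbol
  comes from a Welch t test at p ≤ 0.05, chosen for robustness to the
  unequal variances different protocols produce.
* **No multiplicity adjustment** in the headline tallies, mirroring
  the original analysis; a Holm-adjusted column is emitted alongside
  for readers who want it.

## Numerical conventions and degenerate inputs

Probability normalizations are checked to 1e−12; internal identities
(variance = SD², per-direction energy² = ASM) to 1e−9. GLCM correlation
is defined as 1 with a degeneracy flag when a marginal SD is 0 (a
perfectly homogeneous ROI is perfectly linearly dependent). Empty
masks, seeds failing their criterion, rank-deficient designs, constant
feature columns and zero-run matrices all raise errors naming the
offending object; zero pooled SD with unequal means yields an
infinite-d flag rather than a silent number.

## Problem sizes

The test suite runs the full factorial at one repetition (48 nodule
observations) for end-to-end checks, brute-force oracle comparisons on
grids up to 6³ over all 13 directions and 20 random draws, and
regression calibration on 50 synthetic replicates per noise setting;
the whole suite completes in about a minute. The acceptance script
runs the complete 12 × 10 study (480 observations) and finishes in a
few minutes on one CPU.

## Limitations

Simulated coefficients quantify the *simulation's* parameter
sensitivity; they are not estimates of any physical scanner's values,
and the bundled reference coefficient tables are carried as data for
worked-example arithmetic, not as targets the simulation should hit.
The noise and PSF constants are plausibility-calibrated, not fitted.
Segmentation quality on the noisiest protocols (median Dice ≈ 0.85
against ground truth) is part of the measured pipeline variance, just
as imperfect manual contours were part of the original study's.
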