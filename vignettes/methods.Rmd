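---
title: "Methods: internal dose of inhaled nanoplastics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: internal dose of inhaled nanoplastics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanoburden)
```

This vignette documents the models behind `nanoburden`, the defaults and why
they were chosen, the numerical decisions, and what the synthetic-data
generator does and does not emulate. The package analyses a 28-day rat
inhalation study of two nanoplastics — fluorescently labelled polystyrene
(PS) quantified by 3D confocal microscopy, and polyamide (PA-6) quantified
by pyrolysis-GC/MS — together with the aerosol metrics and clearance
kinetics around them.

## Synthetic confocal stacks

A stack is a 3D intensity field on an anisotropic voxel raster. The defaults
follow the acquisition geometry of a 1.40 NA oil-immersion setup: 0.12 µm
lateral voxels over a 246 µm field, 0.30 µm axial steps, stacks roughly
100 µm deep (`image_grid()`).

The forward model in `generate_stack()` is, per voxel,

$$ I = B + \mathrm{fade}(z)\,\big[(S * G)\big] + \varepsilon, $$

where

* $S$ is the sum of solid-sphere indicators, rasterised with sub-voxel
  occupancy sampling. Boundary voxels are sampled on an $n^3$ sub-grid with
  $n$ chosen adaptively (4–16, finer for spheres near the voxel scale) so
  that the integrated signal of a sphere matches its analytic volume to well
  under 1 %. Emitter intensity is expressed per fully occupied voxel.
* $G$ is a separable anisotropic Gaussian with
  $\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$ per axis. The optics are known
  only through resolution figures (≈0.2 µm lateral, ≈0.5 µm axial), and the
  separable Gaussian is the standard desk-scale surrogate at that level of
  information; no ray tracing or aberration model is attempted.
* $\mathrm{fade}(z) = e^{-z/L}$ models the net loss of fluorescence contrast
  with depth (scattering plus refractive-index-mismatch aberrations, lumped).
  The default $L = 53/\ln 4 \approx 38$ µm puts contrast at 53 µm depth at
  ~25 % of its surface value, consistent with objects ceasing to be
  detectable beyond an average depth of about 53 µm in fixed lung tissue.
* $\varepsilon$ combines a mean-proportional ("shot-like") Gaussian term with
  SD $s\sqrt{I}$ and additive Gaussian read noise. No noise model is
  reported for the real acquisition; this is the minimal model with the
  right qualitative behaviour. Negative values are clipped at zero.

Seeds are mandatory arguments everywhere and are recorded in the scene; the
generators never touch global RNG state (`with_seed()` restores
`.Random.seed`). Two generated stacks with the same specification and seed
are bit-identical.

**What the generator does not emulate:** tissue autofluorescence texture
(background is constant), macrophage structure and the scattering channel,
spherical-aberration anisotropy beyond the net fade, and non-spherical
agglomerate shapes. Passing recovery tests on synthetic stacks therefore
demonstrates that the measurement chain (rasterisation → PSF → segmentation
→ sizing → mass) is internally consistent, not that segmentation of real
tissue is error-free.

## Segmentation and sizing

`segment_stack()` offers three backends behind one interface: a global Otsu
threshold, an absolute threshold, and a small random-forest pixel classifier
on multi-scale Gaussian features (raw intensity, blurs at 0.15/0.4/1.0 µm,
difference-of-Gaussian bands), the desk-scale analogue of an interactively
trained pixel classifier. A `sensitive` preset lowers the effective
threshold, emulating the more sensitive but less separative configuration
used for remote organs. Connected components use 26-connectivity in 3D —
the common choice, and the one matching the intent that only clearly
separated objects count as distinct; two emitters closer than the lateral
resolution merge into one larger object, by design.

Per object, `extract_objects()` computes voxel count, physical volume
(always from voxel counts × voxel volume, never from voxel counts alone,
because the voxels are anisotropic), equivalent sphere diameter
$(6V/\pi)^{1/3}$, mean intensity, deepest z position and an edge flag.
Edge exclusion applies to all six faces (the axial faces included, since
"edges" is otherwise ambiguous). Objects of ≤ 5 voxels are discarded as
noise (`filter_noise()`, default `min_voxels = 6`).

Two documented subtleties:

* A single sub-resolution (0.089 µm) emitter appears as ≥ 6 voxels after the
  PSF at high SNR — reproduced with the absolute-threshold backend at a
  detection-level threshold (a few noise SDs above background). A global
  Otsu threshold on a nearly empty stack settles near half the peak, where a
  point source covers fewer voxels. The 6-voxel minimum implies an apparent
  equivalent sphere diameter of 0.37 µm on this raster; the 0.29 µm average
  reported for single particles in the validation film is not reproduced by
  the voxel geometry, and the generator does not attempt to match it.
* **Scanned volume.** The default is the configured stack extent;
  `scanned_volume(..., truncate_at_deepest = TRUE)` instead truncates the
  axial extent at the deepest detected object, a stricter reading of
  "volumes in which objects are detectable". The default is the full extent
  because it is reproducible without a detection step.

## Mass model and PSF volume calibration

Object mass is $m = V \phi \rho$ with packing density $\phi = 0.64$ (random
close packing of irregular agglomerates) and bulk density
$\rho = 1.05$ g/cm³ for PS, applied uniformly to all retained objects.
Concentrations are per (100 µm)³ = 10⁶ µm³; organ burdens scale the mass
concentration by the organ volume (1 mL = 10⁶ × (100 µm)³; lung ≈ 10 mL,
lymph node ≈ 0.03 mL).

Because the PSF inflates apparent volumes (by ~10 % for 2 µm spheres up to
~60 % near the resolution limit), recovered volumes are corrected by a
single multiplicative constant measured by `volume_calibration()`: spheres
of known diameter (default 0.5–2 µm, the dominant size range in tissue) are
rendered one per stack, pushed through the identical segmentation and
filtering, and the volume-weighted ratio of true to recovered volume is the
correction. This mirrors validating the imaging process on a reference
particle film. With Otsu segmentation at the default acquisition parameters
the factor is ≈ 0.93, and total-mass recovery on scenes of 50 well-separated
agglomerates lands within ~15 % of ground truth.

## Pyrolysis-GC/MS quantification

Pyrolysis physics and chromatography are not modelled; the marker fragment
(caprolactam, m/z 113) is metadata. Peak area is linear in analyte mass.
`fit_calibration()` uses ordinary least squares *with* intercept — the
instrument baseline is absorbed rather than forced through the origin.
Calibration masses derive from the documented stock preparations
(`dilution_series_mass()`): 62 mg/25 mL stock → 37–3700 ng standards for
lungs; 49 mg/25 mL → 20–1140 ng for lymph nodes.

`quantify_organ()` back-calculates crucible mass $(A - a)/b$ and scales by
the dilution factor (extract volume / aliquot volume; 1000 for a 20 mL lung
extract and 20 µL aliquot, 75 for a 3 mL node extract and 40 µL aliquot).
Areas at or below the intercept are reported as 0 with a below-range flag.
Below-LOD burdens are reported censored (`"<LOD"`), never as zeros; group
means substitute LOD/2 by default (configurable, including exclusion of
censored animals as done for the five-week lymph-node group).

**Detection limits.** `LOQ = m_{low} \times` dilution. The published
lymph-node limits (LOD 1.2, LOQ 1.5 µg) are consistent with an effective
subtraction of 20 % of the lowest standard before scaling, and that is the
default: `LOD = 0.8 m_{low} ×` dilution; when replicate SDs at the lowest
standard are available a `k·SD` subtraction can be used instead. The exact
formula behind the published pair is not stated, so this reconstruction is
an assumption, documented here. The published lung limits (36/100 µg) do not
follow from the same rule and are carried as reference constants only.

## Aerosol metrics

Gravimetric concentration is mass gain over sampled volume (3 L/min; 120 or
40 min). For the impactor (cutoffs 21, 15, 10, 6.5, 3.5, 1, 0.7, 0.4 µm),
the final filter is counted as the sub-0.4 µm stage so the cumulative
distribution closes at 1. MMAD and GSD come from unweighted probit
regression of the cumulative undersize fraction on log cutoff; endpoint
fractions (0/1) are excluded, and fractions within ~10⁻⁹ of 1 — which carry
almost no floating-point precision — are also dropped when at least three
interior points remain. Noise-free runs round-trip the generating
(MMAD, GSD) essentially exactly over MMAD 0.5–5 µm, GSD 1.2–3. Whether the
published values came from the same convention or from instrument software
is unknown; round-trip tests use the module's own convention. SMPS count
concentration and geometric mean diameter are pass-through instrument
summaries (averaged, not refit).

## Dosimetry and clearance kinetics

Inhaled ("applied") mass is
`minutes × ventilation rate × concentration / 1000` with the rat ventilation
rate `0.8 L/min/kg × body weight` used **unrounded** — 0.216 L/min for a
270 g rat, displayed as 0.22 — which is required to reproduce the 77.8 mg
total for PS. Exposure time is 360 min/day × 20 days (6 h/day, 5 days/week
over 4 weeks), configurable.

Clearance is phase-wise first order. With two timepoints per phase the
clearance constant is the closed form `ln(N_start/N_end)/Δt`; with more, a
log-linear least-squares fit. Phase boundaries are user-supplied sampling
days (5 and 13 weeks), not change-point detection, matching the
interval-wise calculation; the boundary observation anchors both adjacent
phases so the fitted curve is continuous there. `t½·λ = ln 2` holds exactly
by construction. Increasing burdens yield a negative λ with a warning
(growth, not clearance) rather than an error — the lymph-node burdens do
increase post-exposure.

Two documented data points: the published PS half-time of 46 days is not
reproducible from the rounded group means (0.42 → 0.26 ng/(100 µm)³ over
35 days gives 50.6 days; unrounded means were presumably used), and both
values are carried with a 15 % tolerance check. The five-week PA-6 lung
burden is published only graphically; where a value is needed the
back-calculated 2.74 mg (from 2.31 mg at 13 weeks and the 226-day slow
phase) is used and flagged as derived.

At the study's sampling design (5 animals per timepoint, 30 % inter-animal
CV), individual slow-phase fits are noisy enough that some draws give
negative clearance constants; across replicated simulations the median
clearance constant (converted to a half-time) recovers both generating
half-times within 15 %. A single simulated study can scatter much more
widely — as the real study's authors also caution for their two-timepoint
PS estimate.

Lung overload is flagged above 1 mg poorly soluble particles per gram lung,
with a strict inequality at the boundary (exactly 1.0 mg/g is not flagged).
External dosimetry-model predictions (6.8 %/6.9 % deposition) are stored as
comparison constants in `study_reference()` and never recomputed.

## Problem sizes and numerical choices

* Recovery tests use 192 × 192 × 48-voxel stacks (23 × 23 × 14.4 µm) with 50
  agglomerates at minimum 3 µm separation and SNR ≫ 10 — large enough that
  counts, sizes and PSF inflation behave as in full-field stacks, small
  enough for routine runs.
* Gaussian kernels are truncated at 4σ and sum-normalised, so integrated
  signal is conserved away from the stack faces (zero padding at the
  boundary).
* The classifier backend trains a 50-tree random forest on a balanced sample
  of ≤ 5000 labelled voxels per class; at high SNR it agrees with Otsu on
  object counts.
* Degenerate inputs are rejected with messages: all mass on one impactor
  stage, GSD ≤ 1, rank-deficient calibrations, non-positive burdens, zero
  scanned volume. An all-zero stack segments to an empty labelling (not an
  error).
* Internal units are µm, ng and day; conversions to mL, mg and µg happen at
  interfaces only.

## Known limitations

* The confocal route is semi-quantitative by construction: it assumes even
  particle deposition across the organ, a uniform packing density for all
  agglomerates, and scanned volumes that are a tiny fraction of the organ.
* The volume-calibration constant depends on the segmentation backend and
  acquisition parameters; it must be re-measured when either changes.
* The pyrolysis module does not model matrix interference (which defeated
  liver quantification in practice) or SPE cleanup.
* The clearance model is empirical first-order decay per interval; no
  mucociliary/alveolar compartment ODEs and no PBPK.
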