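---
title: "Focus-stacking reconstruction for single-event proton radiography: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Focus-stacking reconstruction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pradstack)
```

## The problem

Single-event proton radiography (pRad) measures each proton individually on
tracker planes before and after the object: entry/exit position, direction,
and residual energy. The energy loss gives the proton's water-equivalent path
length (WEPL), and binning many protons into pixels yields a projection of
the object's water-equivalent thickness (WET). The spatial resolution of such
radiographs is limited by multiple Coulomb scattering (MCS) inside the
object: the proton's lateral position is only known exactly at the trackers,
and must be interpolated in between.

Distance-driven binning (DDB) forms an image by depositing each proton at its
*estimated* lateral position at a chosen depth \(u\) inside the object. The
resolution of a feature is best when the binning depth coincides with the
feature's depth; away from it, the unaccounted scattering displacement
between the two depths blurs the feature. A stack of DDB images reconstructed
at many depths therefore contains, for every feature, a plane of best focus.

Focus stacking (FS) collapses such a stack into a single image: for each
pixel \((i,j)\), choose the plane \(n\) where a local sharpness measure — the
absolute value of the Laplacian-convolved image,
\(|\Delta f^n_{i,j}|\) — is maximal, and copy that plane's pixel value:

\[
f^{fs}_{i,j} = \arg\max_{f^n_{i,j}} \left(|\Delta f^n_{i,j}|\right),
\qquad n \in \{1,\dots,N\}.
\]

The selected plane index itself is a per-pixel estimate of the radiological
depth of the local feature, so the same machinery yields a focal-depth map
and, from it, feature depth estimates.

## Pipeline

1. **Simulation** (`transport()`): list-mode phase space for a phantom,
   generated by a condensed-history Monte Carlo model (below), or loaded from
   an external scorer (`read_phase_space()`).
2. **Filtering** (`filter_events()`): field-wide 3σ cut on the relative
   scattering angle; a per-pixel 3σ WEPL cut follows at binning time.
3. **Path estimation** (`fit_spline()`): per-event cubic Hermite spline
   between the trackers, endpoint positions and slopes from the
   measurements.
4. **DDB stack** (`reconstruct_stack()`): WET images at every 1 mm of depth,
   0.5 mm pixels by default.
5. **Focus stacking** (`focus_stack()`): 5×5 Gaussian pre-blur, 5×5
   Laplacian, per-pixel Savitzky–Golay smoothing of the sharpness-vs-depth
   profile, argmax selection, value lookup in the *raw* stack.
6. **Analysis** (`cube_mtf()`, `roi_noise()`, `roi_depth_estimate()`):
   slanted-edge MTF10%, ROI noise, and ROI depth estimates.

## The transport model

The simulator replaces a general-purpose Monte Carlo engine with the three
mechanisms that drive pRad image formation, at desk scale:

* **Energy loss**: the Bragg–Kleeman range–energy relation
  \(R(E) = \alpha E^p\) with \(\alpha = 0.022\) mm·MeV\(^{-p}\),
  \(p = 1.77\). Transport tracks the *residual range*: crossing \(ds_w\) mm
  of water-equivalent material decrements it by exactly \(ds_w\), which makes
  the WEPL bookkeeping exact (the WEPL of a deterministic ray equals the RSP
  line integral to machine precision) and needs energy only for the
  scattering power and the straggling conversion.
* **Energy straggling**: Gaussian with the Bohr variance rate
  0.0087 MeV²/mm of water, scaled by the local relative stopping power
  (RSP). Straggling is applied in the range domain through
  \(dR/dE = 1/S(E)\), so early-path energy fluctuations correctly propagate
  into larger WEPL fluctuations.
* **Scattering**: per-step Gaussian direction kicks with the Highland sigma
  \(\theta_0 = \frac{13.6\,\mathrm{MeV}}{\beta c p}\sqrt{x/X_0}
  \,(1 + 0.038\ln(x/X_0))\), \(X_0 = 360.8\) mm of water. The logarithmic
  term is evaluated on the *cumulative* water-equivalent depth (floored at
  zero), a standard choice for condensed-history stepping; the test suite
  checks the resulting exit-angle spread against an independent Fermi–Eyges
  quadrature of the same differential scattering power.

Steps are 1 mm along the beam axis by default, with the RSP sampled at the
step midpoint. Voxelized phantoms use nearest-voxel lookup; the cube phantom
is also available in exact solid geometry (see below). Nuclear interactions
are not modelled; instead an explicit outlier channel
(`outlier_fraction`, `outlier_offset`) perturbs a configurable fraction of
WEPLs by a large offset so that the 3σ data filters are exercised the way
nuclear-event contamination exercises them in measured data.

### What the generator emulates — and what it does not

The default conditions are the reference acquisition: a 20×20×20 cm³ water
tank with five 1 cm bone cubes (RSP 1.27) whose proximal faces sit at
radiological depths 10/50/100/150/190 mm, staggered laterally by 20 mm and
tilted 2.5° about the beam axis; 200 MeV protons in a 10×10 cm² pencil-beam
scanning field with 3 mm Gaussian spots, 3 mm spacing and 2 mrad divergence;
ideal scorers on the tank faces.

The model reproduces the *mechanisms* the FS method exploits — depth-dependent
blur from MCS, WEPL noise from straggling, spot-structured fluence — but not
every Geant4 ingredient: there are no single-scattering (Molière) tails, no
nuclear interactions, no delta rays. Two consequences matter when comparing
with published full-physics numbers. First, per-proton WEPL noise from pure
Bohr straggling (≈2.3 mm for 200 MeV through 20 cm of water) is smaller than
what a full physics list produces once nuclear events inside the 3σ window
are included, so absolute image-noise values come out lower while the
*relative* FS-over-DDB noise amplification is preserved. Second, without
scattering tails the path estimate is more accurate than in full physics,
particularly close to the trackers, so absolute resolution values come out
better (at shallow and deep cubes the measured edge width approaches the
0.5 mm pixel limit), and the sharpness-versus-depth profile of a shallow
feature is flatter, which weakens depth discrimination near the entrance
face. Passing tests therefore demonstrate the method's behaviour under
Gaussian transport, not equality with full-physics simulation.

## Design choices

* **Path parameterization.** The spline is parameterized in geometric depth;
  for the water-dominated phantom (RSP ≈ 1) geometric and radiological depth
  coincide, and geometric depth requires no prior knowledge of the object.
  Tangent scale factors \(\Lambda_0, \Lambda_1\) of the optimized
  cubic-spline family are exposed (`lambda` arguments, `[path]` config
  section) with the plain Hermite default \(\Lambda = 1\). Note that scaled
  tangents (\(\Lambda \ne 1\)) deliberately bend even collinear events; only
  \(\Lambda = 1\) reproduces straight lines.
* **3σ filters.** The angular cut is field-wide (DDB re-bins per plane, so a
  per-plane per-pixel angular cut would be ambiguous); the WEPL cut is per
  pixel at binning time, single-pass: mean/sd → cut at 3σ → recompute the
  mean. Zero-variance pixels keep all events. Single-pass rather than
  iterated keeps the estimator deterministic and fast.
* **Binning.** Pixels are half-open intervals; an event exactly on a
  boundary goes to the higher-index pixel. Pixels with no accepted event
  carry an `NA` validity mask rather than a zero.
* **Kernels.** The Gaussian pre-blur uses a 5×5 kernel with σ = 1 px
  (configurable); invalid pixels are excluded by mask-weighted
  normalization. The Laplacian is a fixed 5×5 zero-sum kernel
  (centre −16, Laplacian-of-Gaussian-like ring), asserted zero-sum at
  construction so constant regions map to zero. Both convolutions use
  edge-inclusive reflect padding.
* **Depth smoothing.** The sharpness profile of each pixel is smoothed along
  depth with a Savitzky–Golay filter, default 11 planes / order 3, clipped
  at zero; window 1 disables it. Ties in the argmax break toward the
  shallowest plane, making the output deterministic.
* **Value lookup.** The FS image samples the *raw* (unblurred) stack at the
  selected plane, so focus stacking cannot bias the WET scale; the blurred
  stack only drives the selection.
* **Solid-geometry cube phantom.** `build_cube_phantom()` voxelizes the tank
  (0.5 mm default), but `transport()` also evaluates the cube phantom in
  exact geometry. At 0.5 mm voxels, a 2.5°-tilted edge becomes a staircase
  with an ~11 mm tread period; over the few-mm extent of a slanted-edge
  analysis region the edge is then locally axis-aligned and the sub-pixel
  phase diversity that the oversampled ESF method relies on disappears.
  Solid geometry preserves the tilt exactly, as a solid-geometry Monte
  Carlo setup would.
* **MTF.** The oversampled ESF (0.1 mm bins) is fitted with an error
  function; the line spread function is then Gaussian and the MTF follows in
  closed form, \( \mathrm{MTF}(f) = e^{-2\pi^2\sigma^2 f^2}\),
  \( \mathrm{MTF}_{10\%} = \sqrt{\ln 10/(2\pi^2)}/\sigma \). A discrete-FFT
  evaluation of the same fitted LSF is available as a cross-check
  (`method = "fft"`). The erf fit can legitimately resolve beyond the pixel
  Nyquist frequency (1 lp/mm at 0.5 mm pixels), so the Nyquist cap is off by
  default and available as an option. Edge polarity is normalized (distance
  measured along the inward normal) before the four cube edges are averaged.
* **Depth estimation.** Feature regions are user-supplied pixel rectangles
  (`cube_bottom_edge_roi()` builds the standard 20×4 px bottom-edge region);
  the median focal depth is the headline estimator, with the IQR and the
  full per-pixel distribution reported alongside.

## Numerical details and degenerate inputs

* The erf fit starts from a moment-based width of the numerical LSF and
  retries from a small ladder of starting widths before giving up, which
  makes it robust to very sharp (sub-pixel) and very blurred edges alike.
* Sharpness values at invalid pixels are treated as zero during depth
  smoothing and restored to invalid afterwards; a pixel invalid in the
  selected plane falls back to its best valid plane, and a pixel invalid
  everywhere is invalid in the output.
* Protons stopping inside the phantom (residual energy below 1 MeV) are
  excluded and counted; records with `e_out > e_in` or non-finite fields are
  rejected at I/O time with a reported count.
* All randomness is generated by a self-contained xoshiro256++ stream seeded
  from a single integer, so a given seed reproduces the phase space
  byte-for-byte on any platform.

## Problem sizes

The reference acquisition uses 10⁷ primaries (≈250 protons per 0.5 mm pixel
over the 10×10 cm² field) with 201 stack planes; reduced-statistics
acquisitions at 5×10⁶ and 10⁶ primaries probe the noise scaling, and
replicate depth-recovery runs use 2×10⁶ primaries per seed. A 10⁷-primary
simulation plus full reconstruction runs in a few minutes on one CPU.

## Known limitations

* Gaussian-only MCS and straggling: absolute resolution and noise are
  optimistic relative to full-physics simulation (see above); the shallow
  cube's focal depth is the least constrained.
* The optimized Λ(E, WET) parameterization of the cubic-spline path is not
  built in; Λ is a plain configuration constant.
* The maximum-likelihood radiography baseline and patient-CT acquisitions
  are out of scope; comparisons are against DDB only.
* Depth estimation requires a WET gradient: homogeneous regions yield
  focal-depth noise spanning a large fraction of the tank (this is a
  property of the method, and the tests assert it).
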