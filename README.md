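# pradstack

Focus-stacking reconstruction for single-event proton radiography (pRad).

## The problem

In single-event proton radiography every proton is tracked individually:
position and direction on a front and a rear tracker, plus the residual
energy behind the object. The energy loss gives each proton's
water-equivalent path length (WEPL), and binning protons into pixels yields a
projection of the object's water-equivalent thickness (WET). Spatial
resolution is limited by multiple Coulomb scattering: the proton's lateral
position inside the object must be interpolated between the trackers.

Distance-driven binning (DDB) deposits each proton at its estimated lateral
position at a chosen depth *u*; a feature is sharpest when *u* matches the
feature's depth, so no single DDB image is optimal for features at different
depths. **Focus stacking (FS)** reconstructs a whole stack of DDB images (one
per mm of depth) and then, per pixel (*i*, *j*), keeps the value from the
plane with maximal sharpness, measured as the absolute value of the
Laplacian-convolved (Gaussian pre-blurred) image:

    f_fs[i,j] = argmax over n of | Laplacian( f_n )[i,j] |

The winning plane index is simultaneously an estimate of the radiological
depth of the local feature, so one acquisition yields a super-resolved WET
radiograph *and* a focal-depth map for 3D feature localization.

The package provides the full chain: a condensed-history Monte Carlo
simulator (Bragg–Kleeman energy loss, Highland scattering, Bohr straggling)
producing list-mode phase space for voxelized or solid-geometry RSP phantoms;
cubic-spline path estimation; DDB stack reconstruction with 3σ data filters;
focus stacking with Savitzky–Golay depth smoothing; slanted-edge MTF10% and
ROI-noise image quality analysis; and feature depth estimation. See the
methods vignette (`vignettes/focus-stacking-methods.Rmd`) for the model and
design details.

## Worked example

A reduced-statistics acquisition of the reference phantom — a 20 cm water
tank with five 1 cm bone cubes (RSP 1.27, tilted 2.5°) at radiological depths
10–190 mm, imaged with 10⁶ protons of 200 MeV in a 10×10 cm² scanned field:

```r
library(pradstack)
phantom <- cube_phantom()
phantom
#> cube_phantom: 200 x 200 x 200 mm water tank, 5 cubes (RSP 1.27, 2.5 deg tilt)
#>    u0  tc  vc
#> 1  10 -40 -40
#> 2  50 -20 -20
#> 3 100   0   0
#> 4 150  20  20
#> 5 190  40  40

beam <- beam_config(n_primaries = 1e6, rng_seed = 7)
records <- transport(phantom, beam, transport_config())
records <- filter_events(records)          # field-wide 3-sigma angular cut

stack <- reconstruct_stack(records, depth_step = 1)
stack
#> ddb_stack: 201 planes over [0, 200] mm, 200 x 200 pixels (0.5 mm)

fs <- focus_stack(stack)                   # collapse the stack per Eq. above
round(roi_noise(fs$fs_image, stack$grid, c(17.5, 42.5, -42.5, -17.5)), 2)
#> [1] 0.93

cube_mtf(fs$fs_image, stack$grid, phantom, 5)   # deepest cube, 4-edge average
#> mtf_curve: edge sigma 0.236 mm, MTF10% = 1.450 lp/mm (analytic)

roi_depth_estimate(fs, cube_bottom_edge_roi(stack$grid, phantom, 5))
#> depth_estimate: median 178.5 mm (IQR 60.2 mm, 80 pixels)
```

Reading the numbers: the homogeneous-region WET noise of the FS image is
0.93 mm at this (low) fluence; the deepest cube's four-edge slanted-edge
analysis gives an edge width of 0.236 mm, i.e. an MTF 10% fall-off at
1.45 lp/mm — beyond the 1 lp/mm pixel Nyquist, which the error-function fit
can legitimately resolve; and the median focal depth of the 80-pixel
bottom-edge region estimates the cube (proximal face at 190 mm) at 178.5 mm,
with the IQR reflecting the fluence-limited depth discrimination. At the
reference fluence of 10⁷ primaries the noise drops to ≈0.3 mm, the deepest
cube resolves at ≈2 lp/mm and its depth estimate tightens to within a few mm
(these are the quantities the acceptance script recomputes).

A thin command-line interface wraps the same functions
(`inst/cli/pradstack`): `simulate`, `reconstruct`, `stack`, `depth`, `qa`,
and `run` for the end-to-end pipeline driven by a YAML configuration
(`run_pipeline()` / `default_run_config()`).

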