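Package: pradstack
Title: Focus-Stacking Reconstruction for Single-Event Proton Radiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs high-resolution water-equivalent-thickness (WET)
    radiographs from list-mode single-event proton data. Protons are binned at
    a series of depths inside the object along their estimated cubic-spline
    trajectories (distance-driven binning), and the resulting image stack is
    collapsed into a single super-resolved radiograph by selecting, per pixel,
    the depth plane of maximal absolute Laplacian sharpness (focus stacking).
    The per-pixel focal depth doubles as an estimate of the radiological depth
    of image features. Includes a condensed-history Monte Carlo transport
    simulator (Highland multiple Coulomb scattering, Bragg-Kleeman range-energy
    relation, Bohr energy straggling) for generating list-mode phase-space data
    from voxelized or solid-geometry relative-stopping-power phantoms, plus
    slanted-edge MTF and ROI-noise image-quality analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    minpack.lm,
    signal,
    stats,
    utils,
    yaml,
    jsonlite,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    arrow
Config/testthat/edition: 3
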