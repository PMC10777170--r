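#' Pencil-beam scanning field configuration
#'
#' Defaults reproduce the cube-phantom acquisition: 200 MeV protons, 3 mm
#' Gaussian spot sigma, 2 mrad Gaussian angular divergence, 3 mm spot spacing,
#' 10 x 10 cm^2 field.
#'
#' @param kinetic_energy initial kinetic energy, MeV
#' @param spot_sigma lateral Gaussian spot standard deviation, mm
#' @param divergence_sigma Gaussian angular divergence, rad
#' @param spot_spacing spacing between adjacent spot centres, mm
#' @param field_size field extent (t, v), mm
#' @param n_primaries number of primary protons
#' @param rng_seed integer seed for the transport RNG
#' @return a `beam_config` object
#' @export
beam_config <- function(kinetic_energy = 200, spot_sigma = 3,
                        divergence_sigma = 0.002, spot_spacing = 3,
                        field_size = c(100, 100), n_primaries = 1e5,
                        rng_seed = 1) {
  stopifnot(kinetic_energy > 0, spot_sigma >= 0, divergence_sigma >= 0,
            spot_spacing > 0, length(field_size) == 2, all(field_size > 0),
            n_primaries >= 1)
  structure(list(kinetic_energy = kinetic_energy, spot_sigma = spot_sigma,
                 divergence_sigma = divergence_sigma,
                 spot_spacing = spot_spacing,
                 field_size = as.numeric(field_size),
                 n_primaries = as.integer(n_primaries),
                 rng_seed = as.integer(rng_seed)),
            class = "beam_config")
}

#' Condensed-history transport configuration
#'
#' @param step_length geometric step length along the beam axis, mm
#' @param straggling_enabled sample Gaussian (Bohr) energy straggling
#' @param scattering_enabled sample Highland multiple Coulomb scattering
#' @param outlier_fraction fraction of events given an anomalous WEPL (an
#'   explicit stand-in for nuclear-event contamination, used to exercise the
#'   3-sigma data filters)
#' @param outlier_offset WEPL offset applied to outlier events, mm
#' @param bohr_rate energy-straggling variance rate in water, MeV^2/mm
#' @param rng_seed optional integer seed overriding the beam seed
#' @return a `transport_config` object
#' @export
transport_config <- function(step_length = 1, straggling_enabled = TRUE,
                             scattering_enabled = TRUE, outlier_fraction = 0,
                             outlier_offset = 50,
                             bohr_rate = .const$bohr, rng_seed = NULL) {
  stopifnot(step_length > 0, outlier_fraction >= 0, outlier_fraction < 1,
            outlier_offset > 0, bohr_rate >= 0)
  structure(list(step_length = step_length,
                 straggling_enabled = isTRUE(straggling_enabled),
                 scattering_enabled = isTRUE(scattering_enabled),
                 outlier_fraction = outlier_fraction,
                 outlier_offset = outlier_offset,
                 bohr_rate = bohr_rate,
                 rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed)),
            class = "transport_config")
}

phantom_to_cpp <- function(phantom) {
  if (inherits(phantom, "rsp_volume")) {
    list(mode = "voxel", grid = as.numeric(phantom$rsp_grid),
         dims = as.integer(dim(phantom$rsp_grid)),
         spacing = phantom$spacing, origin = phantom$origin)
  } else if (inherits(phantom, "cube_phantom")) {
    list(mode = "cubes", size = phantom$size, cube_edge = phantom$cube_edge,
         cube_rsp = phantom$cube_rsp, tilt_deg = phantom$tilt_deg,
         u0 = phantom$cubes$u0, tc = phantom$cubes$tc, vc = phantom$cubes$vc)
  } else {
    stop("phantom must be an rsp_volume or a cube_phantom")
  }
}

#' Simulate a list-mode proton radiography acquisition
#'
#' Condensed-history Monte Carlo transport through a voxelized RSP volume
#' (nearest-voxel lookup at the step midpoint) or an exact-geometry cube
#' phantom. Per geometric step the proton loses
#' \eqn{S(E)\,\mathrm{RSP}\,\Delta s} of energy plus a Gaussian straggling
#' term (Bohr variance rate scaled by the local RSP), and its direction
#' receives Gaussian kicks with the per-step Highland sigma (scattering power
#' scaled by the local RSP, logarithmic correction evaluated on the cumulative
#' water-equivalent depth). Ideal scorers record position and direction on the
#' front and rear tank faces; the WEPL is derived from the energy pair via
#' [compute_wepl()]. Protons stopping inside the phantom are excluded and
#' counted.
#'
#' @param phantom a [cube_phantom()] or [rsp_volume()]
#' @param beam a [beam_config()]
#' @param cfg a [transport_config()]
#' @return a `data.table` of particle records with columns `t0, v0, st0, sv0,
#'   t1, v1, st1, sv1, e_in, e_out, wepl` (mm, slopes dt/du and dv/du, MeV)
#'   and attributes `u_front`, `u_rear`, `n_stopped`, `n_outliers`
#' @export
transport <- function(phantom, beam = beam_config(), cfg = transport_config()) {
  stopifnot(inherits(beam, "beam_config"), inherits(cfg, "transport_config"))
  seed <- cfg$rng_seed %||% beam$rng_seed
  res <- cpp_transport(
    phantom_to_cpp(phantom), beam$kinetic_energy, beam$spot_sigma,
    beam$divergence_sigma, beam$spot_spacing, beam$field_size[1],
    beam$field_size[2], beam$n_primaries, cfg$step_length,
    cfg$scattering_enabled, cfg$straggling_enabled, cfg$outlier_fraction,
    cfg$outlier_offset, cfg$bohr_rate, .const$e_cut, as.double(seed))
  rec <- data.table::setDT(res[1:11])
  data.table::setattr(rec, "u_front", res$u_front)
  data.table::setattr(rec, "u_rear", res$u_rear)
  data.table::setattr(rec, "n_stopped", res$n_stopped)
  data.table::setattr(rec, "n_outliers", res$n_outliers)
  rec
}
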