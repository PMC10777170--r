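# End-to-end pipeline: simulate -> filter -> DDB stack -> focus stack ->
# depth map -> QA report, with per-stage file caching.

#' Default run configuration
#'
#' The cube-phantom acquisition conditions: 200 MeV, 10 x 10 cm^2 scanned
#' field (3 mm spots and spacing, 2 mrad divergence), 0.5 mm pixels, 1 mm
#' depth step, 3-sigma filters, 5x5 kernels and an 11-plane cubic
#' Savitzky-Golay depth smoother.
#'
#' @param n_primaries number of primaries
#' @param seed RNG seed
#' @return a `run_config`
#' @export
default_run_config <- function(n_primaries = 1e5, seed = 1) {
  structure(list(
    run = list(phantom = "cubes", seed = as.integer(seed)),
    beam = list(kinetic_energy = 200, spot_sigma = 3, divergence_sigma = 0.002,
                spot_spacing = 3, field_size = c(100, 100),
                n_primaries = as.integer(n_primaries), rng_seed = as.integer(seed)),
    transport = list(step_length = 1, straggling_enabled = TRUE,
                     scattering_enabled = TRUE, outlier_fraction = 0,
                     outlier_offset = 50),
    path = list(lambda0 = 1, lambda1 = 1),
    reconstruction = list(pixel_size = 0.5, extent = c(100, 100),
                          center = c(0, 0), depth_step = 1, sigma_mult = 3),
    fs = list(sigma = 1, sg_window = 11, sg_polyorder = 3),
    qa = list(noise_roi = c(17.5, 42.5, -42.5, -17.5))
  ), class = "run_config")
}

cfg_get <- function(cfg, sec, key, default) {
  x <- cfg[[sec]][[key]]
  if (is.null(x)) default else x
}

#' Run the full focus-stacking pipeline
#'
#' Simulates the acquisition, applies the angular 3-sigma filter,
#' reconstructs the DDB stack, collapses it with focus stacking, and writes
#' the artifacts: `ps.csv` (phase space), `stack.mha` (DDB stack volume),
#' `fs.mha` (focus-stacked image), `depth.mha` (focal-depth map) and
#' `qa.json` (noise, resolution and provenance report). Existing stage
#' outputs are reused when `resume = TRUE`.
#'
#' @param cfg a `run_config` (see [default_run_config()] / [read_run_config()])
#' @param out_dir output directory, created if needed
#' @param resume reuse stage outputs already on disk
#' @param quiet suppress progress messages
#' @return invisibly, a list with the in-memory results (`records`, `stack`,
#'   `fs`, `qa`)
#' @export
run_pipeline <- function(cfg, out_dir, resume = TRUE, quiet = FALSE) {
  validate_run_config(unclass(cfg))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  seed <- cfg_get(cfg, "run", "seed", 1L)

  phspec <- cfg_get(cfg, "run", "phantom", "cubes")
  phantom <- if (identical(phspec, "cubes")) {
    cube_phantom()
  } else {
    m <- read_mhd(phspec)
    rsp_volume(m$data, m$spacing, m$origin)
  }

  cfg_file <- file.path(out_dir, "run_config.yaml")
  write_run_config(unclass(cfg), cfg_file)
  cfg_hash <- unname(tools::md5sum(cfg_file))

  ps_file <- file.path(out_dir, "ps.csv")
  if (resume && file.exists(ps_file)) {
    say("simulate: reusing ", ps_file)
    records <- read_phase_space(ps_file)
  } else {
    say("simulate: ", cfg$beam$n_primaries, " primaries")
    beam <- do.call(beam_config, modifyList(cfg$beam, list(rng_seed = seed)))
    tr <- do.call(transport_config, cfg$transport)
    records <- transport(phantom, beam, tr)
    write_phase_space(records, ps_file)
  }

  sm <- cfg_get(cfg, "reconstruction", "sigma_mult", 3)
  records <- filter_events(records, sm)

  grid <- image_grid(cfg_get(cfg, "reconstruction", "pixel_size", 0.5),
                     cfg_get(cfg, "reconstruction", "extent", c(100, 100)),
                     cfg_get(cfg, "reconstruction", "center", c(0, 0)))
  lambda <- c(cfg_get(cfg, "path", "lambda0", 1),
              cfg_get(cfg, "path", "lambda1", 1))
  say("reconstruct: DDB stack")
  stack <- reconstruct_stack(records,
                             depth_step = cfg_get(cfg, "reconstruction", "depth_step", 1),
                             grid = grid, lambda = lambda, sigma_mult = sm)
  img <- stack$images
  img[is.na(img)] <- -1
  write_mhd(img, file.path(out_dir, "stack.mha"),
            spacing = c(grid$pixel_size, grid$pixel_size,
                        diff(stack$depths[1:2])),
            origin = c(grid$tmin, grid$vmin, stack$depths[1]))

  say("focus stack")
  fs <- focus_stack(stack,
                    sigma = cfg_get(cfg, "fs", "sigma", 1),
                    sg_window = cfg_get(cfg, "fs", "sg_window", 11),
                    sg_polyorder = cfg_get(cfg, "fs", "sg_polyorder", 3))
  fsi <- fs$fs_image; fsi[is.na(fsi)] <- -1
  dmap <- fs$focal_depth_map; dmap[is.na(dmap)] <- -1
  write_mhd(fsi, file.path(out_dir, "fs.mha"),
            spacing = grid$pixel_size, origin = c(grid$tmin, grid$vmin))
  write_mhd(dmap, file.path(out_dir, "depth.mha"),
            spacing = grid$pixel_size, origin = c(grid$tmin, grid$vmin))

  say("qa report")
  qa <- list(
    provenance = list(config_md5 = cfg_hash, seed = seed,
                      package_version = as.character(utils::packageVersion("pradstack"))),
    n_records = nrow(records),
    n_stopped = attr(records, "n_stopped"),
    n_angle_cut = attr(records, "n_angle_cut"),
    n_planes = length(stack$depths)
  )
  roi <- cfg_get(cfg, "qa", "noise_roi", NULL)
  if (!is.null(roi)) {
    qa$fs_noise <- tryCatch(roi_noise(fs$fs_image, grid, roi), error = function(e) NA)
    mid <- which.min(abs(stack$depths - mean(range(stack$depths))))
    qa$ddb_central_noise <-
      tryCatch(roi_noise(stack$images[, , mid], grid, roi), error = function(e) NA)
  }
  if (identical(phspec, "cubes")) {
    qa$cubes <- lapply(seq_len(nrow(phantom$cubes)), function(k) {
      mtf <- tryCatch(cube_mtf(fs$fs_image, grid, phantom, k,
                               cap_nyquist = cfg_get(cfg, "qa", "cap_nyquist", FALSE)),
                      error = function(e) NULL)
      est <- tryCatch(roi_depth_estimate(fs, cube_bottom_edge_roi(grid, phantom, k)),
                      error = function(e) NULL)
      list(depth = phantom$cubes$u0[k],
           mtf10_fs = if (is.null(mtf)) NA else mtf$mtf10,
           focal_depth_median = if (is.null(est)) NA else est$median_depth)
    })
  }
  jsonlite::write_json(qa, file.path(out_dir, "qa.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(records = records, stack = stack, fs = fs, qa = qa,
                 grid = grid, phantom = phantom))
}
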