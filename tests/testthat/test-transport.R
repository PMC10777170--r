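water_box <- function(thick = 200, spacing = 5) {
  n <- round(thick / spacing)
  rsp_volume(array(1, c(n, 40, 40)), c(spacing, 5, 5), c(0, -100, -100))
}

test_that("with all stochastic terms off transport is an exact ray tracer", {
  ph <- cube_phantom()
  beam <- beam_config(n_primaries = 500, spot_sigma = 2,
                      divergence_sigma = 0.002, rng_seed = 5)
  cfg <- transport_config(straggling_enabled = FALSE, scattering_enabled = FALSE)
  rec <- transport(ph, beam, cfg)
  # straight lines between the trackers
  expect_equal(rec$t1, rec$t0 + rec$st0 * 200, tolerance = 1e-9)
  expect_equal(rec$v1, rec$v0 + rec$sv0 * 200, tolerance = 1e-9)
  expect_equal(rec$st1, rec$st0)
  expect_equal(rec$sv1, rec$sv0)
  # perpendicular rays in water-only regions: WEPL exactly 200 mm
  beam0 <- beam_config(n_primaries = 100, spot_sigma = 0,
                       divergence_sigma = 0, field_size = c(60, 60),
                       spot_spacing = 20, rng_seed = 5)
  rec0 <- transport(ph, beam0, cfg)
  water <- abs(rec0$t0 - rec0$v0) > 1  # off the staggered-cube diagonal
  expect_true(all(abs(rec0$wepl[water] - 200) < 1e-9))
})

test_that("a deterministic axial ray through a cube picks up exactly 2.7 mm WET", {
  ph <- cube_phantom()
  # single spot aimed at the central cube (0, 0); no spot size, no divergence
  beam <- beam_config(n_primaries = 50, spot_sigma = 0, divergence_sigma = 0,
                      field_size = c(1, 1), spot_spacing = 3, rng_seed = 1)
  cfg <- transport_config(straggling_enabled = FALSE, scattering_enabled = FALSE)
  rec <- transport(ph, beam, cfg)
  expect_equal(nrow(rec), 50)
  expect_true(all(abs(rec$wepl - 202.7) < 1e-9))
  expect_true(all(compute_wepl(rec$e_in, rec$e_out) - rec$wepl < 1e-9))
})

test_that("identical seeds give identical phase space; different seeds differ", {
  ph <- cube_phantom()
  beam <- beam_config(n_primaries = 2000, rng_seed = 9)
  a <- transport(ph, beam, transport_config())
  b <- transport(ph, beam, transport_config())
  expect_identical(as.data.frame(a), as.data.frame(b))
  beam2 <- beam_config(n_primaries = 2000, rng_seed = 10)
  c <- transport(ph, beam2, transport_config())
  expect_false(identical(a$t1, c$t1))
})

test_that("exit-angle spread matches the Fermi-Eyges quadrature prediction", {
  vol <- water_box(200)
  beam <- beam_config(n_primaries = 1e5, spot_sigma = 0, divergence_sigma = 0,
                      field_size = c(40, 40), rng_seed = 3)
  rec <- transport(vol, beam, transport_config(straggling_enabled = FALSE))
  # independent oracle: integrate the scattering power T(x) of the same
  # Highland model over depth, with E(x) from the CSDA range relation
  Tfun <- function(x) {
    E <- energy_from_range(residual_range(200) - x)
    corr <- pmax(1 + 0.038 * log(x / 360.8), 0)
    (13.6 / ((E^2 + 2 * E * 938.272) / (E + 938.272)))^2 / 360.8 * corr^2
  }
  pred <- sqrt(stats::integrate(Tfun, 1e-6, 200)$value)
  expect_equal(sd(rec$st1 - rec$st0), pred, tolerance = 0.1)
  expect_equal(sd(rec$sv1 - rec$sv0), pred, tolerance = 0.1)
})

test_that("exit-angle variance grows with phantom thickness", {
  sds <- vapply(c(50, 100, 200), function(th) {
    rec <- transport(water_box(th),
                     beam_config(n_primaries = 2e4, spot_sigma = 0,
                                 divergence_sigma = 0, field_size = c(40, 40),
                                 rng_seed = 4),
                     transport_config(straggling_enabled = FALSE))
    sd(rec$st1 - rec$st0)
  }, 0)
  expect_true(all(diff(sds) > 0))
})

test_that("with straggling off the WEPL equals the RSP line integral", {
  # scattering on: the WEPL must follow the (longer) scattered path through
  # water, staying within 1% of the slab thickness
  rec <- transport(water_box(200),
                   beam_config(n_primaries = 5e3, rng_seed = 8),
                   transport_config(straggling_enabled = FALSE))
  expect_true(all(rec$wepl >= 200 - 1e-9))
  expect_true(all(rec$wepl < 202))
  expect_lt(median(rec$wepl) - 200, 0.2)
})

test_that("protons stopping inside the phantom are excluded and counted", {
  # 100 MeV protons have ~77 mm range: none survive 200 mm of water
  rec <- transport(water_box(200),
                   beam_config(kinetic_energy = 100, n_primaries = 200,
                               rng_seed = 2),
                   transport_config())
  expect_equal(nrow(rec), 0)
  expect_equal(attr(rec, "n_stopped"), 200)
})

test_that("the outlier channel perturbs the configured fraction of WEPLs", {
  rec <- transport(water_box(200),
                   beam_config(n_primaries = 2e4, rng_seed = 6),
                   transport_config(outlier_fraction = 0.05,
                                    outlier_offset = 50))
  f <- attr(rec, "n_outliers") / nrow(rec)
  expect_gt(f, 0.04); expect_lt(f, 0.06)
  expect_equal(sum(rec$wepl > 225), attr(rec, "n_outliers"))
  # records stay internally consistent
  expect_equal(compute_wepl(rec$e_in, rec$e_out), rec$wepl, tolerance = 1e-6)
})
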