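test_that("point phantom places unit scatterers at the requested depths", {
  ph <- make_point_phantom()
  expect_equal(ph$scatterers$axial_m, c(2.5, 3, 3.5, 4, 4.5) * 1e-3)
  expect_true(all(ph$scatterers$lateral_m == 0))
  expect_true(all(ph$scatterers$amplitude == 1))
  expect_equal(nrow(make_point_phantom(3.5e-3)$scatterers), 1)
  expect_error(make_point_phantom(numeric(0)), "empty-phantom")
  expect_error(make_point_phantom(c(1e-3, -2e-3)), "geometry")
})

test_that("cyst phantom is anechoic, seeded, and warns when speckle is sparse", {
  cfg <- small_config()
  ph <- make_cyst_phantom(seed = 11, config = cfg)
  s <- ph$scatterers
  expect_true(all(s$lateral_m^2 + (s$axial_m - 3.5e-3)^2 >= (0.5e-3)^2))
  ph2 <- make_cyst_phantom(seed = 11, config = cfg)
  expect_identical(ph$scatterers, ph2$scatterers)
  ph3 <- make_cyst_phantom(seed = 12, config = cfg)
  expect_false(identical(ph$scatterers, ph3$scatterers))
  expect_warning(
    make_cyst_phantom(density_per_mm2 = 10, seed = 1, config = cfg),
    "resolution cell"
  )
  expect_error(make_cyst_phantom(diameter_m = 5e-3, config = cfg,
                                 axial_range = c(2e-3, 5e-3)),
               "geometry")
})

test_that("simulated RF is linear in scatterer amplitude and zero for empty phantoms", {
  cfg <- small_config()
  ph <- make_point_phantom(2.5e-3)
  rf1 <- simulate_rf(cfg, ph)
  ph2 <- ph
  ph2$scatterers$amplitude <- 2
  rf2 <- simulate_rf(cfg, ph2)
  for (l in c(1L, 24L, 48L)) {
    expect_equal(rf2$samples[[l]], 2 * rf1$samples[[l]], tolerance = 1e-12)
  }
  empty <- multiapod:::new_phantom(
    data.frame(axial_m = numeric(0), lateral_m = numeric(0),
               amplitude = numeric(0)),
    label = "empty"
  )
  rf0 <- simulate_rf(cfg, empty)
  expect_true(all(vapply(rf0$samples, function(m) all(m == 0),
                         logical(1))))
})

test_that("the focal echo arrives at the analytic round-trip time", {
  cfg <- array_config(n_elements = 16L, n_sub = 16L, n_scanlines = 16L)
  ex <- element_positions(cfg)
  l <- 8L
  ph <- make_point_phantom(cfg$tx_focus)
  ph$scatterers$lateral_m <- ex[l]  # directly above element l
  rf <- simulate_rf(cfg, ph)
  # element l: transmit focal delay + two-way path straight down
  d <- sqrt((ex - ex[l])^2 + cfg$tx_focus^2)
  tau_l <- (max(d) - d[l]) / cfg$c
  t_expect <- tau_l + 2 * cfg$tx_focus / cfg$c + rf$pulse_center_s
  env <- multiapod:::hilbert_envelope(rf$samples[[l]][, l, drop = FALSE])
  t_peak <- (which.max(env) - 1) / cfg$fs
  expect_lt(abs(t_peak - t_expect), 3 / cfg$fs)
})

test_that("an on-axis scatterer yields channel data symmetric about the aperture center", {
  ex <- seq(-7.5, 7.5) * 40e-6
  d <- sqrt(ex^2 + (3.5e-3)^2)
  tau <- (max(d) - d) / 1500
  pulse <- sin(2 * pi * 40e6 * seq(0, 5e-8, by = 2.5e-9))
  mat <- multiapod:::sim_scanline_cpp(0, 3.5e-3, 1, ex, tau, pulse,
                                      400e6, 1500, 4000L)
  ne <- length(ex)
  for (e in 1:(ne / 2)) {
    expect_equal(mat[, e], mat[, ne + 1 - e], tolerance = 1e-9)
  }
})

test_that("transmit focusing maximizes the summed echo at the focal depth", {
  # strongly focused aperture (f-number < 1) so defocus decoherence
  # dominates over the residual spreading mismatch
  cfg <- array_config(n_elements = 64L, n_sub = 64L, n_scanlines = 64L,
                      tx_focus = 2e-3)
  l <- 32L
  peak_of <- function(depth) {
    ph <- make_point_phantom(depth)
    # cancel the 1/(d_tx*d_rx) spreading so only focusing gain remains
    ph$scatterers$amplitude <- (depth / cfg$tx_focus)^2
    rf <- simulate_rf(cfg, ph)
    max(abs(rowSums(rf$samples[[l]])))
  }
  at_focus <- peak_of(cfg$tx_focus)
  expect_gt(at_focus, peak_of(cfg$tx_focus - 1e-3))
  expect_gt(at_focus, peak_of(cfg$tx_focus + 1e-3))
})

test_that("simulation is deterministic for a fixed phantom and config", {
  cfg <- small_config()
  ph <- suppressWarnings(
    make_cyst_phantom(diameter_m = 0.5e-3, density_per_mm2 = 50,
                      seed = 3, config = cfg,
                      axial_range = c(2e-3, 3e-3))
  )
  rf_a <- simulate_rf(cfg, ph)
  rf_b <- simulate_rf(cfg, ph)
  expect_identical(rf_a$samples, rf_b$samples)
})

test_that("phantoms round-trip through delimited text export", {
  ph <- make_point_phantom()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_phantom(ph, path)
  back <- utils::read.delim(path)
  expect_equal(back$axial_m, ph$scatterers$axial_m)
  expect_equal(back$amplitude, ph$scatterers$amplitude)
})
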