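# hand-built tiny channel-data object: 3 elements, 1 scanline
tiny_rf <- function(nt = 64, seed = 5) {
  set.seed(seed)
  cfg <- array_config(n_elements = 3L, n_sub = 3L, n_scanlines = 1L,
                      f0 = 5e6, fs = 40e6, pitch = 1e-4,
                      tx_focus = 2e-3)
  rf <- structure(
    list(samples = list(matrix(rnorm(nt * 3), nt, 3)),
         active_elements = list(1:3), t0 = 0, fs = cfg$fs,
         tx_ref_t = sqrt((1e-4)^2 + (2e-3)^2) / cfg$c,
         pulse_center_s = 1e-7,
         z_range = c(1e-3, 2.4e-3), config = cfg),
    class = "rf_channel_data"
  )
  list(cfg = cfg, rf = rf)
}

test_that("delay-and-sum matches the brute-force triple-loop reference", {
  t <- tiny_rf()
  prof <- make_rectangular(3)
  img <- das_beamform(t$rf, t$cfg, prof)
  ex <- element_positions(t$cfg)
  t_offset <- t$rf$tx_ref_t - t$cfg$tx_focus / t$cfg$c +
    t$rf$pulse_center_s
  ref <- das_oracle(t$rf$samples[[1]], ex, ex[1], prof$weights,
                    img$axial_axis, t$cfg$fs, t$cfg$c, t_offset)
  expect_equal(img$pixels[, 1], ref, tolerance = 1e-9)
  # with a tapered profile, output is the weight-linear channel sum
  w <- c(0.25, 1, 0.5)
  tap <- structure(list(weights = w, family = "rectangular",
                        param = NA_real_, N = 3L),
                   class = "apod_profile")
  img_w <- das_beamform(t$rf, t$cfg, tap)
  ref_w <- das_oracle(t$rf$samples[[1]], ex, ex[1], w, img$axial_axis,
                      t$cfg$fs, t$cfg$c, t_offset)
  expect_equal(img_w$pixels[, 1], ref_w, tolerance = 1e-9)
})

test_that("beamforming is linear in the RF data and zero for zero weights", {
  t <- tiny_rf()
  img <- das_beamform(t$rf, t$cfg, make_rectangular(3))
  rf2 <- t$rf
  rf2$samples[[1]] <- 3 * rf2$samples[[1]]
  expect_equal(das_beamform(rf2, t$cfg, make_rectangular(3))$pixels,
               3 * img$pixels, tolerance = 1e-12)
  zero <- structure(list(weights = rep(0, 3), family = "rectangular",
                         param = NA_real_, N = 3L),
                    class = "apod_profile")
  expect_true(all(das_beamform(t$rf, t$cfg, zero)$pixels == 0))
  expect_error(das_beamform(t$rf, t$cfg, make_rectangular(5)),
               "apodization-mapping")
})

test_that("a focal scatterer images at the focal depth and center lateral position", {
  cfg <- small_config()
  rf <- simulate_rf(cfg, make_point_phantom(cfg$tx_focus))
  img <- envelope_detect(das_beamform(rf, cfg, make_rectangular(16)))
  pk <- which(img$pixels == max(img$pixels), arr.ind = TRUE)
  # within the flat top of the round-trip pulse envelope
  expect_lt(abs(img$axial_axis[pk[1]] - cfg$tx_focus), 16e-6)
  expect_lte(abs(img$lateral_axis[pk[2]]), cfg$pitch)
})

test_that("translating a scatterer by whole pitches translates the image", {
  cfg <- small_config()
  ex <- element_positions(cfg)
  mk <- function(col) {
    ph <- make_point_phantom(cfg$tx_focus)
    ph$scatterers$lateral_m <- ex[col]
    envelope_detect(das_beamform(simulate_rf(cfg, ph), cfg,
                                 make_rectangular(16)))
  }
  a <- mk(22L)
  b <- mk(26L)
  # columns whose subapertures are untruncated in both images
  interior <- 10:36
  expect_equal(a$pixels[, interior], b$pixels[, interior + 4L],
               tolerance = 1e-9)
})

test_that("envelope detection returns the analytic-signal magnitude", {
  cfg <- small_config()
  n <- 512
  tone <- matrix(sin(2 * pi * 40e6 * (0:(n - 1)) / cfg$fs), n, 3)
  img <- synthetic_image(tone, seq_len(n) * 1e-6, 1:3 * 1e-4, "rf_line")
  env <- envelope_detect(img)
  core <- env$pixels[50:(n - 50), ]
  expect_true(all(abs(core - 1) < 0.05))
  expect_true(all(env$pixels >= abs(img$pixels) - 1e-9))
  zero <- synthetic_image(matrix(0, 16, 2), 1:16, 1:2, "rf_line")
  expect_true(all(envelope_detect(zero)$pixels == 0))
  expect_error(envelope_detect(env), "stage-order")
})

test_that("self-normalization is idempotent, gain-invariant, and guards zeros", {
  px <- matrix(runif(50, 0, 4), 10)
  img <- synthetic_image(px, 1:10, 1:5, "envelope")
  nrm <- normalize_self(img)
  expect_identical(max(nrm$pixels), 1)
  expect_equal(normalize_self(nrm)$pixels, nrm$pixels)
  scaled <- synthetic_image(10 * px, 1:10, 1:5, "envelope")
  expect_equal(normalize_self(scaled)$pixels, nrm$pixels)
  zero <- synthetic_image(matrix(0, 4, 4), 1:4, 1:4, "envelope")
  expect_error(normalize_self(zero), "degenerate-normalization")
})

test_that("log compression maps to dB and clips at the dynamic range", {
  px <- matrix(c(1, 10^(-60 / 20), 0, 0.1), 2)
  img <- synthetic_image(px, 1:2, 1:2, "normalized")
  lc <- log_compress(img, 60)
  expect_equal(lc$pixels[1, 1], 0)
  expect_equal(lc$pixels[2, 1], -60)
  expect_equal(lc$pixels[1, 2], -60)
  expect_equal(lc$pixels[2, 2], -20)
  expect_true(all(lc$pixels >= -60 & lc$pixels <= 0))
  expect_error(log_compress(lc, 60), "stage-order")
  expect_error(log_compress(img, -5), "positive")
})
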