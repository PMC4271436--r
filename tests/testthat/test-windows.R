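test_that("rectangular window is all ones and validates its length", {
  expect_equal(make_rectangular(32)$weights, rep(1, 32))
  expect_equal(make_rectangular(2)$weights, c(1, 1))
  expect_error(make_rectangular(1), "invalid window length")
  expect_error(make_rectangular(7.5), "invalid window length")
})

test_that("rectangular spectrum matches the analytic Dirichlet kernel", {
  r <- impulse_response(make_rectangular(32))
  expect_equal(mainlobe_width(r, -6), dirichlet_width_oracle(32),
               tolerance = 0.005)
  expect_equal(highest_sidelobe(r), dirichlet_sidelobe_oracle(32),
               tolerance = 0.01)
  # Dirichlet nulls at the integer bins
  at_int <- r$magnitude_db[abs(r$bins - round(r$bins)) < 1e-9 &
                             abs(r$bins) >= 1 & abs(r$bins) <= 8]
  expect_true(all(at_int < -100))
})

test_that("bessel_i0 series agrees with the reference Bessel function", {
  x <- c(0, 0.1, 0.5, 1, 2.5, 5, 10)
  expect_equal(bessel_i0(x), besselI(x, 0), tolerance = 1e-10)
  expect_identical(bessel_i0(0), 1)
  expect_equal(bessel_i0(-x), bessel_i0(x))
  expect_error(bessel_i0(Inf), "finite")
})

test_that("Kaiser window degenerates to rectangular and trades width for side lobes", {
  expect_equal(make_kaiser(32, 0)$weights, make_rectangular(32)$weights,
               tolerance = 1e-12)
  expect_error(make_kaiser(32, -0.1), "invalid parameter")
  grid <- c(0, 0.25, 0.5, 0.8, 1.2)
  widths <- numeric(length(grid))
  lobes <- numeric(length(grid))
  for (i in seq_along(grid)) {
    r <- impulse_response(make_kaiser(32, grid[i]))
    widths[i] <- mainlobe_width(r, -6)
    lobes[i] <- highest_sidelobe(r)
  }
  expect_true(all(diff(widths) >= -1e-9))
  expect_true(all(diff(lobes) <= 1e-9))
})

test_that("Dolph-Chebyshev weights match the direct-sum oracle and are symmetric", {
  for (N in c(8, 16, 32)) {
    w <- make_dolph_chebyshev(N, 2.5)$weights
    expect_equal(w, dolph_chebyshev_oracle(N, 2.5), tolerance = 1e-9)
    expect_equal(w, rev(w), tolerance = 1e-12)
  }
  expect_error(make_dolph_chebyshev(32, 0), "invalid parameter")
  expect_error(make_dolph_chebyshev(32, -1), "invalid parameter")
})

test_that("Dolph-Chebyshev spectra are equiripple at -20*alpha dB", {
  for (N in c(16, 32)) {
    for (alpha in c(2, 2.5, 3)) {
      r <- impulse_response(make_dolph_chebyshev(N, alpha), 64)
      db <- r$magnitude_db
      # side-lobe local maxima outside the main lobe
      lm <- which(diff(sign(diff(db))) == -2) + 1
      lm <- lm[abs(r$bins[lm]) > mainlobe_width(r, -40)]
      expect_gt(length(lm), 4)
      expect_true(all(abs(db[lm] - (-20 * alpha)) < 0.5))
    }
  }
})

test_that("impulse_response is peak-normalized, centered, and guards pad_factor", {
  for (prof in list(make_rectangular(16), make_kaiser(32, 0.8),
                    make_dolph_chebyshev(32, 2.5))) {
    r <- impulse_response(prof)
    expect_identical(max(r$magnitude_db), 0)
    expect_identical(r$bins[which.max(r$magnitude_db)], 0)
    expect_equal(diff(r$bins), rep(1 / r$pad_factor, length(r$bins) - 1))
  }
  expect_error(impulse_response(make_rectangular(32), 8), "resolution")
})

test_that("mainlobe_width interpolates crossings and nests monotonically", {
  r <- impulse_response(make_dolph_chebyshev(32, 2.5))
  expect_gte(mainlobe_width(r, -35), mainlobe_width(r, -6))
  expect_error(mainlobe_width(r, 6), "negative")
  flat <- structure(
    list(magnitude_db = -abs(seq(-16, 16, by = 1 / 16)),
         bins = seq(-16, 16, by = 1 / 16), N = 32, pad_factor = 16),
    class = "spectral_response"
  )
  # triangular response in dB: exact closed-form crossing
  expect_equal(mainlobe_width(flat, -6), 12)
  expect_error(mainlobe_width(flat, -100), "no-crossing")
})

test_that("highest_sidelobe bounds the main lobe at the first local minima", {
  expect_equal(highest_sidelobe(impulse_response(make_rectangular(32))),
               -13.23, tolerance = 0.05)
  monotone <- structure(
    list(magnitude_db = -(seq(-16, 16, by = 1 / 16))^2,
         bins = seq(-16, 16, by = 1 / 16), N = 32, pad_factor = 16),
    class = "spectral_response"
  )
  expect_identical(highest_sidelobe(monotone), -Inf)
})

test_that("spectra round-trip through delimited text export", {
  r <- impulse_response(make_kaiser(16, 0.5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum(r, path)
  back <- utils::read.delim(path)
  expect_equal(back$bin, r$bins)
  expect_equal(back$dB, r$magnitude_db)
})
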