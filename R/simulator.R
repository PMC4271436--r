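#' Linear-array configuration
#'
#' Geometry and excitation of the simulated 40 MHz high-frequency linear
#' array: 128 elements at 40 um pitch, 32-element walking subaperture,
#' 128 scanlines, 1500 m/s speed of sound, 3.5 mm transmit focus, and a
#' 2-cycle sinusoidal excitation.  The sampling rate defaults to 10x the
#' center frequency (400 MHz); beamforming uses linearly interpolated
#' fractional delays, which keeps delay quantization far below a
#' wavelength at this rate.
#'
#' @param n_elements total number of elements.
#' @param n_sub subaperture size (elements active per scanline).
#' @param n_scanlines number of image scanlines (one per element
#'   position).
#' @param f0 center frequency, Hz.
#' @param pitch element pitch, m.
#' @param c speed of sound, m/s.
#' @param tx_focus transmit focal depth, m.
#' @param fs sampling frequency, Hz (must be >= 8 * f0).
#' @param n_cycles excitation cycles.
#' @param n_ir_cycles length, in cycles at `f0`, of the Hanning-weighted
#'   sinusoid modelling the electromechanical impulse response of each
#'   element, applied once on transmit and once on receive (0 = ideal
#'   broadband elements).  Band-limited elements are what make the far
#'   beam skirts interference-dominated, and hence controllable by
#'   apodization, as in real transducers.
#' @param dynamic_range_db display dynamic range, dB.
#' @return An `array_config`.
#' @export
array_config <- function(n_elements = 128L, n_sub = 32L, n_scanlines = 128L,
                         f0 = 40e6, pitch = 40e-6, c = 1500,
                         tx_focus = 3.5e-3, fs = 400e6, n_cycles = 2,
                         n_ir_cycles = 2, dynamic_range_db = 60) {
  cfg <- list(n_elements = as.integer(n_elements), n_sub = as.integer(n_sub),
              n_scanlines = as.integer(n_scanlines), f0 = f0, pitch = pitch,
              c = c, tx_focus = tx_focus, fs = fs, n_cycles = n_cycles,
              n_ir_cycles = n_ir_cycles, dynamic_range_db = dynamic_range_db)
  if (cfg$n_sub > cfg$n_elements) {
    stop("n_sub must not exceed n_elements", call. = FALSE)
  }
  if (cfg$n_scanlines > cfg$n_elements) {
    stop("n_scanlines must not exceed n_elements (scanlines sit at ",
         "element positions)", call. = FALSE)
  }
  if (cfg$fs < 8 * cfg$f0) {
    stop("fs must be at least 8 * f0", call. = FALSE)
  }
  if (any(unlist(cfg[c("f0", "pitch", "c", "tx_focus", "fs")]) <= 0)) {
    stop("all lengths, rates and speeds must be positive", call. = FALSE)
  }
  structure(cfg, class = "array_config")
}

#' Element lateral positions
#'
#' Element centers, in meters, measured from the array center.
#'
#' @param config an `array_config`.
#' @return Numeric vector of length `n_elements`.
#' @export
element_positions <- function(config) {
  stopifnot(inherits(config, "array_config"))
  (seq_len(config$n_elements) - (config$n_elements + 1) / 2) * config$pitch
}

#' Active-element indices for one scanline
#'
#' The walking subaperture: up to `n_sub` elements nearest the scanline
#' center, truncated (shrinking) at the array ends.  Scanline `l` sits
#' at element `l`'s lateral position.
#'
#' @param config an `array_config`.
#' @param scanline scanline index, 1-based.
#' @return Integer vector of element indices.
#' @export
subaperture_indices <- function(config, scanline) {
  stopifnot(inherits(config, "array_config"))
  half <- config$n_sub %/% 2L
  lo <- max(1L, scanline - half + 1L)
  hi <- min(config$n_elements, scanline + half)
  lo:hi
}

new_phantom <- function(scatterers, seed = NULL, label = "") {
  stopifnot(is.data.frame(scatterers),
            all(c("axial_m", "lateral_m", "amplitude") %in%
                  names(scatterers)))
  if (nrow(scatterers) > 0 &&
      (!all(is.finite(scatterers$amplitude)) ||
       any(scatterers$axial_m <= 0))) {
    stop("geometry error: scatterers need positive axial position and ",
         "finite amplitude", call. = FALSE)
  }
  structure(list(scatterers = scatterers, seed = seed, label = label),
            class = "ultrasound_phantom")
}

#' @export
print.ultrasound_phantom <- function(x, ...) {
  cat(sprintf("<ultrasound_phantom> '%s': %d scatterers\n",
              x$label, nrow(x$scatterers)))
  invisible(x)
}

#' Point-target phantom
#'
#' One unit-amplitude scatterer per requested depth, at the lateral
#' center of the image.  The default depths are the five point targets
#' at 2.5-4.5 mm straddling the 3.5 mm transmit focus.
#'
#' @param depths_m axial depths in meters, all positive.
#' @return An `ultrasound_phantom`.
#' @export
make_point_phantom <- function(depths_m = c(2.5, 3.0, 3.5, 4.0, 4.5) * 1e-3) {
  if (length(depths_m) == 0L) {
    stop("empty-phantom error: at least one depth required", call. = FALSE)
  }
  if (any(!is.finite(depths_m)) || any(depths_m <= 0)) {
    stop("geometry error: depths must be positive and finite", call. = FALSE)
  }
  new_phantom(
    data.frame(axial_m = sort(depths_m), lateral_m = 0, amplitude = 1),
    label = "point targets"
  )
}

#' Anechoic cyst phantom in diffuse scatterers
#'
#' Scatterers are distributed uniformly at random over the imaged region
#' (lateral span `n_scanlines * pitch` centered on the array, axial
#' `axial_range`), with standard-normal amplitudes; scatterers inside
#' the cyst disc are removed, making it anechoic.  Fully developed
#' speckle in the background requires several scatterers per resolution
#' cell; a warning is raised when the density implies fewer than one
#' scatterer per cell (cell area estimated as the two-way -20 dB focal
#' beamwidth times the pulse axial extent).
#'
#' @param diameter_m cyst diameter, m (default 1 mm).
#' @param depth_m cyst center depth, m (default 3.5 mm, the transmit
#'   focus).
#' @param density_per_mm2 scatterer number density, per mm^2 (default
#'   4000, the point where the background envelope SNR reaches the
#'   Rayleigh value of 1.91 for this array, i.e. fully developed
#'   speckle).
#' @param seed integer RNG seed for a reproducible phantom, or `NULL`.
#' @param config an `array_config` (sets the imaged region and the
#'   resolution-cell estimate).
#' @param axial_range axial extent of the scatterer field, m.
#' @return An `ultrasound_phantom`.
#' @export
make_cyst_phantom <- function(diameter_m = 1e-3, depth_m = 3.5e-3,
                              density_per_mm2 = 4000, seed = NULL,
                              config = array_config(),
                              axial_range = c(2e-3, 5e-3)) {
  stopifnot(inherits(config, "array_config"))
  if (density_per_mm2 <= 0) {
    stop("density must be positive", call. = FALSE)
  }
  span <- diff(axial_range)
  if (diameter_m >= span) {
    stop("geometry error: cyst diameter must be smaller than the imaged ",
         "depth span", call. = FALSE)
  }
  lat_half <- config$n_scanlines * config$pitch / 2
  area_mm2 <- (2 * lat_half * 1e3) * (span * 1e3)
  n <- round(density_per_mm2 * area_mm2)
  # resolution-cell estimate: two-way -20 dB focal beamwidth x pulse length
  lambda <- config$c / config$f0
  fnum <- config$tx_focus / (config$n_sub * config$pitch)
  eff_cycles <- config$n_cycles + 2 * config$n_ir_cycles
  cell_mm2 <- (2 * 1.21 * lambda * fnum * 1e3) *
    (eff_cycles * lambda / 2 * 1e3)
  if (density_per_mm2 * cell_mm2 < 1) {
    warning("fewer than one scatterer per resolution cell: speckle will ",
            "not be fully developed", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  x <- runif(n, -lat_half, lat_half)
  z <- runif(n, axial_range[1], axial_range[2])
  a <- rnorm(n)
  inside <- (x^2 + (z - depth_m)^2) < (diameter_m / 2)^2
  new_phantom(
    data.frame(axial_m = z[!inside], lateral_m = x[!inside],
               amplitude = a[!inside]),
    seed = seed,
    label = sprintf("anechoic cyst %.1f mm at %.1f mm", diameter_m * 1e3,
                    depth_m * 1e3)
  )
}

#' Export a phantom as delimited text
#'
#' Tab-separated columns `axial_m`, `lateral_m`, `amplitude`.
#'
#' @param phantom an `ultrasound_phantom`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_phantom <- function(phantom, path) {
  stopifnot(inherits(phantom, "ultrasound_phantom"))
  utils::write.table(phantom$scatterers, path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

excitation_pulse <- function(config) {
  t <- seq(0, config$n_cycles / config$f0, by = 1 / config$fs)
  sin(2 * pi * config$f0 * t)
}

element_impulse_response <- function(config) {
  if (config$n_ir_cycles <= 0) return(1)
  t <- seq(0, config$n_ir_cycles / config$f0, by = 1 / config$fs)
  hann <- 0.5 - 0.5 * cos(2 * pi * seq_along(t) / (length(t) + 1))
  sin(2 * pi * config$f0 * t) * hann
}

# effective round-trip pulse: excitation convolved with the element
# impulse response on transmit and again on receive
round_trip_pulse <- function(config) {
  p <- excitation_pulse(config)
  h <- element_impulse_response(config)
  if (length(h) > 1L) {
    p <- convolve(p, rev(h), type = "open")
    p <- convolve(p, rev(h), type = "open")
  }
  p / max(abs(p))
}

#' Simulate per-channel RF data
#'
#' Point-source simulator for the focused linear array: for each
#' scanline, the walking subaperture transmits the 2-cycle sine pulse
#' with fixed focal delays toward `tx_focus`; every
#' element-scatterer-element path contributes the pulse delayed by the
#' round-trip travel time and scaled by `amplitude / (d_tx * d_rx)`
#' spherical spreading; contributions are summed per receive element.
#' Elements are point-like (no directivity), with no elevation
#' dimension, attenuation, or transducer impulse response, so absolute
#' beam widths agree with full transducer simulations only
#' approximately.
#'
#' @param config an `array_config`.
#' @param phantom an `ultrasound_phantom`.
#' @return An `rf_channel_data`: per-scanline channel matrices
#'   (`samples`, time x active element), active-element index lists,
#'   `t0 = 0`, `fs`, per-scanline transmit reference times, and the
#'   axial range covered.
#' @export
simulate_rf <- function(config, phantom) {
  stopifnot(inherits(config, "array_config"),
            inherits(phantom, "ultrasound_phantom"))
  sc <- phantom$scatterers
  if (nrow(sc) > 0 && any(sc$axial_m <= 0)) {
    stop("geometry error: scatterer behind the array", call. = FALSE)
  }
  ex <- element_positions(config)
  pulse <- round_trip_pulse(config)
  pulse_center_s <- (which.max(hilbert_envelope(matrix(pulse))) - 1) /
    config$fs
  z_hi <- if (nrow(sc) > 0) max(sc$axial_m) + 5e-4 else config$tx_focus + 1e-3
  z_lo <- if (nrow(sc) > 0) max(2e-4, min(sc$axial_m) - 5e-4) else 2e-4
  span <- config$n_elements * config$pitch
  t_need <- 2 * sqrt(z_hi^2 + span^2) / config$c +
    length(pulse) / config$fs + 64 / config$fs
  nt <- as.integer(ceiling(t_need * config$fs))
  samples <- vector("list", config$n_scanlines)
  active <- vector("list", config$n_scanlines)
  tx_ref_t <- numeric(config$n_scanlines)
  for (l in seq_len(config$n_scanlines)) {
    idx <- subaperture_indices(config, l)
    exs <- ex[idx]
    xl <- ex[l]
    d <- sqrt((exs - xl)^2 + config$tx_focus^2)
    tau <- (max(d) - d) / config$c
    samples[[l]] <- sim_scanline_cpp(sc$lateral_m, sc$axial_m, sc$amplitude,
                                     exs, tau, pulse, config$fs, config$c,
                                     nt)
    active[[l]] <- idx
    tx_ref_t[l] <- max(d) / config$c
  }
  structure(
    list(samples = samples, active_elements = active, t0 = 0,
         fs = config$fs, tx_ref_t = tx_ref_t,
         pulse_center_s = pulse_center_s,
         z_range = c(z_lo, z_hi), config = config),
    class = "rf_channel_data"
  )
}

#' @export
print.rf_channel_data <- function(x, ...) {
  cat(sprintf(
    "<rf_channel_data> %d scanlines, %d time samples at %.0f MHz\n",
    length(x$samples), nrow(x$samples[[1]]), x$fs / 1e6))
  invisible(x)
}
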