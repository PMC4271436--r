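#' B-mode image container
#'
#' Internal constructor.  `pixels` is axial x lateral; axes are in
#' meters (axial depth from the array face, lateral from the array
#' center).  `stage` tracks the pipeline position: `rf_line` (beamformed
#' RF), `envelope`, `normalized` (envelope divided by its global
#' maximum, so max <= 1), or `log_compressed` (dB in
#' `[-dynamic_range_db, 0]`).
#' @noRd
new_bmode_image <- function(pixels, axial_axis, lateral_axis, stage,
                            dynamic_range_db = NULL) {
  stopifnot(is.matrix(pixels), nrow(pixels) == length(axial_axis),
            ncol(pixels) == length(lateral_axis),
            stage %in% c("rf_line", "envelope", "normalized",
                         "log_compressed"))
  structure(
    list(pixels = pixels, axial_axis = axial_axis,
         lateral_axis = lateral_axis, stage = stage,
         dynamic_range_db = dynamic_range_db),
    class = "bmode_image"
  )
}

#' @export
print.bmode_image <- function(x, ...) {
  cat(sprintf("<bmode_image> %d x %d pixels, stage '%s'\n",
              nrow(x$pixels), ncol(x$pixels), x$stage))
  invisible(x)
}

#' Delay-and-sum receive beamforming
#'
#' Forms one RF line per scanline with dynamic receive focusing: at
#' every image depth the receive delay of each active element is
#' computed from exact element-to-pixel geometry, channel samples are
#' fetched with linear interpolation, weighted by the receive
#' apodization profile, and summed.  The transmitted wavefront's
#' on-axis arrival time (referenced to the focal delays) and the pulse
#' center lag are folded into the fetch time, so a scatterer appears at
#' its geometric depth.
#'
#' The profile must match the full subaperture length; at truncated edge
#' subapertures the window is re-synthesized at the reduced element
#' count via [regenerate_profile()].
#'
#' @param rf an `rf_channel_data` from [simulate_rf()].
#' @param config the `array_config` used for the simulation.
#' @param profile receive `apod_profile` of length `config$n_sub`.
#' @return A `bmode_image` at stage `"rf_line"` on the axial grid
#'   `z = c * t / 2` spanning the RF data's depth range.
#' @export
das_beamform <- function(rf, config, profile) {
  stopifnot(inherits(rf, "rf_channel_data"),
            inherits(config, "array_config"),
            inherits(profile, "apod_profile"))
  if (profile$N != config$n_sub) {
    stop("apodization-mapping error: profile length must equal n_sub",
         call. = FALSE)
  }
  ex <- element_positions(config)
  dz <- config$c / (2 * config$fs)
  z <- seq(rf$z_range[1], rf$z_range[2], by = dz)
  pulse_center <- rf$pulse_center_s
  pixels <- matrix(0, length(z), config$n_scanlines)
  for (l in seq_len(config$n_scanlines)) {
    idx <- rf$active_elements[[l]]
    w <- if (length(idx) == config$n_sub) profile$weights
         else regenerate_profile(profile, length(idx))$weights
    t_offset <- rf$tx_ref_t[l] - config$tx_focus / config$c + pulse_center
    pixels[, l] <- das_scanline_cpp(rf$samples[[l]], ex[idx], ex[l], w, z,
                                    config$fs, config$c, t_offset)
  }
  new_bmode_image(pixels, z, ex[seq_len(config$n_scanlines)], "rf_line")
}

hilbert_envelope <- function(mat) {
  n <- nrow(mat)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(mvfft(mvfft(mat) * h, inverse = TRUE) / n)
}

#' Envelope detection
#'
#' Per-scanline magnitude of the analytic signal along the axial
#' dimension (full-length transform), removing the RF carrier.
#'
#' @param img a `bmode_image` at stage `"rf_line"`.
#' @return A `bmode_image` at stage `"envelope"` (nonnegative pixels).
#' @export
envelope_detect <- function(img) {
  stopifnot(inherits(img, "bmode_image"))
  if (!identical(img$stage, "rf_line")) {
    stop("stage-order error: envelope detection applies to rf_line images",
         call. = FALSE)
  }
  new_bmode_image(hilbert_envelope(img$pixels), img$axial_axis,
                  img$lateral_axis, "envelope")
}

#' Self-normalization
#'
#' Divides an envelope image by its own global maximum ("normalized by
#' itself"), so differently-weighted member images become comparable in
#' the minimum-selection stage.  Idempotent and gain-invariant.
#'
#' @param img a `bmode_image` at stage `"envelope"` or `"normalized"`.
#' @return A `bmode_image` at stage `"normalized"` with max exactly 1.
#' @export
normalize_self <- function(img) {
  stopifnot(inherits(img, "bmode_image"))
  if (!img$stage %in% c("envelope", "normalized")) {
    stop("stage-order error: normalization applies to envelope images",
         call. = FALSE)
  }
  m <- max(img$pixels)
  if (m <= 0) {
    stop("degenerate-normalization error: all-zero image", call. = FALSE)
  }
  new_bmode_image(img$pixels / m, img$axial_axis, img$lateral_axis,
                  "normalized")
}

#' Log compression
#'
#' Maps the normalized envelope to display brightness:
#' `20 * log10(pixels)` clipped to `[-dynamic_range_db, 0]` (zeros clip
#' to the floor).
#'
#' @param img a `bmode_image` at stage `"normalized"` (max <= 1; the
#'   minimum-combined image proceeds here without re-normalization).
#' @param dynamic_range_db positive display dynamic range in dB
#'   (default 60).
#' @return A `bmode_image` at stage `"log_compressed"`.
#' @export
log_compress <- function(img, dynamic_range_db = 60) {
  stopifnot(inherits(img, "bmode_image"))
  if (!identical(img$stage, "normalized")) {
    stop("stage-order error: log compression applies to normalized images",
         call. = FALSE)
  }
  if (dynamic_range_db <= 0) {
    stop("dynamic_range_db must be positive", call. = FALSE)
  }
  db <- 20 * log10(pmax(img$pixels, 10^(-dynamic_range_db / 20 - 16)))
  db <- pmin(pmax(db, -dynamic_range_db), 0)
  new_bmode_image(db, img$axial_axis, img$lateral_axis, "log_compressed",
                  dynamic_range_db = dynamic_range_db)
}

#' Write a log-compressed image as an 8-bit grayscale PNG
#'
#' Maps `[-dynamic_range_db, 0]` dB to `[0, 255]`.  Requires the
#' `png` package.
#'
#' @param img a `bmode_image` at stage `"log_compressed"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bmode_png <- function(img, path) {
  stopifnot(inherits(img, "bmode_image"))
  if (!identical(img$stage, "log_compressed")) {
    stop("stage-order error: raster export applies to log_compressed ",
         "images", call. = FALSE)
  }
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("package 'png' is required for raster export", call. = FALSE)
  }
  gray <- (img$pixels + img$dynamic_range_db) / img$dynamic_range_db
  png::writePNG(pmin(pmax(gray, 0), 1), path)
  invisible(path)
}
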