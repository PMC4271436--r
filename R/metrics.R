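#' Lateral beam projection
#'
#' Projects an envelope image onto the lateral axis by taking, at each
#' lateral position, the maximum envelope over an axial window spanning
#' the target and its side lobes; the projection is converted to dB and
#' peak-normalized.  The axial maximum (rather than mean) preserves
#' side-lobe peaks, which is what the side-lobe ROI ranges quantify.
#'
#' @param img a `bmode_image` at stage `"envelope"` or `"normalized"`.
#' @param axial_window `c(z_min, z_max)` in meters, within the image
#'   span.
#' @return A `lateral_projection` with fields `lateral_axis` (m) and
#'   `level_db` (peak 0 dB).
#' @export
lateral_projection <- function(img, axial_window) {
  stopifnot(inherits(img, "bmode_image"))
  if (!img$stage %in% c("envelope", "normalized")) {
    stop("stage-order error: projection applies to envelope images",
         call. = FALSE)
  }
  rows <- which(img$axial_axis >= axial_window[1] &
                  img$axial_axis <= axial_window[2])
  if (length(rows) == 0L) {
    stop("window error: axial window contains no image rows",
         call. = FALSE)
  }
  prof <- apply(img$pixels[rows, , drop = FALSE], 2, max)
  if (max(prof) <= 0) {
    stop("degenerate-normalization error: projection is identically zero",
         call. = FALSE)
  }
  db <- 20 * log10(pmax(prof / max(prof), 1e-300))
  structure(
    list(lateral_axis = img$lateral_axis, level_db = db,
         axial_window = axial_window),
    class = "lateral_projection"
  )
}

#' Main-lobe width of a lateral projection
#'
#' Full width between the first crossings of `level_db` on either side
#' of the projection peak, linearly interpolated between lateral
#' samples, reported in micrometers.
#'
#' @param proj a `lateral_projection`.
#' @param level_db negative reference level in dB (e.g. -6 or -35).
#' @return Width in micrometers.
#' @export
width_at_level <- function(proj, level_db) {
  stopifnot(inherits(proj, "lateral_projection"))
  if (level_db >= 0) stop("level_db must be negative", call. = FALSE)
  db <- proj$level_db
  x <- proj$lateral_axis
  n <- length(db)
  p <- which.max(db)
  i <- p
  while (i < n && db[i] > level_db) i <- i + 1L
  if (db[i] > level_db) {
    stop("no-crossing error: projection never falls below level_db",
         call. = FALSE)
  }
  fr <- (level_db - db[i - 1L]) / (db[i] - db[i - 1L])
  right <- x[i - 1L] + fr * (x[i] - x[i - 1L])
  j <- p
  while (j > 1L && db[j] > level_db) j <- j - 1L
  if (db[j] > level_db) {
    stop("no-crossing error: projection never falls below level_db",
         call. = FALSE)
  }
  fl <- (level_db - db[j + 1L]) / (db[j] - db[j + 1L])
  left <- x[j + 1L] + fl * (x[j] - x[j + 1L])
  (right - left) * 1e6
}

#' Side-lobe level over a lateral ROI
#'
#' Minimum and maximum of the projection, in dB, over two lateral
#' strips placed symmetrically on both sides of the projection peak at
#' the given offsets (default 0.3-0.4 mm, the standard side-lobe ROI
#' for these targets).
#'
#' @param proj a `lateral_projection`.
#' @param roi_lateral `c(min_offset, max_offset)` from the peak, m.
#' @return Named numeric `c(min_db, max_db)`.
#' @export
sidelobe_level <- function(proj, roi_lateral = c(0.3e-3, 0.4e-3)) {
  stopifnot(inherits(proj, "lateral_projection"))
  x0 <- proj$lateral_axis[which.max(proj$level_db)]
  off <- abs(proj$lateral_axis - x0)
  sel <- off >= roi_lateral[1] & off <= roi_lateral[2]
  if (!any(sel)) {
    stop("roi error: side-lobe ROI contains no lateral samples",
         call. = FALSE)
  }
  c(min_db = min(proj$level_db[sel]), max_db = max(proj$level_db[sel]))
}

#' ROI specification for cyst contrast measurements
#'
#' Inside: a disc concentric with the cyst, shrunk to 70% of the cyst
#' radius to avoid boundary blur.  Outside: two square background
#' patches at the same depth, laterally flanking the cyst.
#'
#' @param center `c(lateral_m, axial_m)` cyst center.
#' @param radius inside-disc radius, m.
#' @param offset lateral offset of the background patch centers, m.
#' @param half half-width of the square background patches, m.
#' @return An `roi_spec`.
#' @export
roi_spec <- function(center = c(0, 3.5e-3), radius = 0.35e-3,
                     offset = 1.2e-3, half = 0.35e-3) {
  if (offset - half < radius) {
    stop("roi error: inside and outside regions must be disjoint",
         call. = FALSE)
  }
  structure(
    list(center = center, radius = radius,
         outside = list(
           list(x = c(-offset - half, -offset + half),
                z = c(center[2] - half, center[2] + half)),
           list(x = c(offset - half, offset + half),
                z = c(center[2] - half, center[2] + half)))),
    class = "roi_spec"
  )
}

roi_masks <- function(img, roi) {
  lat <- matrix(img$lateral_axis, nrow(img$pixels), ncol(img$pixels),
                byrow = TRUE)
  ax <- matrix(img$axial_axis, nrow(img$pixels), ncol(img$pixels))
  inside <- (lat - roi$center[1])^2 + (ax - roi$center[2])^2 <
    roi$radius^2
  outside <- Reduce(`|`, lapply(roi$outside, function(r) {
    lat >= r$x[1] & lat <= r$x[2] & ax >= r$z[1] & ax <= r$z[2]
  }))
  list(inside = inside, outside = outside)
}

#' Contrast-to-noise ratio of a cyst image
#'
#' `|mean(outside) - mean(inside)| / sqrt(var(inside) + var(outside))`
#' computed on log-compressed ("brightness") pixel values, the standard
#' lesion-detectability measure.  With both ROIs constant the
#' denominator is zero and `Inf` is returned as a documented sentinel.
#'
#' @param img a `bmode_image` at stage `"log_compressed"`.
#' @param roi an `roi_spec`.
#' @return CNR (unitless).
#' @export
cnr <- function(img, roi = roi_spec()) {
  stopifnot(inherits(img, "bmode_image"), inherits(roi, "roi_spec"))
  if (!identical(img$stage, "log_compressed")) {
    stop("stage-order error: CNR is computed on log_compressed images",
         call. = FALSE)
  }
  m <- roi_masks(img, roi)
  if (!any(m$inside) || !any(m$outside)) {
    stop("roi error: empty ROI", call. = FALSE)
  }
  si <- img$pixels[m$inside]
  so <- img$pixels[m$outside]
  denom <- sqrt(var(si) + var(so))
  if (denom == 0) return(Inf)
  abs(mean(so) - mean(si)) / denom
}

#' Envelope signal-to-noise ratio of a speckle region
#'
#' Mean over standard deviation of the (linear) envelope in a
#' rectangular background region; fully developed (Rayleigh) speckle
#' gives `sqrt(pi / (4 - pi))` = 1.91.  Around the transmit focus the
#' deterministic depth-gain profile varies across any usefully large
#' region and would inflate the standard deviation, so the profile is
#' estimated by smoothing the per-row means over depth (the gain is
#' smooth, so smoothing avoids re-injecting speckle noise into the
#' compensation) and divided out before the statistics are taken.
#'
#' @param img a `bmode_image` at stage `"envelope"` or `"normalized"`.
#' @param region `list(x = c(min, max), z = c(min, max))` in meters.
#' @param gain_compensate divide out the smoothed depth-gain profile
#'   before computing the statistics (default `TRUE`).
#' @return Envelope SNR (unitless).
#' @export
speckle_snr <- function(img, region, gain_compensate = TRUE) {
  stopifnot(inherits(img, "bmode_image"))
  if (!img$stage %in% c("envelope", "normalized")) {
    stop("stage-order error: speckle SNR uses the linear envelope",
         call. = FALSE)
  }
  rows <- img$axial_axis >= region$z[1] & img$axial_axis <= region$z[2]
  cols <- img$lateral_axis >= region$x[1] & img$lateral_axis <= region$x[2]
  if (!any(rows) || !any(cols)) {
    stop("roi error: empty region", call. = FALSE)
  }
  v <- img$pixels[rows, cols, drop = FALSE]
  if (gain_compensate && nrow(v) > 10) {
    gain <- stats::lowess(seq_len(nrow(v)), rowMeans(v), f = 0.3)$y
    v <- v / gain
  }
  mean(v) / stats::sd(v)
}
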