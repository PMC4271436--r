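#' Minimum-selection combination of window spectra
#'
#' The core non-linear apodization step, applied at the spectrum level:
#' each member response is already normalized to a 0 dB peak, and the
#' combined response is the pointwise minimum of the dB magnitudes,
#' re-normalized so its peak is 0 dB.  Dual-apodization combines the
#' rectangular and Dolph-Chebyshev responses; tri-apodization adds the
#' Kaiser response.  The combination inherits the narrowest main lobe
#' near the peak and, far from the peak, the lowest member side-lobe
#' floor.
#'
#' @param responses list of >= 2 `spectral_response` objects on identical
#'   bin axes, each peak-normalized to 0 dB.
#' @return A `spectral_response`.
#' @examples
#' r <- impulse_response(make_rectangular(32))
#' d <- impulse_response(make_dolph_chebyshev(32, 2.5))
#' mainlobe_width(combine_spectra_min(list(r, d)), -6)  # 1.21 bins
#' @export
combine_spectra_min <- function(responses) {
  if (!is.list(responses) || length(responses) < 2L ||
      !all(vapply(responses, inherits, logical(1), "spectral_response"))) {
    stop("combine_spectra_min needs a list of >= 2 spectral_response objects",
         call. = FALSE)
  }
  ref <- responses[[1L]]
  for (r in responses[-1L]) {
    if (length(r$bins) != length(ref$bins) ||
        max(abs(r$bins - ref$bins)) > 1e-12) {
      stop("axis-mismatch error: member responses must share one bin axis",
           call. = FALSE)
    }
  }
  for (r in responses) {
    if (abs(max(r$magnitude_db)) > 1e-9) {
      stop("normalization error: member responses must peak at 0 dB",
           call. = FALSE)
    }
  }
  db <- Reduce(pmin, lapply(responses, `[[`, "magnitude_db"))
  db <- db - max(db)
  structure(
    list(magnitude_db = db, bins = ref$bins, N = ref$N,
         pad_factor = ref$pad_factor),
    class = "spectral_response"
  )
}

#' Minimum-selection combination of envelope images
#'
#' The comparator stage of the dual-/tri-apodization pipeline: each
#' member image has been beamformed with its own window, envelope
#' detected, and normalized by its own global maximum; the combined
#' image keeps the pixelwise minimum on the linear (pre-log) scale.
#' Minimum in dB and minimum on the linear scale agree for positive
#' data, but normalizing *before* the comparator is what lets the
#' differently-weighted images be compared at all, so the stage order
#' is enforced.  The output maximum is <= 1 (member peaks need not be
#' collocated) and the image proceeds directly to log compression.
#'
#' @param images list of >= 2 `bmode_image` objects at stage
#'   `"normalized"` on identical pixel grids.
#' @return A `bmode_image` at stage `"normalized"` (max <= 1).
#' @export
combine_images_min <- function(images) {
  if (!is.list(images) || length(images) < 2L ||
      !all(vapply(images, inherits, logical(1), "bmode_image"))) {
    stop("combine_images_min needs a list of >= 2 bmode_image objects",
         call. = FALSE)
  }
  ref <- images[[1L]]
  for (im in images[-1L]) {
    if (!identical(dim(im$pixels), dim(ref$pixels)) ||
        max(abs(im$axial_axis - ref$axial_axis)) > 1e-12 ||
        max(abs(im$lateral_axis - ref$lateral_axis)) > 1e-12) {
      stop("grid-mismatch error: images must share one pixel grid",
           call. = FALSE)
    }
  }
  for (im in images) {
    if (!identical(im$stage, "normalized")) {
      stop("stage-order error: combine after envelope detection and ",
           "self-normalization", call. = FALSE)
    }
    if (abs(max(im$pixels) - 1) > 1e-9) {
      stop("normalization error: each member image must have max 1",
           call. = FALSE)
    }
  }
  px <- Reduce(pmin, lapply(images, `[[`, "pixels"))
  new_bmode_image(px, ref$axial_axis, ref$lateral_axis, "normalized")
}

#' Singular window profiles and multi-apodization member sets
#'
#' Convenience constructor for the five methods under study: the three
#' singular windows plus the dual (rectangular + Dolph-Chebyshev) and
#' tri (+ Kaiser) member sets, all at one subaperture length.
#'
#' @param N window length (subaperture size), default 32.
#' @param alpha Dolph-Chebyshev parameter, default 2.5 (-50 dB design).
#' @param alpha_k Kaiser parameter, default `2.5/pi` (-21 dB design).
#' @return Named list: `rectangular`, `dolph_chebyshev` and `kaiser` map
#'   to a one-member list; `dual` and `tri` to their member lists.
#' @export
apodization_methods <- function(N = 32, alpha = 2.5, alpha_k = 2.5 / pi) {
  rect <- make_rectangular(N)
  dc <- make_dolph_chebyshev(N, alpha)
  ka <- make_kaiser(N, alpha_k)
  list(
    rectangular = list(rect),
    dolph_chebyshev = list(dc),
    kaiser = list(ka),
    dual = list(rect, dc),
    tri = list(rect, dc, ka)
  )
}
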