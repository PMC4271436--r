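#' Apodization profile constructor
#'
#' Internal constructor for the S3 class holding a length-`N` vector of
#' element (or sample) weights together with the window family and its
#' control parameter.  Weights are unitless, peak-normalized to 1.
#'
#' @param weights numeric weight vector, max 1.
#' @param family one of `"rectangular"`, `"dolph_chebyshev"`, `"kaiser"`.
#' @param param control parameter (alpha for Dolph-Chebyshev, alpha_k for
#'   Kaiser, `NA` for rectangular).
#' @noRd
new_apod_profile <- function(weights, family, param = NA_real_) {
  stopifnot(is.numeric(weights), all(is.finite(weights)),
            all(weights >= -1e-12), max(weights) <= 1 + 1e-12)
  structure(
    list(weights = as.numeric(weights), family = family,
         param = param, N = length(weights)),
    class = "apod_profile"
  )
}

#' @export
print.apod_profile <- function(x, ...) {
  p <- if (is.na(x$param)) "" else sprintf(", param = %.6g", x$param)
  cat(sprintf("<apod_profile> %s, N = %d%s\n", x$family, x$N, p))
  invisible(x)
}

check_window_length <- function(N) {
  if (!is.numeric(N) || length(N) != 1L || !is.finite(N) ||
      N != round(N) || N < 2) {
    stop("invalid window length: N must be an integer >= 2", call. = FALSE)
  }
  as.integer(N)
}

#' Rectangular (uniform) apodization window
#'
#' All weights equal to one.  The rectangular window has the narrowest
#' main lobe of any window (-6 dB spectral width 1.21 bins at N = 32) and
#' the highest side lobes (-13 dB).
#'
#' @param N window length (number of elements/samples), integer >= 2.
#' @return An `apod_profile`.
#' @examples
#' make_rectangular(32)
#' @export
make_rectangular <- function(N) {
  N <- check_window_length(N)
  new_apod_profile(rep(1, N), "rectangular")
}

#' Chebyshev polynomial of the first kind, any argument
#'
#' Evaluates T_n(x) piecewise: cos(n acos x) on [-1, 1] and the cosh/acosh
#' continuation outside, avoiding complex intermediates.
#' @noRd
cheb_poly <- function(n, x) {
  out <- numeric(length(x))
  inside <- abs(x) <= 1
  out[inside] <- cos(n * acos(x[inside]))
  up <- x > 1
  out[up] <- cosh(n * acosh(x[up]))
  dn <- x < -1
  out[dn] <- (-1)^n * cosh(n * acosh(-x[dn]))
  out
}

#' Dolph-Chebyshev equiripple apodization window
#'
#' Synthesizes the length-`N` Dolph-Chebyshev window by inverse DFT of its
#' Chebyshev-polynomial spectrum.  The design parameter `alpha` is the
#' common logarithm of the main-lobe-to-side-lobe ratio, so every side
#' lobe of the window's spectrum sits at exactly -20*alpha dB; alpha = 2.5
#' gives the -50 dB design used for dual-/tri-apodization.
#'
#' The spectrum samples are `T_(N-1)(beta * cos(pi*k/N))` with
#' `beta = cosh(acosh(10^alpha)/(N-1))`; for even `N` a half-sample linear
#' phase shifts the time origin so the returned weights are symmetric,
#' `w[n] == w[N-1-n]`.  The numerically-zero imaginary residue of the
#' inverse transform is discarded and the result is peak-normalized.
#'
#' @param N window length, integer >= 2.
#' @param alpha positive real; side lobes sit at -20*alpha dB.
#' @return An `apod_profile`.
#' @examples
#' w <- make_dolph_chebyshev(32, 2.5)
#' highest_sidelobe(impulse_response(w))  # -50 dB
#' @export
make_dolph_chebyshev <- function(N, alpha) {
  N <- check_window_length(N)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0) {
    stop("invalid parameter: alpha must be a positive real", call. = FALSE)
  }
  ord <- N - 1L
  beta <- cosh(acosh(10^alpha) / ord)
  k <- 0:(N - 1L)
  spec <- cheb_poly(ord, beta * cos(pi * k / N))
  if (N %% 2L == 0L) {
    # half-sample origin shift makes the even-length window symmetric
    w <- Re(fft(spec * exp(1i * pi * k / N)))
    half <- N %/% 2L + 1L
    w <- c(rev(w[2:half]), w[2:half])
  } else {
    w <- Re(fft(spec))
    half <- (N + 1L) %/% 2L
    w <- c(rev(w[2:half]), w[1:half])
  }
  new_apod_profile(w / max(w), "dolph_chebyshev", alpha)
}

#' Zero-order modified Bessel function of the first kind
#'
#' Power-series evaluation of I0(x) = sum_m ((x/2)^(2m) / (m!)^2),
#' terminated when a term falls below 1e-12 of the running sum.
#' Vectorized over `x`; the series converges for all finite arguments.
#'
#' @param x numeric vector, finite.
#' @return I0 evaluated elementwise.
#' @examples
#' bessel_i0(0)  # exactly 1
#' @export
bessel_i0 <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("bessel_i0 requires finite numeric input", call. = FALSE)
  }
  x2 <- (x / 2)^2
  total <- rep(1, length(x))
  term <- rep(1, length(x))
  m <- 0
  repeat {
    m <- m + 1
    term <- term * x2 / m^2
    total <- total + term
    if (all(term <= 1e-12 * total)) break
  }
  total
}

#' Kaiser apodization window
#'
#' Weights `I0(pi*alpha_k*sqrt(1 - x_n^2)) / I0(pi*alpha_k)` with
#' `x_n = 2n/(N-1) - 1`, evaluated with the series [bessel_i0()] and
#' peak-normalized.  The control parameter `alpha_k` trades main-lobe
#' width against side-lobe level: `alpha_k = 0` degenerates to the
#' rectangular window; `alpha_k = 2.5/pi` (the tri-apodization setting)
#' gives a -21 dB highest side lobe and a 1.43-bin -6 dB main lobe at
#' N = 32, between the rectangular and -50 dB Dolph-Chebyshev designs.
#'
#' @param N window length, integer >= 2.
#' @param alpha_k nonnegative control parameter.
#' @return An `apod_profile`.
#' @export
make_kaiser <- function(N, alpha_k) {
  N <- check_window_length(N)
  if (!is.numeric(alpha_k) || length(alpha_k) != 1L || !is.finite(alpha_k) ||
      alpha_k < 0) {
    stop("invalid parameter: alpha_k must be a nonnegative real",
         call. = FALSE)
  }
  n <- 0:(N - 1L)
  xn <- 2 * n / (N - 1L) - 1
  w <- bessel_i0(pi * alpha_k * sqrt(pmax(0, 1 - xn^2))) /
    bessel_i0(pi * alpha_k)
  new_apod_profile(w / max(w), "kaiser", alpha_k)
}

#' Re-synthesize a profile at a different length
#'
#' Regenerates the same window family and control parameter at length
#' `N`.  Used when a walking subaperture is truncated at the array edge:
#' re-synthesis preserves the family's spectral character, whereas
#' cropping would not.
#'
#' @param profile an `apod_profile`.
#' @param N new length.
#' @return An `apod_profile` of length `N`.
#' @export
regenerate_profile <- function(profile, N) {
  stopifnot(inherits(profile, "apod_profile"))
  switch(profile$family,
    rectangular = make_rectangular(N),
    dolph_chebyshev = make_dolph_chebyshev(N, profile$param),
    kaiser = make_kaiser(N, profile$param),
    stop("unknown window family: ", profile$family, call. = FALSE)
  )
}

#' Spectral impulse response of an apodization window
#'
#' Magnitude of the zero-padded DFT of the window, peak-normalized to
#' 0 dB, on a bin axis in units of the *unpadded* N-point DFT sample
#' spacing ("bin is a spectrum sample"); zero-padding by `pad_factor`
#' yields fractional-bin resolution `1/pad_factor`.  The response is
#' rotated so the main-lobe peak sits at bin 0.
#'
#' This padded numerical DFT is the single spectral pathway for all
#' window families; it is the discrete proxy for the one-way beam
#' pattern of the apodized aperture.
#'
#' @param profile an `apod_profile`.
#' @param pad_factor integer >= 16 (default 64, i.e. 1/64-bin resolution,
#'   enough to quote widths to 0.01 bins).
#' @return A `spectral_response` with fields `magnitude_db`, `bins`,
#'   `N`, `pad_factor`.
#' @examples
#' r <- impulse_response(make_rectangular(32))
#' mainlobe_width(r, -6)   # 1.21 bins
#' highest_sidelobe(r)     # -13 dB
#' @export
impulse_response <- function(profile, pad_factor = 64) {
  stopifnot(inherits(profile, "apod_profile"))
  if (!is.numeric(pad_factor) || length(pad_factor) != 1L ||
      pad_factor != round(pad_factor) || pad_factor < 16) {
    stop("resolution error: pad_factor must be an integer >= 16 ",
         "(bin measurements need <= 1/16-bin granularity)", call. = FALSE)
  }
  pad_factor <- as.integer(pad_factor)
  N <- profile$N
  M <- N * pad_factor
  mag <- Mod(fft(c(profile$weights, rep(0, M - N))))
  mag <- mag / max(mag)
  peak <- which.max(mag)
  half <- M %/% 2L
  # rotate so the peak lands at index half + 1 (bin 0)
  idx <- ((seq_len(M) - 1L + (peak - 1L) - half) %% M) + 1L
  mag <- mag[idx]
  db <- 20 * log10(pmax(mag, 1e-300))
  structure(
    list(magnitude_db = db,
         bins = (seq_len(M) - 1L - half) / pad_factor,
         N = N, pad_factor = pad_factor),
    class = "spectral_response"
  )
}

#' @export
print.spectral_response <- function(x, ...) {
  cat(sprintf("<spectral_response> N = %d, pad_factor = %d, %d samples\n",
              x$N, x$pad_factor, length(x$bins)))
  invisible(x)
}

interp_crossing <- function(bins, db, i_in, i_out, level_db) {
  # linear interpolation of the level crossing between adjacent samples
  frac <- (level_db - db[i_in]) / (db[i_out] - db[i_in])
  bins[i_in] + frac * (bins[i_out] - bins[i_in])
}

#' Main-lobe width at a reference level
#'
#' Full width, in bins, between the first crossings of `level_db` on
#' either side of the 0 dB peak, linearly interpolated between adjacent
#' spectrum samples.
#'
#' @param resp a `spectral_response` (peak at 0 dB).
#' @param level_db negative reference level in dB (e.g. -6).
#' @return Width in bins.
#' @export
mainlobe_width <- function(resp, level_db = -6) {
  stopifnot(inherits(resp, "spectral_response"))
  if (!is.numeric(level_db) || length(level_db) != 1L || level_db >= 0) {
    stop("level_db must be a negative real", call. = FALSE)
  }
  db <- resp$magnitude_db
  n <- length(db)
  p <- which.max(db)
  i <- p
  while (i < n && db[i] > level_db) i <- i + 1L
  if (db[i] > level_db) {
    stop("no-crossing error: response never falls below level_db",
         call. = FALSE)
  }
  right <- interp_crossing(resp$bins, db, i - 1L, i, level_db)
  j <- p
  while (j > 1L && db[j] > level_db) j <- j - 1L
  if (db[j] > level_db) {
    stop("no-crossing error: response never falls below level_db",
         call. = FALSE)
  }
  left <- interp_crossing(resp$bins, db, j + 1L, j, level_db)
  right - left
}

#' Highest side-lobe level
#'
#' Maximum of the response outside the main lobe, where the main lobe
#' extends from the peak to the first local minimum on each side.
#' Returns `-Inf` (no-side-lobe sentinel) for a response that decays
#' monotonically on both sides.
#'
#' @param resp a `spectral_response`.
#' @return Highest side-lobe level in dB (peak = 0 dB), or `-Inf`.
#' @export
highest_sidelobe <- function(resp) {
  stopifnot(inherits(resp, "spectral_response"))
  db <- resp$magnitude_db
  n <- length(db)
  p <- which.max(db)
  i <- p
  while (i < n && db[i + 1L] <= db[i]) i <- i + 1L
  j <- p
  while (j > 1L && db[j - 1L] <= db[j]) j <- j - 1L
  outside <- c(if (j > 1L) db[1:(j - 1L)], if (i < n) db[(i + 1L):n])
  if (length(outside) == 0L) return(-Inf)
  max(outside)
}

#' Harmonic (far) side-lobe level
#'
#' Level of the repeated side-lobe floor far from the main lobe: the
#' maximum response over `|bin| >= from_bin`.  For minimum-combined
#' spectra the near-in transition lobes (set by crossings between member
#' main lobes) differ from the far floor, which is capped by the lowest
#' member ripple; this reports the far floor.  The default region starts
#' at `N/8` bins, beyond the main lobe of every practical member window.
#'
#' @param resp a `spectral_response`.
#' @param from_bin start of the far side-lobe region in bins
#'   (default `N/8`).
#' @return Far side-lobe level in dB.
#' @export
harmonic_sidelobe_level <- function(resp, from_bin = NULL) {
  stopifnot(inherits(resp, "spectral_response"))
  if (is.null(from_bin)) from_bin <- resp$N / 8
  sel <- abs(resp$bins) >= from_bin
  if (!any(sel)) {
    stop("roi error: no spectrum samples at |bin| >= from_bin",
         call. = FALSE)
  }
  max(resp$magnitude_db[sel])
}

#' Export a spectral response as delimited text
#'
#' Two tab-separated columns, `bin` and `dB`, for external plotting.
#'
#' @param resp a `spectral_response`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(resp, path) {
  stopifnot(inherits(resp, "spectral_response"))
  utils::write.table(
    data.frame(bin = resp$bins, dB = resp$magnitude_db),
    path, sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
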