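# Independent brute-force oracles used across the suite.  None of these
# share code paths with the package implementation.

# Dirichlet kernel (spectrum of the uniform window), |W(f)| normalized to
# 1 at f = 0, f in bins.
dirichlet_mag <- function(f, N) {
  ifelse(abs(f) < 1e-12, 1,
         abs(sin(pi * f) / (N * sin(pi * f / N))))
}

# analytic -6 dB full width of the uniform window, in bins
dirichlet_width_oracle <- function(N, level_db = -6) {
  target <- 10^(level_db / 20)
  2 * stats::uniroot(function(f) dirichlet_mag(f, N) - target,
                     c(1e-6, 1))$root
}

# analytic highest side lobe of the uniform window, in dB
dirichlet_sidelobe_oracle <- function(N) {
  opt <- stats::optimize(function(f) dirichlet_mag(f, N),
                         c(1, 2), maximum = TRUE)
  20 * log10(opt$objective)
}

# Dolph-Chebyshev weights by direct loop summation of the inverse
# transform of the Chebyshev-polynomial spectrum (degree N-1, half-sample
# origin shift for even N) -- explicit cosines, no FFT.
cheb_oracle_poly <- function(n, x) {
  if (abs(x) <= 1) return(cos(n * acos(x)))
  if (x > 1) return(cosh(n * acosh(x)))
  (-1)^n * cosh(n * acosh(-x))
}

dolph_chebyshev_oracle <- function(N, alpha) {
  ord <- N - 1
  beta <- cosh(acosh(10^alpha) / ord)
  p <- vapply(0:(N - 1),
              function(k) cheb_oracle_poly(ord, beta * cos(pi * k / N)),
              numeric(1))
  if (N %% 2 == 0) {
    wp <- vapply(0:(N - 1), function(m) {
      s <- 0
      for (k in 0:(N - 1)) {
        s <- s + p[k + 1] * cos(pi * k * (2 * m - 1) / N)
      }
      s
    }, numeric(1))
    half <- N / 2 + 1
    w <- c(rev(wp[2:half]), wp[2:half])
  } else {
    wp <- vapply(0:(N - 1), function(m) {
      s <- 0
      for (k in 0:(N - 1)) s <- s + p[k + 1] * cos(2 * pi * k * m / N)
      s
    }, numeric(1))
    half <- (N + 1) / 2
    w <- c(rev(wp[2:half]), wp[1:half])
  }
  w / max(w)
}

# Delay-and-sum by explicit triple loop (depth x element x manual linear
# interpolation), mirroring the documented beamforming equations.
das_oracle <- function(rf_mat, ex, xl, w, z, fs, c0, t_offset) {
  nt <- nrow(rf_mat)
  out <- numeric(length(z))
  for (k in seq_along(z)) {
    acc <- 0
    for (e in seq_along(ex)) {
      t <- t_offset + z[k] / c0 +
        sqrt((ex[e] - xl)^2 + z[k]^2) / c0
      pos <- t * fs
      i0 <- floor(pos)
      if (i0 < 0 || i0 >= nt - 1) next
      frac <- pos - i0
      acc <- acc + w[e] *
        ((1 - frac) * rf_mat[i0 + 1, e] + frac * rf_mat[i0 + 2, e])
    }
    out[k] <- acc
  }
  out
}

# threshold-crossing width by dense scanning of a linearly resampled
# projection (no interpolation formula shared with the implementation)
dense_width_oracle <- function(proj, level_db, n_dense = 200000) {
  g <- stats::approx(proj$lateral_axis, proj$level_db, n = n_dense)
  p <- which.max(g$y)
  right <- which(g$y[p:n_dense] < level_db)[1]
  left <- which(rev(g$y[1:p]) < level_db)[1]
  (g$x[p + right - 1] - g$x[p - left + 1]) * 1e6
}

# small array configuration for fast simulator/beamformer tests
small_config <- function(...) {
  array_config(n_elements = 48L, n_sub = 16L, n_scanlines = 48L,
               tx_focus = 2.5e-3, ...)
}

# bare bmode_image builder for metric-level tests
synthetic_image <- function(pixels, axial, lateral, stage,
                            dynamic_range_db = NULL) {
  multiapod:::new_bmode_image(pixels, axial, lateral, stage,
                              dynamic_range_db)
}
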