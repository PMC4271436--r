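#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// RF channel data for one scanline.
//
// Each transmit-element -> scatterer -> receive-element path contributes
// the excitation pulse delayed by the transmit focal delay plus the
// round-trip travel time, scaled by amplitude / (d_tx * d_rx) spherical
// spreading.  Per receive element a fractional-delay impulse train is
// accumulated (linear interpolation between the two neighbouring
// samples) and convolved once with the pulse.
//
// sx, sz, sa : scatterer lateral/axial positions [m] and amplitudes
// ex         : active-element lateral positions [m]
// tx_delay   : per-element transmit focal delays [s]
// pulse      : sampled excitation at fs
// [[Rcpp::export]]
NumericMatrix sim_scanline_cpp(NumericVector sx, NumericVector sz,
                               NumericVector sa, NumericVector ex,
                               NumericVector tx_delay, NumericVector pulse,
                               double fs, double c0, int nt) {
  const int ns = sx.size();
  const int ne = ex.size();
  const int np = pulse.size();
  NumericMatrix out(nt, ne);
  if (ns == 0) return out;

  // transmit leg: per scatterer, per transmit element, in units of
  // samples so the receive loop is a single add per path
  std::vector<double> t_tx_fs(ns * ne), inv_tx(ns * ne);
  for (int s = 0; s < ns; ++s) {
    for (int j = 0; j < ne; ++j) {
      double dx = ex[j] - sx[s];
      double d = std::sqrt(dx * dx + sz[s] * sz[s]);
      t_tx_fs[s * ne + j] = (tx_delay[j] + d / c0) * fs;
      inv_tx[s * ne + j] = 1.0 / d;
    }
  }

  std::vector<double> train(nt);
  const double* sxp = &sx[0];
  const double* szp = &sz[0];
  const double* sap = &sa[0];
  const double* pp = &pulse[0];
  for (int e = 0; e < ne; ++e) {
    std::fill(train.begin(), train.end(), 0.0);
    const double exe = ex[e];
    for (int s = 0; s < ns; ++s) {
      double dx = exe - sxp[s];
      double d_rx = std::sqrt(dx * dx + szp[s] * szp[s]);
      double t_rx_fs = d_rx / c0 * fs;
      double amp_rx = sap[s] / d_rx;
      const double* tt = &t_tx_fs[s * ne];
      const double* it = &inv_tx[s * ne];
      for (int j = 0; j < ne; ++j) {
        double pos = tt[j] + t_rx_fs;
        int i0 = (int)pos;
        if (i0 >= 0 && i0 < nt - 1) {
          double amp = amp_rx * it[j];
          double a1 = amp * (pos - i0);
          train[i0] += amp - a1;
          train[i0 + 1] += a1;
        }
      }
    }
    // convolve impulse train with the excitation pulse
    double* col = &out(0, e);
    for (int k = 0; k < nt; ++k) {
      double v = train[k];
      if (v != 0.0) {
        int kmax = std::min(np, nt - k);
        double* c = col + k;
        for (int m = 0; m < kmax; ++m) c[m] += v * pp[m];
      }
    }
  }
  return out;
}

// Delay-and-sum beamforming of one scanline with dynamic receive
// focusing.  For each image depth z the receive delay of each element is
// computed from exact geometry; channel samples are fetched with linear
// interpolation and summed with the apodization weights.
//
// rf        : nt x ne channel matrix for this scanline
// ex        : active-element lateral positions [m]
// xl        : scanline lateral position [m]
// w         : receive apodization weights (length ne)
// z         : image depths [m]
// t_offset  : transmit time-of-arrival offset: the transmitted wavefront
//             reaches on-axis depth z at t_offset + z/c0 (includes the
//             pulse-centre lag)
// [[Rcpp::export]]
NumericVector das_scanline_cpp(NumericMatrix rf, NumericVector ex,
                               double xl, NumericVector w, NumericVector z,
                               double fs, double c0, double t_offset) {
  const int nz = z.size();
  const int ne = ex.size();
  const int nt = rf.nrow();
  NumericVector out(nz);
  for (int k = 0; k < nz; ++k) {
    double t_tx = t_offset + z[k] / c0;
    double acc = 0.0;
    for (int e = 0; e < ne; ++e) {
      if (w[e] == 0.0) continue;
      double dx = ex[e] - xl;
      double t = t_tx + std::sqrt(dx * dx + z[k] * z[k]) / c0;
      double pos = t * fs;
      int i0 = (int)std::floor(pos);
      if (i0 < 0 || i0 >= nt - 1) continue;
      double frac = pos - i0;
      acc += w[e] * ((1.0 - frac) * rf(i0, e) + frac * rf(i0 + 1, e));
    }
    out[k] = acc;
  }
  return out;
}
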