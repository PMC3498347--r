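#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Hann-windowed sinc interpolation kernel value at offset u (samples)
static inline double wsinc(double u, int half) {
  if (std::fabs(u) >= half) return 0.0;
  double s = (u == 0.0) ? 1.0 : std::sin(M_PI * u) / (M_PI * u);
  double w = 0.5 * (1.0 + std::cos(M_PI * u / half));
  return s * w;
}

// Delay-and-sum focus: out[t] = (1/sum w) * sum_i w_i * x_i[t + d_i]
// with fractional advance d_i (in samples) realised by an n_taps
// Hann-windowed sinc interpolator. Samples outside the matrix are zero.
// X: n x M (one column per channel), delays/weights length M.
// [[Rcpp::export]]
NumericVector cpp_delay_sum(NumericMatrix X, NumericVector delays,
                            NumericVector weights, int n_taps) {
  const int n = X.nrow(), M = X.ncol();
  if (n_taps < 3 || n_taps > 63) stop("n_taps must be in [3, 63]");
  const int half = n_taps / 2;
  NumericVector out(n);
  double wsum = 0.0;
  for (int i = 0; i < M; ++i) wsum += weights[i];
  for (int i = 0; i < M; ++i) {
    const double w = weights[i];
    if (w == 0.0) continue;
    const double d = delays[i];
    const int d_int = (int)std::floor(d);
    const double frac = d - d_int;
    if (frac == 0.0) {
      // exact integer advance
      for (int t = 0; t < n; ++t) {
        const int s = t + d_int;
        if (s >= 0 && s < n) out[t] += w * X(s, i);
      }
    } else {
      double kern[64];
      int k0 = -half + 1, k1 = half;
      for (int k = k0; k <= k1; ++k) kern[k - k0] = wsinc(k - frac, half);
      for (int t = 0; t < n; ++t) {
        double acc = 0.0;
        for (int k = k0; k <= k1; ++k) {
          const int s = t + d_int + k;
          if (s >= 0 && s < n) acc += kern[k - k0] * X(s, i);
        }
        out[t] += w * acc;
      }
    }
  }
  if (wsum > 0.0) for (int t = 0; t < n; ++t) out[t] /= wsum;
  return out;
}

// RMS over interior samples [from, to) (0-based, half-open)
// [[Rcpp::export]]
double cpp_rms(NumericVector x, int from, int to) {
  double acc = 0.0;
  for (int t = from; t < to; ++t) acc += x[t] * x[t];
  int n = to - from;
  return n > 0 ? std::sqrt(acc / n) : 0.0;
}

// Beamform every pixel and return its interior RMS.
// delays_px: n_px x M matrix of per-pixel advances in samples.
// edge: number of samples trimmed at each end before the RMS.
// [[Rcpp::export]]
NumericVector cpp_map_rms(NumericMatrix X, NumericMatrix delays_px,
                          NumericVector weights, int n_taps, int edge) {
  const int n_px = delays_px.nrow();
  const int n = X.nrow();
  NumericVector out(n_px);
  int from = edge, to = n - edge;
  if (to <= from) { from = 0; to = n; }
  for (int p = 0; p < n_px; ++p) {
    NumericVector d = delays_px(p, _);
    NumericVector y = cpp_delay_sum(X, d, weights, n_taps);
    out[p] = cpp_rms(y, from, to);
  }
  return out;
}

// Banded cross-correlations over interior samples:
// R[l + maxlag, i, j] = sum_{t in [edge, n-edge)} x_i(t + l) * x_j(t)
// (t + l clipped to valid range). Returned as (2*maxlag+1) x (M*M) matrix.
// [[Rcpp::export]]
NumericMatrix cpp_xcorr_band(NumericMatrix X, int edge, int maxlag) {
  const int n = X.nrow(), M = X.ncol();
  const int L = 2 * maxlag + 1;
  NumericMatrix R(L, M * M);
  int t0 = edge, t1 = n - edge;
  if (t1 <= t0) { t0 = 0; t1 = n; }
  for (int i = 0; i < M; ++i) {
    for (int j = 0; j <= i; ++j) {
      const double *xi = &X(0, i), *xj = &X(0, j);
      for (int l = -maxlag; l <= maxlag; ++l) {
        int a = t0, b = t1;
        if (a + l < 0) a = -l;
        if (b + l > n) b = n - l;
        double acc = 0.0;
        for (int t = a; t < b; ++t) acc += xi[t + l] * xj[t];
        R(l + maxlag, i * M + j) = acc;
        R(-l + maxlag, j * M + i) = acc;
      }
    }
  }
  return R;
}

// Per-pixel beamformed power via the lag-domain identity:
// n' * rms^2 = (1/W^2) sum_ij w_i w_j R_ij(d_i - d_j),
// R interpolated at fractional lags with the same windowed sinc.
// [[Rcpp::export]]
NumericVector cpp_map_rms_lag(NumericMatrix delays_px, NumericVector weights,
                              NumericMatrix R, int maxlag, int n_taps,
                              double n_samples) {
  const int n_px = delays_px.nrow();
  const int M = weights.size();
  const int half = n_taps / 2;
  NumericVector out(n_px);
  double W = 0.0;
  for (int i = 0; i < M; ++i) W += weights[i];
  for (int p = 0; p < n_px; ++p) {
    double acc = 0.0;
    for (int i = 0; i < M; ++i) {
      if (weights[i] == 0.0) continue;
      for (int j = 0; j < M; ++j) {
        if (weights[j] == 0.0) continue;
        double tau = delays_px(p, i) - delays_px(p, j);
        int t_int = (int)std::floor(tau);
        double frac = tau - t_int;
        double val;
        const int col = i * M + j;
        if (frac == 0.0) {
          val = R(t_int + maxlag, col);
        } else {
          val = 0.0;
          for (int k = -half + 1; k <= half; ++k) {
            int l = t_int + k;
            if (l < -maxlag || l > maxlag) continue;
            val += wsinc(k - frac, half) * R(l + maxlag, col);
          }
        }
        acc += weights[i] * weights[j] * val;
      }
    }
    acc /= (W * W * n_samples);
    out[p] = acc > 0.0 ? std::sqrt(acc) : 0.0;
  }
  return out;
}
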