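// Numeric kernels for the accelerometry pipeline. These are the only parts
// of the package where per-sample loops over full-day recordings (8.6e6
// samples/day) or per-frame spectral decompositions are unavoidable.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Interleave three per-axis sample vectors into the canonical 3 x T
// recording matrix in one sequential pass.
// [[Rcpp::export]]
NumericMatrix interleave3_cpp(NumericVector a, NumericVector b,
                              NumericVector c) {
  R_xlen_t T = a.size();
  if (b.size() != T || c.size() != T) stop("axis lengths differ");
  NumericMatrix x(3, (int)T);
  double *p = x.begin();
  for (R_xlen_t t = 0; t < T; ++t) {
    p[3 * t] = a[t];
    p[3 * t + 1] = b[t];
    p[3 * t + 2] = c[t];
  }
  return x;
}

// Assemble the background of a simulated recording in one sequential
// pass: piecewise-constant noise innovations (one value per blk samples,
// per axis) plus gravity linearly interpolated between orientation nodes
// (3 x nn matrix, one node per `block` samples).
// [[Rcpp::export]]
NumericMatrix assemble_background_cpp(NumericMatrix noise, int blk,
                                      NumericMatrix gnodes, int block,
                                      int T) {
  if (noise.nrow() != 3 || gnodes.nrow() != 3) stop("expected 3 axes");
  const int nb = noise.ncol(), nn = gnodes.ncol();
  if ((long long)nb * blk < T) stop("not enough noise innovations");
  if ((long long)(nn - 1) * block < T) stop("not enough gravity nodes");
  NumericMatrix x(3, T);
  double *p = x.begin();
  for (int t = 0; t < T; ++t) {
    const int ib = t / blk;
    const int seg = t / block;
    const double frac = (double)(t - seg * block) / block;
    for (int a = 0; a < 3; ++a) {
      const double g0 = gnodes(a, seg), g1 = gnodes(a, seg + 1);
      p[3 * t + a] = noise(a, ib) + g0 + (g1 - g0) * frac;
    }
  }
  return x;
}

// Euclidean norm of the three acceleration axes. x is 3 x T.
// [[Rcpp::export]]
NumericVector magnitude_cpp(NumericMatrix x) {
  if (x.nrow() != 3) stop("expected a 3 x T acceleration matrix");
  R_xlen_t T = x.ncol();
  NumericVector m(T);
  const double *p = x.begin();
  for (R_xlen_t t = 0; t < T; ++t) {
    const double a = p[3 * t], b = p[3 * t + 1], c = p[3 * t + 2];
    m[t] = std::sqrt(a * a + b * b + c * c);
  }
  return m;
}

// Windowed mean and population standard deviation of m at the given window
// centres (1-based sample indices). The window holds every sample within
// +/- halfw samples of the centre, truncated at the recording edges, and the
// 1/N normalisation is used. A long-double running sum over globally centred
// values keeps the add/drop update numerically exact to well below 1e-10.
// [[Rcpp::export]]
List window_moments_cpp(NumericVector m, IntegerVector centers, int halfw) {
  R_xlen_t T = m.size(), nc = centers.size();
  long double acc = 0.0L;
  for (R_xlen_t i = 0; i < T; ++i) acc += m[i];
  const double gmean = (double)(acc / (long double)T);

  NumericVector sigma(nc), mu(nc);
  IntegerVector nw(nc);
  long double s1 = 0.0L, s2 = 0.0L;
  R_xlen_t lo = 1, hi = 0;  // current window [lo, hi], 1-based, empty
  for (R_xlen_t j = 0; j < nc; ++j) {
    R_xlen_t c = centers[j];
    R_xlen_t wlo = std::max((R_xlen_t)1, c - halfw);
    R_xlen_t whi = std::min(T, c + halfw);
    if (wlo < lo || whi < hi) {  // non-monotone centres: rebuild
      s1 = 0.0L; s2 = 0.0L; lo = wlo; hi = wlo - 1;
    }
    while (hi < whi) {
      ++hi;
      const double v = m[hi - 1] - gmean;
      s1 += v; s2 += v * v;
    }
    while (lo < wlo) {
      const double v = m[lo - 1] - gmean;
      s1 -= v; s2 -= v * v;
      ++lo;
    }
    const long double n = (long double)(whi - wlo + 1);
    const long double mean_c = s1 / n;
    long double var = s2 / n - mean_c * mean_c;
    if (var < 0.0L) var = 0.0L;
    sigma[j] = (double)std::sqrt((double)var);
    mu[j] = (double)(mean_c + gmean);
    nw[j] = (int)n;
  }
  return List::create(_["sigma"] = sigma, _["mu"] = mu, _["n"] = nw);
}

// Eigenspectrum of the channel-delay correlation matrix of one frame, at one
// delay scale. frame is M x n; the M*N delayed copies (channel-major blocks,
// delays 0, d, ..., (N-1)*d samples) are truncated to their common overlap
// and standardised before correlation. Eigenvalues are returned in
// descending order, clamped at zero.
// [[Rcpp::export]]
arma::vec frame_eigenspectrum_cpp(NumericMatrix frame, int d, int N) {
  const int M = frame.nrow(), n = frame.ncol();
  const int L = n - (N - 1) * d;
  if (L < 2) stop("frame too short for delay scale %d", d);
  arma::mat E(M * N, L);
  for (int c = 0; c < M; ++c) {
    for (int k = 0; k < N; ++k) {
      const int r = c * N + k, off = k * d;
      double s1 = 0.0, s2 = 0.0;
      for (int t = 0; t < L; ++t) {
        const double v = frame(c, t + off);
        E(r, t) = v; s1 += v; s2 += v * v;
      }
      const double mean = s1 / L;
      double var = s2 / L - mean * mean;
      if (var <= 0.0) stop("zero-variance delayed copy in frame");
      const double sd = std::sqrt(var);
      for (int t = 0; t < L; ++t) E(r, t) = (E(r, t) - mean) / sd;
    }
  }
  arma::mat R = (E * E.t()) / (double)L;
  arma::vec ev;
  arma::eig_sym(ev, R);                    // ascending
  ev = arma::reverse(ev);
  ev.clamp(0.0, arma::datum::inf);
  return ev;
}

// Fused magnitude + windowed moments for the segmentation path: computes
// the magnitude internally and returns the windowed statistics, avoiding a
// round trip of the full magnitude vector through R.
// [[Rcpp::export]]
List recording_energy_cpp(NumericMatrix x, IntegerVector centers,
                          int halfw) {
  NumericVector m = magnitude_cpp(x);
  return window_moments_cpp(m, centers, halfw);
}

// First-peak autocorrelation check of one gait frame. For each axis the
// mean-removed autocorrelation, normalised by lag zero, is evaluated on the
// sample grid. Within delays [tau6, tau7] the first negative value is
// located; the first local maximum at a strictly later delay is the step
// peak. Returns the per-axis peak delay in seconds (NA when no qualifying
// peak) and its height.
// [[Rcpp::export]]
List gait_acf_peaks_cpp(NumericMatrix frame, double fs, double tau6,
                        double tau7, double gamma4) {
  const int M = frame.nrow(), n = frame.ncol();
  const int lmin = (int)std::ceil(tau6 * fs - 1e-9);
  const int lmax = (int)std::floor(tau7 * fs + 1e-9);
  if (lmax + 1 >= n) stop("frame shorter than maximum autocorrelation delay");
  NumericVector step(M, NA_REAL), height(M, NA_REAL);
  std::vector<double> r(lmax + 2);
  for (int c = 0; c < M; ++c) {
    double s1 = 0.0;
    for (int t = 0; t < n; ++t) s1 += frame(c, t);
    const double mean = s1 / n;
    double r0 = 0.0;
    for (int t = 0; t < n; ++t) {
      const double v = frame(c, t) - mean;
      r0 += v * v;
    }
    if (r0 <= 0.0) continue;  // zero-variance axis: no peak
    for (int lag = lmin - 1; lag <= lmax + 1; ++lag) {
      double s = 0.0;
      for (int t = 0; t < n - lag; ++t)
        s += (frame(c, t) - mean) * (frame(c, t + lag) - mean);
      r[lag - (lmin - 1)] = s / r0;  // biased estimator, unit lag-zero
    }
    // first negative within [lmin, lmax]
    int ineg = -1;
    for (int lag = lmin; lag <= lmax; ++lag)
      if (r[lag - (lmin - 1)] < 0.0) { ineg = lag; break; }
    if (ineg < 0) continue;  // no negative excursion: conservative reject
    // first local maximum after the first negative (earliest of a plateau)
    for (int lag = ineg + 1; lag <= lmax; ++lag) {
      const double prev = r[lag - 1 - (lmin - 1)];
      const double cur = r[lag - (lmin - 1)];
      const double nxt = r[lag + 1 - (lmin - 1)];
      if (cur > prev && cur >= nxt) {
        step[c] = lag / fs;
        height[c] = cur;
        break;
      }
    }
  }
  bool valid = true;
  for (int c = 0; c < M; ++c)
    if (!(R_finite(height[c]) && height[c] > gamma4)) { valid = false; break; }
  return List::create(_["valid"] = valid, _["step_time_s"] = step,
                      _["height"] = height);
}
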