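// Hot loops of the pipeline: the iAAFT surrogate iteration (FFTW-backed)
// and the Bandt-Pompe ordinal-pattern coding.
#include <Rcpp.h>
#include <fftw3.h>
#include <algorithm>
#include <cmath>
#include <complex>
#include <cstdint>
#include <cstring>
#include <vector>

using namespace Rcpp;

// FFTW plans are cached per transform length (the surrogate ensemble calls
// this thousands of times with one length), with measured planning for
// long transforms. Single-threaded use only, as everywhere in R.
struct FftCache {
  int n = -1;
  std::vector<double> buf_r;
  std::vector<std::complex<double>> buf_c;
  fftw_plan fwd = nullptr, bwd = nullptr;

  void prepare(int n_new) {
    if (n_new == n) return;
    release();
    n = n_new;
    buf_r.assign(n, 0.0);
    buf_c.assign(n / 2 + 1, std::complex<double>(0.0, 0.0));
    unsigned flags = n >= 4096 ? FFTW_MEASURE : FFTW_ESTIMATE;
    fwd = fftw_plan_dft_r2c_1d(
        n, buf_r.data(), reinterpret_cast<fftw_complex*>(buf_c.data()), flags);
    bwd = fftw_plan_dft_c2r_1d(
        n, reinterpret_cast<fftw_complex*>(buf_c.data()), buf_r.data(), flags);
  }
  void release() {
    if (fwd) fftw_destroy_plan(fwd);
    if (bwd) fftw_destroy_plan(bwd);
    fwd = bwd = nullptr;
  }
};
static FftCache g_fft;

// Radix-based rank remap: argsorts z (LSD radix on the top 48 bits of the
// order-preserving IEEE-754 bit flip — values equal to within ~2^-37
// relative may tie, resolved stably by index) and in the same final pass
// writes the remapped surrogate y (sorted_x placed at the ranks of z) and
// the rank vector used for fixed-point detection.
static void radix_rank_remap(const std::vector<double>& z,
                             const std::vector<double>& sorted_x,
                             std::vector<double>& y,
                             std::vector<int>& rank,
                             std::vector<std::pair<uint64_t, int>>& a,
                             std::vector<std::pair<uint64_t, int>>& b,
                             std::vector<int>& hist) {
  const int n = static_cast<int>(z.size());
  hist.assign(3 << 16, 0);
  for (int i = 0; i < n; ++i) {
    uint64_t u;
    std::memcpy(&u, &z[i], 8);
    u ^= (u >> 63) ? ~uint64_t(0) : (uint64_t(1) << 63);
    u >>= 16;
    a[i] = std::make_pair(u, i);
    ++hist[u & 0xFFFF];
    ++hist[(1 << 16) + ((u >> 16) & 0xFFFF)];
    ++hist[(2 << 16) + (u >> 32)];
  }
  for (int pass = 0; pass < 3; ++pass) {
    int* count = hist.data() + (pass << 16);
    int pos = 0;
    for (int d = 0; d < (1 << 16); ++d) {
      int c = count[d];
      count[d] = pos;
      pos += c;
    }
  }
  for (int i = 0; i < n; ++i)
    b[hist[a[i].first & 0xFFFF]++] = a[i];
  std::swap(a, b);
  {
    int* count = hist.data() + (1 << 16);
    for (int i = 0; i < n; ++i)
      b[count[(a[i].first >> 16) & 0xFFFF]++] = a[i];
    std::swap(a, b);
  }
  {
    int* count = hist.data() + (2 << 16);
    for (int i = 0; i < n; ++i) {
      const int k = count[a[i].first >> 32]++;   // final sorted position
      const int src = a[i].second;
      y[src] = sorted_x[k];
      rank[k] = src;
    }
  }
}

// One iAAFT surrogate. `y0` is the initial series (a seeded random
// permutation of `x`, drawn on the R side). Each iteration imposes the
// amplitude spectrum of `x` in the Fourier domain, then rank-remaps onto
// the sorted values of `x`. Stops when the rank order is identical on two
// consecutive iterations (exact fixed point), when the relative
// amplitude-spectrum discrepancy drops below `spec_tol` (the surrogate is
// spectrally faithful), when the discrepancy stalls (relative improvement
// below `stall_tol`, allowed only once the discrepancy is already below
// `stall_ceiling`, so a slow mid-descent plateau cannot freeze a poor
// surrogate), or at `max_iter`.
// [[Rcpp::export(name = ".iaaft_core")]]
List iaaft_core(const NumericVector& x, const NumericVector& y0,
                int max_iter, double stall_tol = 0.05,
                double spec_tol = 3.5e-3, double stall_ceiling = 4.5e-3,
                int min_iter = 10) {
  const int n = x.size();
  const int nc = n / 2 + 1;

  std::vector<double> sorted_x(x.begin(), x.end());
  std::sort(sorted_x.begin(), sorted_x.end());

  g_fft.prepare(n);
  std::vector<double>& buf_r = g_fft.buf_r;
  std::vector<std::complex<double>>& buf_c = g_fft.buf_c;
  const fftw_plan& fwd = g_fft.fwd;
  const fftw_plan& bwd = g_fft.bwd;

  // amplitude spectrum of the original
  std::copy(x.begin(), x.end(), buf_r.begin());
  fftw_execute(fwd);
  std::vector<double> amp(nc);
  double amp_norm2 = 0.0;
  for (int k = 0; k < nc; ++k) {
    amp[k] = std::abs(buf_c[k]);
    amp_norm2 += amp[k] * amp[k];
  }

  std::vector<double> y(y0.begin(), y0.end());
  std::vector<std::pair<uint64_t, int>> ra(n), rb(n);
  std::vector<int> hist;
  std::vector<int> rank(n), prev_rank(n, -1);

  bool converged = false;
  double err_prev = -1.0;
  int iter = 0;
  for (iter = 1; iter <= max_iter; ++iter) {
    std::copy(y.begin(), y.end(), buf_r.begin());
    fftw_execute(fwd);
    // discrepancy of the CURRENT y: the quality-based stops fire here, so
    // the returned surrogate is exactly the one that met them (a further
    // spectral projection + remap could degrade it again)
    double diff2 = 0.0;
    for (int k = 0; k < nc; ++k) {
      double mag = std::abs(buf_c[k]);
      double d = mag - amp[k];
      diff2 += d * d;
      if (mag > 0.0)
        buf_c[k] *= amp[k] / mag;
      else
        buf_c[k] = std::complex<double>(amp[k], 0.0);
    }
    double err = std::sqrt(diff2 / amp_norm2);
    if (iter > 1) {
      if (err < spec_tol) {
        converged = true;  // spectrally faithful
        --iter;
        break;
      }
      if (iter > min_iter && err < stall_ceiling &&
          err >= err_prev * (1.0 - stall_tol)) {
        converged = true;  // spectral discrepancy has stalled
        --iter;
        break;
      }
    }
    err_prev = err;

    // (i) impose the original amplitude spectrum, keep current phases
    fftw_execute(bwd);  // unnormalized inverse: scale is rank-irrelevant
    // (ii) rank-remap onto the original sorted values
    radix_rank_remap(buf_r, sorted_x, y, rank, ra, rb, hist);

    if (rank == prev_rank) {
      converged = true;
      break;
    }
    prev_rank = rank;
  }
  if (iter > max_iter) iter = max_iter;

  // periodogram (power) relative L2 error of the final surrogate
  std::copy(y.begin(), y.end(), buf_r.begin());
  fftw_execute(fwd);
  double dp2 = 0.0, q2 = 0.0;
  for (int k = 0; k < nc; ++k) {
    double p = std::norm(buf_c[k]);
    double q = amp[k] * amp[k];
    dp2 += (p - q) * (p - q);
    q2 += q * q;
  }
  double spec_err = q2 > 0.0 ? std::sqrt(dp2 / q2) : 0.0;

  return List::create(_["surrogate"] = NumericVector(y.begin(), y.end()),
                      _["iterations"] = iter,
                      _["converged"] = converged,
                      _["spectrum_rel_error"] = spec_err);
}

// Base-M code of the rank-position vector of each M-point embedding window
// (lag tau). For window at time u (0-based, u >= (M-1)*tau) the components
// are v_j = x[u - j*tau], j = 0..M-1. pos_j = number of components ranked
// above v_j in the descending order, ties broken so that the component with
// the LARGER lag index comes first (equal values => smaller lag takes the
// later slot). Code = sum_j pos_j * M^j.
// [[Rcpp::export(name = ".ordinal_codes")]]
IntegerVector ordinal_codes(const NumericVector& x, int M, int tau) {
  const int T = x.size();
  const int span = (M - 1) * tau;
  const int nvec = T - span;
  if (nvec < 1) stop("series too short for the requested embedding");
  IntegerVector codes(nvec);
  std::vector<double> v(M);
  std::vector<int> powM(M);
  powM[0] = 1;
  for (int j = 1; j < M; ++j) powM[j] = powM[j - 1] * M;

  for (int i = 0; i < nvec; ++i) {
    const int u = span + i;
    for (int j = 0; j < M; ++j) v[j] = x[u - j * tau];
    int code = 0;
    for (int j = 0; j < M; ++j) {
      int pos = 0;
      for (int k = 0; k < M; ++k) {
        if (k == j) continue;
        if (v[k] > v[j] || (v[k] == v[j] && k > j)) ++pos;
      }
      code += pos * powM[j];
    }
    codes[i] = code;
  }
  return codes;
}
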