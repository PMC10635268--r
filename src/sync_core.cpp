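// Hot loops for synchronization detection: subject-wise bootstrap of the
// per-TR group median, and the phase-randomization max-statistic null.
// Both draw from R's RNG so results are reproducible under set.seed().
#include <RcppArmadillo.h>
#include <fftw3.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// median of n values via insertion sort of a scratch buffer; subject counts
// are small (tens), where this beats nth_element by a wide margin
static inline double median_small(double* buf, const int n) {
  for (int i = 1; i < n; ++i) {
    const double key = buf[i];
    int j = i - 1;
    while (j >= 0 && buf[j] > key) {
      buf[j + 1] = buf[j];
      --j;
    }
    buf[j + 1] = key;
  }
  const int h = n / 2;
  return (n % 2) ? buf[h] : 0.5 * (buf[h] + buf[h - 1]);
}

// type-7 quantile of a sorted array
static inline double quantile7_sorted(const double* x, const int n,
                                      const double p) {
  if (n == 1) return x[0];
  const double h = (n - 1) * p;
  const int lo = (int)std::floor(h);
  if (lo >= n - 1) return x[n - 1];
  return x[lo] + (h - lo) * (x[lo + 1] - x[lo]);
}

// X: subjects x TR. Returns 2 x TR matrix (row 0: lower, row 1: upper)
// percentile bootstrap interval for the per-TR median over subject resamples.
// [[Rcpp::export]]
NumericMatrix cpp_boot_median_ci(const NumericMatrix& X, const int n_boot,
                                 const double p_lo, const double p_hi) {
  const int n = X.nrow(), T = X.ncol();
  arma::mat meds(n_boot, T);          // column t: bootstrap medians at TR t
  std::vector<int> idx(n);
  std::vector<double> buf(n);
  const double* xp = X.begin();       // column-major, column t at xp + n*t
  for (int b = 0; b < n_boot; ++b) {
    for (int j = 0; j < n; ++j) {
      int k = (int)(unif_rand() * n);
      if (k == n) k = n - 1;
      idx[j] = k;
    }
    for (int t = 0; t < T; ++t) {
      const double* col = xp + (size_t)n * t;
      for (int j = 0; j < n; ++j) buf[j] = col[idx[j]];
      meds(b, t) = median_small(buf.data(), n);
    }
  }
  NumericMatrix out(2, T);
  for (int t = 0; t < T; ++t) {
    double* col = meds.colptr(t);
    std::sort(col, col + n_boot);
    out(0, t) = quantile7_sorted(col, n_boot, p_lo);
    out(1, t) = quantile7_sorted(col, n_boot, p_hi);
  }
  return out;
}

// X: subjects x TR. Each draw phase-randomizes every subject's series
// independently (amplitude spectrum preserved; DC and Nyquist untouched),
// takes the per-TR median across subjects, and records the max over TRs.
// Uses FFTW half-complex transforms with one reused batched plan so the
// per-draw cost is a single plan execution plus the random phases.
// [[Rcpp::export]]
NumericVector cpp_null_max_median(const NumericMatrix& X, const int n_phase) {
  const int n = X.nrow(), T = X.ncol();
  const int nc = T / 2 + 1;                 // r2c spectrum length
  const int half = (T - 1) / 2;             // indices 1..half get random phase
  std::vector<double> tbuf(T);
  std::vector<std::complex<double>> F((size_t)nc * n);
  fftw_plan pf = fftw_plan_dft_r2c_1d(
      T, tbuf.data(), reinterpret_cast<fftw_complex*>(F.data()), FFTW_ESTIMATE);
  for (int j = 0; j < n; ++j) {
    for (int t = 0; t < T; ++t) tbuf[t] = X(j, t);
    fftw_execute_dft_r2c(
        pf, tbuf.data(),
        reinterpret_cast<fftw_complex*>(F.data() + (size_t)nc * j));
  }
  fftw_destroy_plan(pf);
  // pre-scale by 1/T so the inverse transform is orthonormalized
  for (size_t i = 0; i < F.size(); ++i) F[i] /= (double)T;
  std::vector<double> mag((size_t)nc * n);
  for (size_t i = 0; i < F.size(); ++i) mag[i] = std::abs(F[i]);

  std::vector<std::complex<double>> spec((size_t)nc * n);
  std::vector<double> yr((size_t)T * n);
  int Tn = T;
  // interleaved output (subject-major within each TR) keeps the median
  // gather below contiguous
  fftw_plan pb = fftw_plan_many_dft_c2r(
      1, &Tn, n, reinterpret_cast<fftw_complex*>(spec.data()), NULL, 1, nc,
      yr.data(), NULL, n, 1, FFTW_ESTIMATE);

  NumericVector out(n_phase);
  std::vector<double> buf(n);
  for (int d = 0; d < n_phase; ++d) {
    for (int j = 0; j < n; ++j) {
      std::complex<double>* sc = spec.data() + (size_t)nc * j;
      const std::complex<double>* fc = F.data() + (size_t)nc * j;
      const double* mc = mag.data() + (size_t)nc * j;
      sc[0] = fc[0];                        // DC kept
      for (int k = 1; k <= half; ++k) {
        // uniform random phase via Marsaglia polar draw (no trig calls):
        // (u, v) uniform in the unit disc gives cos = (u^2 - v^2) / s,
        // sin = 2uv / s with s = u^2 + v^2
        double u, v, s;
        do {
          u = 2.0 * unif_rand() - 1.0;
          v = 2.0 * unif_rand() - 1.0;
          s = u * u + v * v;
        } while (s >= 1.0 || s == 0.0);
        sc[k] = std::complex<double>(mc[k] * (u * u - v * v) / s,
                                     mc[k] * (2.0 * u * v) / s);
      }
      if (T % 2 == 0) sc[nc - 1] = fc[nc - 1]; // Nyquist kept
    }
    fftw_execute(pb);
    double mx = -std::numeric_limits<double>::infinity();
    // the median at a TR can only exceed the running max when at least
    // ceil((n+1)/2) values do; count first, sort only when it can
    const int need = (n % 2) ? (n / 2 + 1) : (n / 2);
    for (int t = 0; t < T; ++t) {
      const double* col = yr.data() + (size_t)n * t;
      int cnt = 0;
      for (int j = 0; j < n; ++j) cnt += (col[j] > mx);
      if (cnt < need) continue;
      std::copy(col, col + n, buf.begin());
      const double m = median_small(buf.data(), n);
      if (m > mx) mx = m;
    }
    out[d] = mx;
  }
  fftw_destroy_plan(pb);
  return out;
}

// per-TR median across subjects (rows) of X
// [[Rcpp::export]]
NumericVector cpp_col_median(const NumericMatrix& X) {
  const int n = X.nrow(), T = X.ncol();
  NumericVector out(T);
  std::vector<double> buf(n);
  const double* xp = X.begin();
  for (int t = 0; t < T; ++t) {
    const double* col = xp + (size_t)n * t;
    std::copy(col, col + n, buf.begin());
    out[t] = median_small(buf.data(), n);
  }
  return out;
}

// Permutation null for the bias tests: each draw places n_sync[c] TRs
// uniformly without replacement over valid_trs for every cell c, maps them
// through the lag window to unique movie bins, and records the labeled
// fraction. A stamp array makes the bin union O(window) per TR.
// [[Rcpp::export]]
NumericMatrix cpp_random_biases(const IntegerVector& n_sync,
                                const IntegerVector& valid_trs,
                                const IntegerVector& labels,
                                const int n_perm, const int tr_offset,
                                const int lag_lo, const int lag_hi) {
  const int ncell = n_sync.size(), nv = valid_trs.size(),
            nb = labels.size();
  std::vector<int> pool(valid_trs.begin(), valid_trs.end());
  std::vector<int> stamp(nb, -1);
  NumericMatrix out(n_perm, ncell);
  int era = 0;
  for (int p = 0; p < n_perm; ++p) {
    for (int c = 0; c < ncell; ++c) {
      const int k = n_sync[c];
      for (int i = 0; i < k; ++i) {          // partial Fisher-Yates
        int j = i + (int)(unif_rand() * (nv - i));
        if (j >= nv) j = nv - 1;
        std::swap(pool[i], pool[j]);
      }
      ++era;
      int tot = 0, lab = 0;
      for (int i = 0; i < k; ++i) {
        const int m = pool[i] + tr_offset;
        for (int b = m - lag_hi; b < m - lag_lo; ++b) {
          if (b < 0 || b >= nb || stamp[b] == era) continue;
          stamp[b] = era;
          ++tot;
          lab += labels[b];
        }
      }
      out(p, c) = tot ? (double)lab / tot : NA_REAL;
    }
  }
  return out;
}
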