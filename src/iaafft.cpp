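// Iterative amplitude-adjusted Fourier transform surrogate engine.
// Each iteration imposes the original Fourier amplitudes on the current
// phases, then rank-remaps onto the original value multiset; iteration
// stops when the relative spectral mismatch stabilises.  Randomness
// (the initial permutations) comes from R's RNG so set.seed() applies.
//
// FFTs use FFTW real<->complex half-spectrum transforms with plans
// created once per call and reused across iterations and surrogates.

#include <Rcpp.h>
#include <fftw3.h>
#include <algorithm>
#include <cmath>
#include <vector>

// [[Rcpp::export]]
Rcpp::List iaafft_engine(Rcpp::NumericVector x, int n_surr, int max_iter,
                         double tol, bool trace) {
  const int n = x.size();
  const int nh = n / 2 + 1;  // half-spectrum length

  std::vector<double> sx(x.begin(), x.end());
  std::sort(sx.begin(), sx.end());

  std::vector<double> buf(n);
  std::vector<fftw_complex> fbuf(nh);
  fftw_plan fwd = fftw_plan_dft_r2c_1d(n, buf.data(), fbuf.data(),
                                       FFTW_ESTIMATE);
  fftw_plan bwd = fftw_plan_dft_c2r_1d(n, fbuf.data(), buf.data(),
                                       FFTW_ESTIMATE);

  // target amplitude spectrum of x
  std::copy(x.begin(), x.end(), buf.begin());
  fftw_execute(fwd);
  std::vector<double> ax(nh);
  double ax_norm2 = 0.0;
  for (int k = 0; k < nh; ++k) {
    ax[k] = std::hypot(fbuf[k][0], fbuf[k][1]);
    // interior bins represent a conjugate pair in the full spectrum
    double w = (k == 0 || (n % 2 == 0 && k == nh - 1)) ? 1.0 : 2.0;
    ax_norm2 += w * ax[k] * ax[k];
  }
  const double ax_norm = std::sqrt(ax_norm2);

  // initial independent random permutations of x (R RNG)
  Rcpp::NumericMatrix y(n, n_surr);
  for (int j = 0; j < n_surr; ++j) {
    Rcpp::IntegerVector idx = Rcpp::sample(n, n, false);
    for (int i = 0; i < n; ++i) y(i, j) = x[idx[i] - 1];
  }

  std::vector<double> prev(n_surr, R_PosInf), cur(n_surr);
  std::vector<std::vector<double>> hist;
  std::vector<int> ord(n);
  std::vector<double> y2(n);

  for (int it = 0; it <= max_iter; ++it) {
    bool converged = true;
    for (int j = 0; j < n_surr; ++j) {
      double* col = &y(0, j);
      std::copy(col, col + n, buf.begin());
      fftw_execute(fwd);
      double d2 = 0.0;
      for (int k = 0; k < nh; ++k) {
        double m = std::hypot(fbuf[k][0], fbuf[k][1]);
        double w = (k == 0 || (n % 2 == 0 && k == nh - 1)) ? 1.0 : 2.0;
        double d = m - ax[k];
        d2 += w * d * d;
        // impose the original amplitude, keep the current phase
        double scale = (m > 0.0) ? ax[k] / m : 0.0;
        fbuf[k][0] *= scale;
        fbuf[k][1] *= scale;
      }
      cur[j] = std::sqrt(d2) / ax_norm;
      if (!(std::fabs(prev[j] - cur[j]) < tol)) converged = false;
      fftw_execute(bwd);  // unnormalised inverse; order statistics only
      std::copy(buf.begin(), buf.end(), y2.begin());
      // rank remap onto the original value multiset (stable order)
      for (int i = 0; i < n; ++i) ord[i] = i;
      std::stable_sort(ord.begin(), ord.end(),
                       [&](int a, int b) { return y2[a] < y2[b]; });
      for (int i = 0; i < n; ++i) col[ord[i]] = sx[i];
    }
    if (trace) hist.push_back(cur);
    // y always leaves this loop straight after a rank remap, so the
    // value multiset is exact whenever we stop
    if (converged || it == max_iter) break;
    prev = cur;
  }

  fftw_destroy_plan(fwd);
  fftw_destroy_plan(bwd);

  Rcpp::NumericMatrix mm(trace ? hist.size() : 0, trace ? n_surr : 0);
  if (trace)
    for (size_t r = 0; r < hist.size(); ++r)
      for (int j = 0; j < n_surr; ++j) mm(r, j) = hist[r][j];
  return Rcpp::List::create(Rcpp::Named("y") = y,
                            Rcpp::Named("mismatch") = mm);
}
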