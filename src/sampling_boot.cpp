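#include <Rcpp.h>
using namespace Rcpp;

// Rejection sampler for random temporal sampling functions. Draws
// candidate waveforms sum_j a_j sin(w_j t + phi_j) with a ~ U(0,1),
// phi ~ U(0,2*pi), range-normalizes each to [0, 0.5] and keeps draws
// whose frame sum lies within sum_tol of sum_target. Basis matrices
// (n_freq x n_frames, column-major) are precomputed in R; uses R's RNG so
// results are reproducible under set.seed().
// [[Rcpp::export]]
List cpp_sample_functions(int n, NumericMatrix bsin, NumericMatrix bcos,
                          double sum_target, double sum_tol, int max_draws) {
  const int nf = bsin.nrow(), nt = bsin.ncol();
  NumericMatrix vals(n, nt), amps(n, nf), phas(n, nf);
  double* V = REAL(vals);
  double* A = REAL(amps);
  double* P = REAL(phas);
  const double* BS = REAL(bsin);
  const double* BC = REAL(bcos);
  std::vector<double> a(nf), p(nf), ca(nf), sa(nf), w(nt);
  int got = 0, drawn = 0;
  while (got < n) {
    if (drawn >= max_draws)
      stop("redraw budget exhausted: could not find %d sampling functions "
           "with |sum - %f| <= %f", n, sum_target, sum_tol);
    ++drawn;
    for (int j = 0; j < nf; ++j) {
      a[j] = unif_rand();
      p[j] = unif_rand() * 2.0 * M_PI;
      ca[j] = a[j] * std::cos(p[j]);
      sa[j] = a[j] * std::sin(p[j]);
    }
    double lo = R_PosInf, hi = R_NegInf;
    for (int t = 0; t < nt; ++t) {
      const double* bs = BS + (size_t)t * nf;
      const double* bc = BC + (size_t)t * nf;
      double v = 0.0;
      for (int j = 0; j < nf; ++j) v += ca[j] * bs[j] + sa[j] * bc[j];
      w[t] = v;
      if (v < lo) lo = v;
      if (v > hi) hi = v;
    }
    double rng = hi - lo;
    if (rng <= 1e-12) continue;  // degenerate (flat) draw: redraw
    double s = 0.0;
    for (int t = 0; t < nt; ++t) {
      w[t] = (w[t] - lo) / rng * 0.5;
      s += w[t];
    }
    if (std::abs(s - sum_target) > sum_tol) continue;
    for (int t = 0; t < nt; ++t) V[got + (size_t)n * t] = w[t];
    for (int j = 0; j < nf; ++j) {
      A[got + (size_t)n * j] = a[j];
      P[got + (size_t)n * j] = p[j];
    }
    ++got;
  }
  return List::create(_["values"] = vals, _["amplitudes"] = amps,
                      _["phases"] = phas);
}

// Bootstrap null classification images: on each iteration, pair the fixed
// accuracy-label multiset (n_c correct, n_e error slots) with trials drawn
// with replacement from the feature matrix (n x p) and record the
// mean(correct) - mean(error) image. Returns p x n_boot.
// [[Rcpp::export]]
NumericMatrix cpp_boot_images(NumericMatrix feats, int n_c, int n_e,
                              int n_boot) {
  const int n = feats.nrow(), p = feats.ncol();
  NumericMatrix out(p, n_boot);
  double* O = REAL(out);
  const double* F = REAL(feats);
  std::vector<double> acc_c(p), acc_e(p);
  for (int b = 0; b < n_boot; ++b) {
    std::fill(acc_c.begin(), acc_c.end(), 0.0);
    std::fill(acc_e.begin(), acc_e.end(), 0.0);
    for (int i = 0; i < n_c; ++i) {
      int k = (int)(unif_rand() * n); if (k == n) k = n - 1;
      for (int j = 0; j < p; ++j) acc_c[j] += F[k + (size_t)n * j];
    }
    for (int i = 0; i < n_e; ++i) {
      int k = (int)(unif_rand() * n); if (k == n) k = n - 1;
      for (int j = 0; j < p; ++j) acc_e[j] += F[k + (size_t)n * j];
    }
    for (int j = 0; j < p; ++j)
      O[j + (size_t)p * b] = acc_c[j] / n_c - acc_e[j] / n_e;
  }
  return out;
}
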