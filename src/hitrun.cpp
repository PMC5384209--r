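#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Hit-and-run walk in the affine null-space parametrisation of S v = b.
// The state is kept in full flux coordinates x = vp + B y and updated
// incrementally; directions are isotropic in the K-dimensional null space.
// Uses R's RNG so runs are reproducible via set.seed().
// [[Rcpp::export]]
NumericMatrix hr_walk_cpp(NumericMatrix B, NumericVector vp,
                          NumericVector lo, NumericVector hi,
                          NumericVector y0, double nsteps, int n_samples) {
  const int N = B.nrow(), K = B.ncol();
  const double big = 1e9; // effective chord cap for unbounded fluxes
  std::vector<double> x(N);
  for (int i = 0; i < N; i++) {
    double s = vp[i];
    for (int k = 0; k < K; k++) s += B(i, k) * y0[k];
    x[i] = s;
  }
  long long Tn = (long long) nsteps;
  long long stride = Tn / n_samples;
  if (stride < 1) stride = 1;
  NumericMatrix out(n_samples, N);
  int row = 0;
  std::vector<double> w(N), u(K);
  for (long long t = 1; t <= Tn && row < n_samples; t++) {
    double nrm = 0;
    for (int k = 0; k < K; k++) { u[k] = norm_rand(); nrm += u[k] * u[k]; }
    nrm = std::sqrt(nrm);
    if (nrm == 0) continue;
    for (int k = 0; k < K; k++) u[k] /= nrm;
    for (int i = 0; i < N; i++) {
      double s = 0;
      for (int k = 0; k < K; k++) s += B(i, k) * u[k];
      w[i] = s;
    }
    double tmin = -big, tmax = big;
    for (int i = 0; i < N; i++) {
      double wi = w[i];
      if (std::fabs(wi) < 1e-14) continue;
      double t1 = (lo[i] - x[i]) / wi, t2 = (hi[i] - x[i]) / wi;
      if (wi > 0) {
        if (t1 > tmin) tmin = t1;
        if (t2 < tmax) tmax = t2;
      } else {
        if (t2 > tmin) tmin = t2;
        if (t1 < tmax) tmax = t1;
      }
    }
    double step = 0;
    if (tmax > tmin) step = tmin + unif_rand() * (tmax - tmin);
    for (int i = 0; i < N; i++) x[i] += step * w[i];
    if (t % stride == 0 && row < n_samples) {
      for (int i = 0; i < N; i++) out(row, i) = x[i];
      row++;
    }
  }
  for (; row < n_samples; row++)
    for (int i = 0; i < N; i++) out(row, i) = x[i];
  return out;
}
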