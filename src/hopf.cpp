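#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Euler-Maruyama integration of N coupled Stuart-Landau oscillators:
//   dx_n = [(a_n - x_n^2 - y_n^2) x_n - w_n y_n + G sum_p C_np (x_p - x_n)] dt + nu dW
//   dy_n = [(a_n - x_n^2 - y_n^2) y_n + w_n x_n + G sum_p C_np (y_p - y_n)] dt + nu dW
// Noise is drawn from R's RNG so runs are reproducible under set.seed().
// Returns x and y sampled every `stride` steps after `burn_steps`.
// [[Rcpp::export]]
List hopf_integrate_cpp(NumericMatrix C, NumericVector a, NumericVector omega,
                        double G, double nu, double dt,
                        int burn_steps, int n_keep, int stride,
                        NumericVector x0, NumericVector y0) {
  const int N = C.nrow();
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> rowsum(N, 0.0), cx(N), cy(N);
  for (int n = 0; n < N; ++n) {
    double s = 0.0;
    for (int p = 0; p < N; ++p) s += C(n, p);
    rowsum[n] = s;
  }
  NumericMatrix outx(N, n_keep), outy(N, n_keep);
  const double sqdt = std::sqrt(dt);
  const long total = (long)burn_steps + (long)n_keep * stride;
  const bool noisy = nu > 0.0;
  int kept = 0;
  RNGScope scope;
  for (long step = 1; step <= total; ++step) {
    // C is symmetric; accumulate by columns for cache-friendly access
    std::fill(cx.begin(), cx.end(), 0.0);
    std::fill(cy.begin(), cy.end(), 0.0);
    const double *Cd = C.begin();
    for (int p = 0; p < N; ++p) {
      const double xp = x[p], yp = y[p];
      const double *col = Cd + (size_t)p * N;
      for (int n = 0; n < N; ++n) {
        cx[n] += col[n] * xp;
        cy[n] += col[n] * yp;
      }
    }
    for (int n = 0; n < N; ++n) {
      const double r2 = x[n] * x[n] + y[n] * y[n];
      const double dxn = (a[n] - r2) * x[n] - omega[n] * y[n] + G * (cx[n] - rowsum[n] * x[n]);
      const double dyn = (a[n] - r2) * y[n] + omega[n] * x[n] + G * (cy[n] - rowsum[n] * y[n]);
      x[n] += dt * dxn;
      y[n] += dt * dyn;
      if (noisy) {
        x[n] += nu * sqdt * norm_rand();
        y[n] += nu * sqdt * norm_rand();
      }
      if (std::fabs(x[n]) > 1e6 || std::fabs(y[n]) > 1e6) {
        stop("hopf integration diverged (|state| > 1e6) at step %ld; consider a smaller dt", step);
      }
    }
    if (step > burn_steps && (step - burn_steps) % stride == 0) {
      for (int n = 0; n < N; ++n) {
        outx(n, kept) = x[n];
        outy(n, kept) = y[n];
      }
      if (++kept == n_keep) break;
    }
  }
  return List::create(_["x"] = outx, _["y"] = outy);
}
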