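#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Full-memory Adams-Bashforth-Moulton PECE scheme for the Caputo IVP
//   D^theta u(t) = f(t, u),  u(t0) = u0,  0 < theta <= 1,
// on the uniform grid t_j = t0 + j*h, j = 0..n_steps.
//
// Predictor (fractional rectangle rule):
//   u_P(t_{n+1}) = u0 + h^theta/Gamma(theta+1) *
//                  sum_{j=0}^{n} [(n+1-j)^theta - (n-j)^theta] f_j
// Corrector (fractional trapezoid rule, Gamma(theta+2) normalisation):
//   u_{n+1} = u0 + h^theta/Gamma(theta+2) *
//             [ f(t_{n+1}, u_P) + sum_{j=0}^{n} a_{j,n+1} f_j ]
//   a_{0,n+1}   = n^{theta+1} - (n - theta)(n+1)^theta
//   a_{j,n+1}   = (n-j+2)^{theta+1} + (n-j)^{theta+1} - 2 (n-j+1)^{theta+1}
//
// The weights depend on j only through the lag, so the two power sequences
// are precomputed once; each step is then a plain convolution over history.
// Components that dip below zero are clamped to `floor_` (clamps on the
// accepted state are counted; the predictor is clamped silently before f is
// evaluated, so fractional powers of the state never see negative input).

// [[Rcpp::export(name = ".abm_pece")]]
List abm_pece(Function f, NumericVector u0, double theta, double h,
              int n_steps, double t0, int corrector_iters,
              double floor_, bool clamp) {
  const int d = u0.size();
  const int N = n_steps;
  const double t1 = theta + 1.0;
  const double fac_p = std::pow(h, theta) / std::tgamma(theta + 1.0);
  const double fac_c = std::pow(h, theta) / std::tgamma(theta + 2.0);

  // lag-indexed weight tables
  std::vector<double> bw(N + 2), aw(N + 2);
  for (int k = 0; k <= N + 1; ++k) {
    bw[k] = (k == 0) ? 0.0 : std::pow((double)k, theta) -
                               std::pow((double)(k - 1), theta);
    aw[k] = std::pow((double)(k + 2), t1) + std::pow((double)k, t1) -
            2.0 * std::pow((double)(k + 1), t1);
  }

  NumericMatrix u(N + 1, d);      // states, one row per grid point
  std::vector<double> fh((N + 1) * d); // f history, column-major by step
  int clamped = 0;

  for (int c = 0; c < d; ++c) u(0, c) = u0[c];
  {
    NumericVector f0 = f(t0, u0);
    if (f0.size() != d) stop("f must return a vector of length %d", d);
    for (int c = 0; c < d; ++c) fh[c] = f0[c];
  }

  NumericVector upred(d), ucur(d);
  for (int n = 0; n < N; ++n) {
    const double tn1 = t0 + (n + 1) * h;
    // predictor + corrector history sums in one pass
    std::vector<double> sp(d, 0.0), sc(d, 0.0);
    for (int j = 0; j <= n; ++j) {
      const double wb = bw[n + 1 - j];
      const double wa = (j == 0)
        ? std::pow((double)n, t1) - (n - theta) * std::pow((double)(n + 1), theta)
        : aw[n - j];
      const double *fj = &fh[(size_t)j * d];
      for (int c = 0; c < d; ++c) {
        sp[c] += wb * fj[c];
        sc[c] += wa * fj[c];
      }
    }
    for (int c = 0; c < d; ++c) {
      double v = u0[c] + fac_p * sp[c];
      if (clamp && v < 0.0) v = floor_;
      upred[c] = v;
    }
    NumericVector fp = f(tn1, upred);
    bool step_clamped = false;
    for (int it = 0; it < corrector_iters; ++it) {
      step_clamped = false;
      for (int c = 0; c < d; ++c) {
        double v = u0[c] + fac_c * (fp[c] + sc[c]);
        if (clamp && v < 0.0) { v = floor_; step_clamped = true; }
        ucur[c] = v;
        if (!std::isfinite(v))
          stop("non-finite state at step %d (t = %g), component %d",
               n + 1, tn1, c + 1);
      }
      fp = f(tn1, ucur);
    }
    if (step_clamped) ++clamped;
    for (int c = 0; c < d; ++c) {
      u(n + 1, c) = ucur[c];
      fh[(size_t)(n + 1) * d + c] = fp[c];
    }
    if (n % 256 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["states"] = u, _["clamped_count"] = clamped);
}
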