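#include <Rcpp.h>
using namespace Rcpp;

// Activation dynamics du/dt = (c1*e(t-d) + c2) * (e(t-d) - u) integrated
// with the exact update for piecewise-constant excitation:
//   u[k+1] = e[k] + (u[k] - e[k]) * exp(-(c1*e[k] + c2) * dt)
// The excitation is first shifted by the per-muscle electromechanical
// delay d (linear interpolation on the regular frame grid; the pre-frame
// buffer must cover the delay, checked at the R level). u is initialised
// at the delayed excitation of the first frame.
// [[Rcpp::export(name = ".activation_dynamics_cpp")]]
List activation_dynamics_cpp(NumericMatrix E, NumericVector delay,
                             NumericVector c1, NumericVector c2,
                             double dt) {
  const int n = E.nrow(), m = E.ncol();
  NumericMatrix ed(n, m), u(n, m);
  for (int j = 0; j < m; ++j) {
    const double shift = delay[j] / dt;  // in frames
    for (int k = 0; k < n; ++k) {
      double pos = k - shift;
      if (pos <= 0.0) {
        ed(k, j) = E(0, j);
      } else {
        int i0 = (int)std::floor(pos);
        if (i0 >= n - 1) {
          ed(k, j) = E(n - 1, j);
        } else {
          double w = pos - i0;
          ed(k, j) = (1.0 - w) * E(i0, j) + w * E(i0 + 1, j);
        }
      }
    }
    u(0, j) = ed(0, j);
    for (int k = 0; k < n - 1; ++k) {
      double e = ed(k, j);
      double rate = c1[j] * e + c2[j];
      u(k + 1, j) = e + (u(k, j) - e) * std::exp(-rate * dt);
    }
  }
  return List::create(Named("delayed") = ed, Named("u") = u);
}
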