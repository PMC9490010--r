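#include <Rcpp.h>
using namespace Rcpp;

// Full forward chain for one trial with the package's default Hill curve
// family (Gaussian active force-length, Hill hyperbola force-velocity
// with C1 eccentric branch, exponential passive): excitation scaling and
// clamping, delayed activation dynamics (exact piecewise-constant
// update), parametric activation nonlinearity, rigid-tendon fiber
// kinematics, muscle forces, and net joint moments. Custom curve sets
// take the equivalent R path instead (see .forward_from_kinematics).
// [[Rcpp::export(name = ".forward_chain_cpp")]]
List forward_chain_cpp(NumericMatrix E, NumericVector semg,
                       NumericVector delay, NumericVector c1,
                       NumericVector c2, NumericVector c3,
                       NumericVector g, NumericMatrix lmt,
                       NumericMatrix vmt, NumericVector r,
                       NumericVector lo, NumericVector ls,
                       NumericVector fmax, NumericVector cosa,
                       double dt, double fl_gamma) {
  const int n = E.nrow(), m = E.ncol();
  IntegerVector rdim = r.attr("dim");
  const int nd = rdim[2];
  NumericMatrix u(n, m), a(n, m), F(n, m), M(n, nd);
  const double g1 = g[0], g3 = g[2], g4 = g[3], g5 = g[4];
  const double lg2 = std::log(g[1]);
  const bool g4_is_2 = g4 == 2.0;
  std::vector<double> e(n), ed(n);
  for (int j = 0; j < m; ++j) {
    for (int k = 0; k < n; ++k) {
      double v = E(k, j) * semg[j];
      e[k] = v < 0.0 ? 0.0 : (v > 1.0 ? 1.0 : v);
    }
    const double shift = delay[j] / dt;
    for (int k = 0; k < n; ++k) {
      double pos = k - shift;
      if (pos <= 0.0) {
        ed[k] = e[0];
      } else {
        int i0 = (int)std::floor(pos);
        if (i0 >= n - 1) {
          ed[k] = e[n - 1];
        } else {
          double w = pos - i0;
          ed[k] = (1.0 - w) * e[i0] + w * e[i0 + 1];
        }
      }
    }
    u(0, j) = ed[0];
    for (int k = 0; k < n - 1; ++k) {
      double rate = c1[j] * ed[k] + c2[j];
      u(k + 1, j) = ed[k] + (u(k, j) - ed[k]) * std::exp(-rate * dt);
    }
    const double invlo = 1.0 / lo[j];
    for (int k = 0; k < n; ++k) {
      double uu = u(k, j);
      double ug = uu + g3;
      double expnt = g4_is_2 ? ug * ug : std::pow(ug, g4);
      double bracket = g1 * std::exp(lg2 * expnt) + g5 + 1.0;
      double aa = (1.0 - c3[j]) * uu + c3[j] * bracket;
      a(k, j) = aa;
      double l = (lmt(k, j) - ls[j]) * invlo;
      double v = vmt(k, j) * invlo * 0.1;
      double fl = std::exp(-(l - 1.0) * (l - 1.0) / fl_gamma);
      double fv;
      if (v < 0.0) {
        double num = 1.0 + (v < -1.0 ? -1.0 : v);
        fv = (num < 0.0 ? 0.0 : num) / (1.0 - 4.0 * v);
      } else {
        fv = 1.0 + 0.4 * v / (v + 0.08);
      }
      double fp = l > 1.0 ? std::expm1(4.0 * (l - 1.0)) / std::expm1(2.8)
                          : 0.0;
      F(k, j) = fmax[j] * (aa * fl * fv + fp) * cosa[j];
    }
  }
  const double* rp = r.begin();
  for (int d = 0; d < nd; ++d)
    for (int j = 0; j < m; ++j) {
      const double* col = rp + (size_t)d * n * m + (size_t)j * n;
      for (int k = 0; k < n; ++k) M(k, d) += F(k, j) * col[k];
    }
  return List::create(Named("u") = u, Named("a") = a, Named("F") = F,
                      Named("M") = M);
}
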