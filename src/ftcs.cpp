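#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Explicit FTCS update for the coupled cooperator/defector system in species
// form: u_t = D u_xx + reaction, 4-point stencil, reflecting (no-flux) ghost
// cells.  The reaction terms are the parametric law family: cubic Allee
// growth with linearly frequency-dependent g0, K, nstar and linear
// frequency-dependent selection with a (possibly smoothed) density step in
// the preferred defector frequency.  When `nonviable` is set, defectors are
// removed wherever the total density is below n_c (the exactly solvable
// special case).

static inline double fstar_at(double n, double f_high, double f_low,
                              double n_c, double eps) {
  if (eps > 0.0)
    return f_low + (f_high - f_low) / (1.0 + std::exp(-(n - n_c) / eps));
  return (n >= n_c) ? f_high : f_low;
}

// [[Rcpp::export]]
List ftcs_advance_cd(NumericVector c_in, NumericVector d_in, int steps,
                     double dx, double dt, double D,
                     double g0, double K, double nstar,
                     double nstar_slope, double K_slope, double g0_slope,
                     double s, double f_high, double f_low, double n_c,
                     double smooth_eps, bool nonviable, double clip_tol) {
  const int nx = c_in.size();
  std::vector<double> c(c_in.begin(), c_in.end());
  std::vector<double> d(d_in.begin(), d_in.end());
  std::vector<double> cn(nx), dn(nx);
  const double idx2 = D / (dx * dx);
  bool bad = false;
  int bad_step = -1;

  for (int step = 0; step < steps && !bad; ++step) {
    for (int i = 0; i < nx; ++i) {
      const int im = (i == 0) ? 0 : i - 1;
      const int ip = (i == nx - 1) ? nx - 1 : i + 1;
      const double ci = c[i], di = d[i];
      const double lap_c = idx2 * (c[im] - 2.0 * ci + c[ip]);
      const double lap_d = idx2 * (d[im] - 2.0 * di + d[ip]);
      const double n = ci + di;
      double rc = 0.0, rd = 0.0;
      if (n > 0.0) {
        const double f = di / n;
        const double Kf = K + K_slope * f;
        const double g0f = g0 + g0_slope * f;
        const double nsf = nstar + nstar_slope * f;
        const double g = g0f * (1.0 - n / Kf) * (n / Kf - nsf / Kf);
        const double w = s * (fstar_at(n, f_high, f_low, n_c, smooth_eps) - f);
        rc = ci * (g - f * w);
        rd = di * (g + (1.0 - f) * w);
      }
      cn[i] = ci + dt * (lap_c + rc);
      dn[i] = di + dt * (lap_d + rd);
    }
    for (int i = 0; i < nx; ++i) {
      double ci = cn[i], di = dn[i];
      if (ci < 0.0) { if (ci > -clip_tol) ci = 0.0; else { bad = true; } }
      if (di < 0.0) { if (di > -clip_tol) di = 0.0; else { bad = true; } }
      if (!std::isfinite(ci) || !std::isfinite(di)) bad = true;
      if (nonviable && ci + di < n_c) di = 0.0;
      c[i] = ci; d[i] = di;
    }
    if (bad) bad_step = step;
  }
  return List::create(_["c"] = NumericVector(c.begin(), c.end()),
                      _["d"] = NumericVector(d.begin(), d.end()),
                      _["blowup"] = bad, _["bad_step"] = bad_step);
}

// Same dynamics in density-frequency form (validation path):
//   n_t = D n_xx + n g(n,f)
//   f_t = D f_xx + 2 D (n_x / n) f_x + f (1 - f) w(n,f)
// The mixed gradient term is the advection generated by migration down
// density gradients; it is evaluated with centered differences and switched
// off where n is numerically zero.
// [[Rcpp::export]]
List ftcs_advance_nf(NumericVector n_in, NumericVector f_in, int steps,
                     double dx, double dt, double D,
                     double g0, double K, double nstar,
                     double nstar_slope, double K_slope, double g0_slope,
                     double s, double f_high, double f_low, double n_c,
                     double smooth_eps, bool nonviable, double clip_tol,
                     double n_floor) {
  const int nx = n_in.size();
  std::vector<double> n(n_in.begin(), n_in.end());
  std::vector<double> f(f_in.begin(), f_in.end());
  std::vector<double> nn(nx), fn(nx);
  const double idx2 = D / (dx * dx);
  bool bad = false;
  int bad_step = -1;

  for (int step = 0; step < steps && !bad; ++step) {
    for (int i = 0; i < nx; ++i) {
      const int im = (i == 0) ? 0 : i - 1;
      const int ip = (i == nx - 1) ? nx - 1 : i + 1;
      const double ni = n[i], fi = f[i];
      const double lap_n = idx2 * (n[im] - 2.0 * ni + n[ip]);
      const double lap_f = idx2 * (f[im] - 2.0 * fi + f[ip]);
      double gn = 0.0, gf = 0.0, adv = 0.0;
      if (ni > 0.0) {
        const double Kf = K + K_slope * fi;
        const double g0f = g0 + g0_slope * fi;
        const double nsf = nstar + nstar_slope * fi;
        const double g = g0f * (1.0 - ni / Kf) * (ni / Kf - nsf / Kf);
        const double w = s * (fstar_at(ni, f_high, f_low, n_c, smooth_eps) - fi);
        gn = ni * g;
        gf = fi * (1.0 - fi) * w;
        if (ni > n_floor) {
          const double nx_grad = (n[ip] - n[im]) / (2.0 * dx);
          const double fx_grad = (f[ip] - f[im]) / (2.0 * dx);
          adv = 2.0 * D * (nx_grad / ni) * fx_grad;
        }
      }
      nn[i] = ni + dt * (lap_n + gn);
      fn[i] = fi + dt * (lap_f + adv + gf);
    }
    for (int i = 0; i < nx; ++i) {
      double ni = nn[i], fi = fn[i];
      if (ni < 0.0) { if (ni > -clip_tol) ni = 0.0; else bad = true; }
      if (fi < 0.0) { if (fi > -clip_tol) fi = 0.0; else bad = true; }
      if (fi > 1.0) { if (fi < 1.0 + clip_tol) fi = 1.0; else bad = true; }
      if (!std::isfinite(ni) || !std::isfinite(fi)) bad = true;
      if (nonviable && ni < n_c) fi = 0.0;
      n[i] = ni; f[i] = fi;
    }
    if (bad) bad_step = step;
  }
  return List::create(_["n"] = NumericVector(n.begin(), n.end()),
                      _["f"] = NumericVector(f.begin(), f.end()),
                      _["blowup"] = bad, _["bad_step"] = bad_step);
}
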