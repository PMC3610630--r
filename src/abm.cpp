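#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Individual-based lattice simulator.  One time step = one possible
// migration event and one possible reproduction-or-death event at every
// site, sites swept left to right; N time steps make one generation.
//
// Migration: with probability m * n_i / N one organism, chosen uniformly
// among the residents of site i, moves to a uniformly chosen neighbor
// (reflecting at the habitat ends), so that the expected per-generation
// flux is m * n / 2 each way and the continuum limit is diffusion with
// D = m / 2 (site spacings squared per generation).
//
// Demography: with local density rho = n / N and Allee fraction
// rho* = nstar(f) (in units of the per-site capacity),
//   P(birth) = g0 (1 + rho*) rho^2,   P(death) = g0 (rho^3 + rho* rho),
// whose difference g0 rho (1 - rho)(rho - rho*) per step reproduces the
// cubic Allee drift with unit carrying capacity when time is measured in
// generations.  A death removes a uniformly chosen resident.  A birth is a
// cooperator with the payoff-share probability
//   P(C) = (1-f) piC / ((1-f) piC + f piD)
// built from the 2x2 interaction matrix A(n) with entries
//   A_CC = A_CD = 1,  A_DC = 1 + s fstar(n),  A_DD = 1 - s (1 - fstar(n)),
// which mimics linear frequency-dependent selection with density-dependent
// preferred frequency fstar(n); payoffs are floored at zero.

static inline double fstar_step(double rho, double f_high, double f_low,
                                double n_c) {
  return (rho >= n_c) ? f_high : f_low;
}

// [[Rcpp::export]]
List abm_advance(IntegerVector coop_in, IntegerVector def_in, int steps,
                 int N, double m, double g0, double nstar,
                 double nstar_slope, double s, double f_high, double f_low,
                 double n_c, bool nonviable) {
  const int ns = coop_in.size();
  std::vector<int> C(coop_in.begin(), coop_in.end());
  std::vector<int> Dd(def_in.begin(), def_in.end());
  RNGScope scope;

  for (int step = 0; step < steps; ++step) {
    // migration sweep
    for (int i = 0; i < ns; ++i) {
      const int n = C[i] + Dd[i];
      if (n == 0) continue;
      if (unif_rand() < m * (double)n / (double)N) {
        int j = (unif_rand() < 0.5) ? i - 1 : i + 1;
        if (j < 0) j = 1;              // reflecting ends
        if (j >= ns) j = ns - 2;
        if (ns == 1) continue;
        // move one uniformly chosen resident
        if (unif_rand() * n < (double)C[i]) { --C[i]; ++C[j]; }
        else { --Dd[i]; ++Dd[j]; }
      }
    }
    // demographic sweep
    for (int i = 0; i < ns; ++i) {
      const int n = C[i] + Dd[i];
      if (n == 0) continue;
      const double rho = (double)n / (double)N;
      const double f = (double)Dd[i] / (double)n;
      const double rstar = nstar + nstar_slope * f;
      double pb = g0 * (1.0 + rstar) * rho * rho;
      double pd = g0 * (rho * rho * rho + rstar * rho);
      if (pb < 0.0) pb = 0.0;
      if (pd < 0.0) pd = 0.0;
      // death has priority in the (rarely reached) far-above-capacity tail
      if (pd > 1.0) pd = 1.0;
      if (pb > 1.0 - pd) pb = 1.0 - pd;
      const double u = unif_rand();
      if (u < pb) {
        const double fst = fstar_step(rho, f_high, f_low, n_c);
        const double piC = 1.0;                 // A_CC (1-f) + A_CD f
        double piD = (1.0 + s * fst) * (1.0 - f)
                   + (1.0 - s * (1.0 - fst)) * f;
        if (piD < 0.0) piD = 0.0;
        const double wc = (1.0 - f) * piC, wd = f * piD;
        const double pc = (wc + wd > 0.0) ? wc / (wc + wd) : 1.0;
        if (unif_rand() < pc) ++C[i]; else ++Dd[i];
      } else if (u < pb + pd) {
        if (unif_rand() * n < (double)C[i]) { if (C[i] > 0) --C[i]; }
        else { if (Dd[i] > 0) --Dd[i]; }
      }
      if (nonviable && (double)(C[i] + Dd[i]) / (double)N < n_c) Dd[i] = 0;
    }
  }
  return List::create(_["coop"] = IntegerVector(C.begin(), C.end()),
                      _["def"] = IntegerVector(Dd.begin(), Dd.end()));
}
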