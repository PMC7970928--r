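#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Minimum arrival time of each player to each target under the
// damped-acceleration motion model.
//
// The reachable set at time t is a disc centred on the drift point
//   c(t) = x0 + s(t) v0,            s(t) = (1 - exp(-alpha t)) / alpha
// with radius
//   r(t) = vmax (t - s(t)).
// The arrival time is the FIRST root of
//   g(t) = || target - c(t) || - r(t),
// located by a forward scan of step `dt` (g need not be monotone when the
// initial velocity points away from the target, so a plain bracketing
// solver from t = 0 could skip the first crossing) and refined by
// bisection to `tol` seconds.
//
// Returns an n_players x n_targets matrix of seconds; NA when no crossing
// occurs before `tmax` (absurd inputs). Targets closer than `pos_tol`
// metres to the player's position give 0.
// [[Rcpp::export]]
NumericMatrix arrival_times_cpp(NumericVector px, NumericVector py,
                                NumericVector vx, NumericVector vy,
                                NumericVector tx, NumericVector ty,
                                NumericVector vmax, NumericVector alpha,
                                double dt, double tmax, double tol,
                                double pos_tol) {
  const int np = px.size();
  const int nt = tx.size();
  const int nstep = (int) std::ceil(tmax / dt);
  NumericMatrix out(np, nt);

  std::vector<double> sv(nstep + 1), rv(nstep + 1);

  for (int p = 0; p < np; ++p) {
    const double a = alpha[p], vm = vmax[p];
    const double pxp = px[p], pyp = py[p], vxp = vx[p], vyp = vy[p];
    // drift fraction and sprint radius tabulated once per player
    for (int i = 0; i <= nstep; ++i) {
      const double t = i * dt;
      const double s = (1.0 - std::exp(-a * t)) / a;
      sv[i] = s;
      rv[i] = vm * (t - s);
    }
    const double speed0 = std::sqrt(vxp * vxp + vyp * vyp);
    for (int j = 0; j < nt; ++j) {
      const double dx0 = tx[j] - pxp, dy0 = ty[j] - pyp;
      const double d0 = std::sqrt(dx0 * dx0 + dy0 * dy0);
      if (d0 < pos_tol) {
        out(p, j) = 0.0;
        continue;
      }
      // no crossing is possible while vm * t < d0 - |v0| / alpha, because
      // r(t) <= vm t and the drift point moves at most |v0|/alpha metres;
      // skip that provably positive stretch of g
      int i0 = (int) std::floor(((d0 - speed0 / a) / vm) / dt);
      if (i0 < 0) i0 = 0;
      if (i0 > nstep) i0 = nstep;
      double res = NA_REAL;
      double tlo = i0 * dt;
      for (int i = i0 + 1; i <= nstep; ++i) {
        const double cx = pxp + sv[i] * vxp, cy = pyp + sv[i] * vyp;
        const double ddx = tx[j] - cx, ddy = ty[j] - cy;
        const double g = std::sqrt(ddx * ddx + ddy * ddy) - rv[i];
        if (g <= 0.0) {
          double lo = tlo, hi = i * dt;
          while (hi - lo > tol) {
            const double mid = 0.5 * (lo + hi);
            const double s = (1.0 - std::exp(-a * mid)) / a;
            const double mdx = tx[j] - (pxp + s * vxp);
            const double mdy = ty[j] - (pyp + s * vyp);
            const double gm = std::sqrt(mdx * mdx + mdy * mdy) - vm * (mid - s);
            if (gm <= 0.0) hi = mid; else lo = mid;
          }
          res = 0.5 * (lo + hi);
          break;
        }
        tlo = i * dt;
      }
      out(p, j) = res;
    }
  }
  return out;
}
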