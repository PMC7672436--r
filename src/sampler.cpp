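// Overdamped Langevin (Euler-Maruyama) sampler on the analytic model
// surfaces, with an optional ABF-like adaptive bias accumulated on a grid.
// All random numbers are pre-generated in R so trajectories are exactly
// reproducible from the R-side seed.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Surface {
  int dims;
  double x0, y0, cx, cy, asym, tau;
  NumericMatrix wells; // columns: x, y, depth, wx, wy

  void grad(double x, double y, double &gx, double &gy) const {
    double th = std::tanh((x - x0) / tau);
    double ax = 1.0 + asym * (1.0 - th) / 2.0;
    double dax = -asym * (1.0 - th * th) / (2.0 * tau);
    gx = cx * (2.0 * (x - x0) * ax + (x - x0) * (x - x0) * dax);
    gy = 2.0 * cy * (y - y0);
    for (int i = 0; i < wells.nrow(); ++i) {
      double dx = x - wells(i, 0), dy = y - wells(i, 1);
      double wx2 = wells(i, 3) * wells(i, 3), wy2 = wells(i, 4) * wells(i, 4);
      double e = std::exp(-(dx * dx / (2.0 * wx2) + dy * dy / (2.0 * wy2)));
      gx += wells(i, 2) * e * dx / wx2;
      gy += wells(i, 2) * e * dy / wy2;
    }
  }
};

// reflect into [lo, hi]
inline double reflect(double x, double lo, double hi) {
  double span = hi - lo;
  for (int it = 0; it < 64 && (x < lo || x > hi); ++it) {
    if (x < lo) x = 2.0 * lo - x;
    if (x > hi) x = 2.0 * hi - x;
  }
  if (x < lo) x = lo;
  if (x > hi) x = hi;
  return x;
}

inline double wrap(double x, double lo, double hi) {
  double span = hi - lo;
  double t = (x - lo) / span;
  return lo + (t - std::floor(t)) * span;
}

inline int bin_of(double v, double lo, double hi, int nb, bool periodic) {
  if (periodic) v = wrap(v, lo, hi);
  if (v < lo || v > hi) return -1;
  int i = (int)std::floor((v - lo) / ((hi - lo) / nb));
  if (i == nb) i = nb - 1;
  return (i < 0 || i >= nb) ? -1 : i;
}

} // namespace

// [[Rcpp::export(name = ".langevin_cpp")]]
List langevin_cpp(int n_steps, NumericVector x0, NumericVector h, double RT,
                  List surf, NumericVector dom_min, NumericVector dom_max,
                  LogicalVector periodic,
                  bool abf, NumericVector grid_min, NumericVector grid_max,
                  IntegerVector grid_nbins, int n_ramp,
                  NumericMatrix noise_motion, NumericMatrix noise_force,
                  double force_sd, double force_ar1,
                  IntegerVector abf_n, NumericMatrix abf_sum,
                  int stride) {
  Surface S;
  S.dims = as<int>(surf["dims"]);
  S.x0 = as<double>(surf["x0"]); S.y0 = as<double>(surf["y0"]);
  S.cx = as<double>(surf["cx"]); S.cy = as<double>(surf["cy"]);
  S.asym = as<double>(surf["asym"]); S.tau = as<double>(surf["tau"]);
  S.wells = as<NumericMatrix>(surf["wells"]);
  const int d = S.dims;
  const int n_rec = n_steps / stride;
  NumericMatrix values(n_rec, d), forces(n_rec, d);

  std::vector<double> x(d), eta(d, 0.0), g(2), fb(2);
  for (int k = 0; k < d; ++k) x[k] = x0[k];
  const double ar_w = std::sqrt(1.0 - force_ar1 * force_ar1);
  int rec = 0;
  const int nb0 = abf ? grid_nbins[0] : 0;

  for (int t = 0; t < n_steps; ++t) {
    double gx = 0, gy = 0;
    S.grad(x[0], d == 2 ? x[1] : S.y0, gx, gy);
    g[0] = gx; g[1] = gy;
    // instantaneous generalized force: -grad V plus AR(1) noise
    double f[2];
    for (int k = 0; k < d; ++k) {
      eta[k] = force_ar1 * eta[k] + ar_w * force_sd * noise_force(t, k);
      f[k] = -g[k] + eta[k];
    }
    // ABF bias: cancel the running mean force estimate (ramped)
    int bidx = -1;
    if (abf) {
      int i0 = bin_of(x[0], grid_min[0], grid_max[0], grid_nbins[0], periodic[0]);
      int i1 = 0;
      if (d == 2)
        i1 = bin_of(x[1], grid_min[1], grid_max[1], grid_nbins[1], periodic[1]);
      if (i0 >= 0 && i1 >= 0) bidx = i1 * nb0 + i0;
    }
    fb[0] = 0; fb[1] = 0;
    if (bidx >= 0) {
      int nsam = abf_n[bidx];
      if (nsam > 0) {
        double ramp = nsam >= n_ramp ? 1.0 : (double)nsam / n_ramp;
        for (int k = 0; k < d; ++k) fb[k] = -ramp * abf_sum(bidx, k) / nsam;
      }
      abf_n[bidx] = nsam + 1;
      for (int k = 0; k < d; ++k) abf_sum(bidx, k) += f[k];
    }
    if (t % stride == 0) {
      for (int k = 0; k < d; ++k) {
        values(rec, k) = x[k];
        forces(rec, k) = f[k];
      }
      ++rec;
    }
    for (int k = 0; k < d; ++k) {
      double drift = h[k] * (-g[k] + fb[k]);
      double step = drift + std::sqrt(2.0 * RT * h[k]) * noise_motion(t, k);
      double span = dom_max[k] - dom_min[k];
      if (std::fabs(step) > span / 2.0)
        stop("step size too large: single-step displacement %f exceeds half the domain span in dimension %d at step %d", step, k + 1, t + 1);
      double xn = x[k] + step;
      x[k] = periodic[k] ? wrap(xn, dom_min[k], dom_max[k])
                         : reflect(xn, dom_min[k], dom_max[k]);
    }
  }
  return List::create(_["values"] = values, _["forces"] = forces,
                      _["abf_n"] = abf_n, _["abf_sum"] = abf_sum);
}
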