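#include <Rcpp.h>
#include <cmath>

// Overdamped Brownian dynamics of a point particle in the radial drift
// field v_r(r) = -(a2/r^2 + a3/r^3), full 3D positions (no Jacobian
// correction needed), Euler-Maruyama stepping with R's RNG.
//
// Time step adaptivity: far from both boundaries the step is enlarged so
// that a 6-sigma diffusive displacement still cannot reach the nearest
// boundary; within the near-boundary zone the base dt is used, so boundary
// contacts are always resolved at the base resolution and the partially
// reflecting (Robin) absorption probability k*sqrt(pi*dt/D) stays
// consistent with the dt in force at contact.

namespace {

struct Field {
  double a2, a3, D;
  inline double vr(double r) const { return -(a2 / (r * r) + a3 / (r * r * r)); }
};

// One walker: returns +1 if absorbed at r_e, 0 if it reached r_out.
int walk(const Field& f, double re, double rout, double rstart,
         double dt, double pabs, long max_steps) {
  const double sigma2 = 2.0 * f.D;          // per-coordinate variance / dt
  // start on the z-axis; the problem is isotropic
  double x = 0.0, y = 0.0, z = rstart;
  double r = rstart;
  for (long step = 0; step < max_steps; ++step) {
    double gap_in = r - re;
    double gap_out = rout - r;
    double gap = gap_in < gap_out ? gap_in : gap_out;
    double dtl = dt;
    if (gap > 0.0) {
      // allow larger steps when 6 sqrt(6 D dtl) < gap (3D displacement)
      double dt_big = gap * gap / (36.0 * 6.0 * f.D);
      if (dt_big > dtl) dtl = dt_big;
    }
    // keep the drift displacement under control as well
    double v = f.vr(r);
    double vmag = std::fabs(v);
    if (vmag > 0.0) {
      double dt_drift = 0.5 * (gap > 10.0 * re ? gap : 0.1 * re) / vmag;
      if (dt_drift < dt) dt_drift = dt;     // never below base resolution
      if (dtl > dt_drift) dtl = dt_drift;
    }
    double sd = std::sqrt(sigma2 * dtl);
    double ux = x / r, uy = y / r, uz = z / r;
    x += v * ux * dtl + sd * R::norm_rand();
    y += v * uy * dtl + sd * R::norm_rand();
    z += v * uz * dtl + sd * R::norm_rand();
    r = std::sqrt(x * x + y * y + z * z);
    if (r <= re) {
      if (pabs >= 1.0 || R::unif_rand() < pabs) return 1;
      // specular (radial) reflection off the inner sphere
      double rnew = 2.0 * re - r;
      if (rnew <= 0.0) rnew = 1e-3 * re;
      double scale = rnew / r;
      x *= scale; y *= scale; z *= scale;
      r = rnew;
      if (r >= rout) return 0;
    } else if (r >= rout) {
      return 0;
    }
  }
  Rcpp::stop("walker exceeded max_steps; decrease dt or domain size");
  return 0;  // not reached
}

}  // namespace

// [[Rcpp::export(name = ".bd_splitting_cpp")]]
Rcpp::List bd_splitting_cpp(double a2, double a3, double D,
                            double re, double rout, double rstart,
                            double dt, double pabs, int n,
                            double max_steps) {
  Field f{a2, a3, D};
  int captured = 0;
  long ms = static_cast<long>(max_steps);
  for (int i = 0; i < n; ++i) {
    captured += walk(f, re, rout, rstart, dt, pabs, ms);
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(Rcpp::Named("captured") = captured,
                            Rcpp::Named("n") = n);
}

// Capture-rate estimator: walkers injected at r_inj; reaching r_far they
// either escape for good or are re-injected at r_inj with the analytic
// return probability p_return (computed in R from the same potential).
// [[Rcpp::export(name = ".bd_capture_cpp")]]
Rcpp::List bd_capture_cpp(double a2, double a3, double D,
                          double re, double rinj, double rfar,
                          double p_return, double dt, double pabs, int n,
                          double max_steps) {
  Field f{a2, a3, D};
  int captured = 0;
  long ms = static_cast<long>(max_steps);
  for (int i = 0; i < n; ++i) {
    for (;;) {
      int res = walk(f, re, rfar, rinj * (1.0 - 1e-12), dt, pabs, ms);
      if (res == 1) { ++captured; break; }
      if (R::unif_rand() >= p_return) break;  // escaped to infinity
      // else re-injected at rinj and the walk continues
    }
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(Rcpp::Named("captured") = captured,
                            Rcpp::Named("n") = n);
}
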