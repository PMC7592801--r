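#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Normalized Hill curves. Fiber velocity is dl_fiber/dt: negative while
// shortening. All lengths normalized by l_opt, velocities by l_opt/s.

namespace {

struct Curves {
  double af, ecc_max, k_ecc, e0_t, k_t, e0_pe, k_pe, fl_floor, a_min, beta;
  double ln_floor; // log(fl_floor), Gaussian shape factor
};

inline double active_fl(double ln, double width, const Curves &c) {
  double z = (ln - 1.0) / width;
  return std::exp(c.ln_floor * z * z);
}

// exponential toe with C1 linear extrapolation beyond 4x the reference
// strain (guards against overflow in pathological transients)
inline double toe_curve(double e, double k) {
  const double e_lin = 4.0;
  double den = std::exp(k) - 1.0;
  if (e <= 0.0) return 0.0;
  if (e <= e_lin) return (std::exp(k * e) - 1.0) / den;
  double f0 = (std::exp(k * e_lin) - 1.0) / den;
  double s = k * std::exp(k * e_lin) / den;
  return f0 + s * (e - e_lin);
}

inline double passive_f(double ln, const Curves &c) {
  return toe_curve((ln - 1.0) / c.e0_pe, c.k_pe);
}

inline double tendon_f(double strain, const Curves &c) {
  return toe_curve(strain / c.e0_t, c.k_t);
}

// force-velocity multiplier for normalized velocity vn (l_opt/s) given v_max
inline double force_velocity(double vn, double vmax, const Curves &c) {
  if (vn <= 0.0) { // shortening branch (Hill hyperbola)
    if (vn <= -vmax) return 0.0;
    return (vmax + vn) / (vmax - vn / c.af);
  }
  return c.ecc_max - (c.ecc_max - 1.0) * std::exp(-c.k_ecc * vn / vmax);
}

inline double force_velocity_deriv(double vn, double vmax, const Curves &c) {
  if (vn <= 0.0) {
    if (vn <= -vmax) return 0.0;
    double den = vmax - vn / c.af;
    return vmax * (1.0 + 1.0 / c.af) / (den * den);
  }
  return (c.ecc_max - 1.0) * (c.k_ecc / vmax) *
         std::exp(-c.k_ecc * vn / vmax);
}

struct MusclePar {
  double f_max, l_opt, l_slack, penn_opt, v_max, width;
  double h; // constant fiber thickness l_opt * sin(penn_opt)
};

// pennation from constant-thickness assumption
inline void pennation(double lf, const MusclePar &p, double &cosp,
                      double &sinp) {
  double s = p.h / std::max(lf, 1e-6);
  if (s > 0.99) s = 0.99;
  sinp = s;
  cosp = std::sqrt(1.0 - s * s);
}

// rigid-tendon fiber length from muscle-tendon length
inline double rigid_fiber_length(double lmt, const MusclePar &p) {
  double along = lmt - p.l_slack;
  double lf = std::sqrt(along * along + p.h * p.h);
  return std::max(lf, 0.01 * p.l_opt);
}

// equilibrium fiber velocity (m/s) at state lf given activation and lmt.
// The fiber carries a small damper in parallel with the contractile
// element (damped-equilibrium formulation), so the velocity solves the
// smooth, strictly monotone residual
//   a fl fv(vn) + beta vn / v_max + f_pe - f_tendon / cos(penn) = 0
// by safeguarded Newton iteration; no hard force-velocity clamps remain.
inline double fiber_velocity(double a, double lmt, double lf,
                             const MusclePar &p, const Curves &c) {
  double cosp, sinp;
  pennation(lf, p, cosp, sinp);
  double lt = lmt - lf * cosp;
  double ft = tendon_f(lt / p.l_slack - 1.0, c);          // normalized
  double ln = lf / p.l_opt;
  double fpe = passive_f(ln, c);
  double fl = active_fl(ln, p.width, c);
  double a_eff = std::max(a, c.a_min);
  double afl = a_eff * std::max(fl, 1e-6);
  double rhs = ft / cosp - fpe;
  double vmax = p.v_max;
  // bracket the root of g(vn) = afl*fv(vn) + beta*vn/vmax - rhs
  double lo = -2.0 * vmax, hi = 2.0 * vmax;
  while (afl * force_velocity(lo, vmax, c) + c.beta * lo / vmax > rhs)
    lo *= 2.0;
  while (afl * force_velocity(hi, vmax, c) + c.beta * hi / vmax < rhs)
    hi *= 2.0;
  double vn = 0.0;
  if (vn < lo || vn > hi) vn = 0.5 * (lo + hi);
  for (int it = 0; it < 30; ++it) {
    double g = afl * force_velocity(vn, vmax, c) + c.beta * vn / vmax - rhs;
    if (g > 0) hi = vn; else lo = vn;
    double dg = afl * force_velocity_deriv(vn, vmax, c) + c.beta / vmax;
    double step = g / dg;
    double vn_new = vn - step;
    if (vn_new <= lo || vn_new >= hi) vn_new = 0.5 * (lo + hi);
    if (std::fabs(vn_new - vn) < 1e-10 * vmax) { vn = vn_new; break; }
    vn = vn_new;
  }
  // wide safety cap, far outside the physiological operating range; it
  // only limits start-up transients
  if (vn > 3.0 * vmax) vn = 3.0 * vmax;
  if (vn < -3.0 * vmax) vn = -3.0 * vmax;
  return vn * p.l_opt;
}

// contractile-element force including the parallel damper, N (normalized)
inline double ce_force(double a, double fl, double vn, double vmax,
                       const Curves &c) {
  return a * fl * force_velocity(vn, vmax, c) + c.beta * vn / vmax;
}

inline double lerp(const NumericVector &x, double t) {
  // t in sample units (0-based, fractional)
  int n = x.size();
  if (t <= 0) return x[0];
  if (t >= n - 1) return x[n - 1];
  int i = (int)t;
  double w = t - i;
  return x[i] * (1.0 - w) + x[i + 1] * w;
}

} // namespace

//' @name hill_integrate_cpp
//' @title Low-level fixed-step integration of the equilibrium muscle model
//' @param activation,lmt aligned series (activation in 0-1, lmt in m)
//' @param dt sample interval, s
//' @param substeps RK4 substeps per sample interval
//' @param par list of muscle parameters
//' @param curves list of Hill-curve constants
//' @param rigid_tendon if true, the fiber length is slaved to lmt
//' @param lf0 initial fiber length, m (ignored when rigid)
//' @return matrix with columns lf, vf, act, f_ce, f_pe, f_tendon, cos_penn,
//'   residual (force-equilibrium residual, N)
//' @keywords internal
// [[Rcpp::export]]
NumericMatrix hill_integrate_cpp(NumericVector activation, NumericVector lmt,
                                 double dt, int substeps, List par,
                                 List curves, bool rigid_tendon, double lf0) {
  int n = activation.size();
  if (lmt.size() != n) stop("activation and lmt must have equal length");
  if (n < 2) stop("need at least two samples");
  if (dt <= 0) stop("dt must be positive");
  if (substeps < 1) substeps = 1;

  MusclePar p;
  p.f_max = as<double>(par["f_max"]);
  p.l_opt = as<double>(par["l_opt"]);
  p.l_slack = as<double>(par["l_slack"]);
  p.penn_opt = as<double>(par["pennation_opt"]);
  p.v_max = as<double>(par["v_max"]);
  p.width = as<double>(par["width"]);
  p.h = p.l_opt * std::sin(p.penn_opt);

  Curves c;
  c.af = as<double>(curves["af"]);
  c.ecc_max = as<double>(curves["ecc_max"]);
  c.k_ecc = as<double>(curves["k_ecc"]);
  c.e0_t = as<double>(curves["e0_tendon"]);
  c.k_t = as<double>(curves["k_tendon"]);
  c.e0_pe = as<double>(curves["e0_pe"]);
  c.k_pe = as<double>(curves["k_pe"]);
  c.fl_floor = as<double>(curves["fl_floor"]);
  c.a_min = as<double>(curves["a_min"]);
  c.beta = as<double>(curves["damping"]);
  c.ln_floor = std::log(c.fl_floor);

  NumericMatrix out(n, 8);
  colnames(out) = CharacterVector::create("lf", "vf", "act", "f_ce", "f_pe",
                                          "f_tendon", "cos_penn", "residual");

  double lf = rigid_tendon ? rigid_fiber_length(lmt[0], p)
                           : std::max(lf0, 0.01 * p.l_opt);
  double hsub = dt / substeps;
  double lf_min = 0.01 * p.l_opt;

  for (int i = 0; i < n; ++i) {
    double a_i = activation[i];
    double lmt_i = lmt[i];

    if (rigid_tendon) lf = rigid_fiber_length(lmt_i, p);

    // record state at sample i
    double cosp, sinp;
    pennation(lf, p, cosp, sinp);
    double ln = lf / p.l_opt;
    double fl = active_fl(ln, p.width, c);
    double fpe = passive_f(ln, c) * p.f_max;
    // the reported f_ce is the active contractile force at the true
    // activation; the equilibrium residual uses the full fiber force
    // including the parallel damper and the solver's activation floor
    double a_eff = std::max(a_i, c.a_min);
    double fl_eff = std::max(fl, 1e-6);
    double vf, fce_full, ft;
    if (rigid_tendon) {
      // velocity from finite difference of the slaved fiber length
      double lf_next = (i + 1 < n) ? rigid_fiber_length(lmt[i + 1], p) : lf;
      double lf_prev = (i > 0) ? rigid_fiber_length(lmt[i - 1], p) : lf;
      vf = (lf_next - lf_prev) / (dt * ((i > 0 && i + 1 < n) ? 2.0 : 1.0));
      fce_full = p.f_max * ce_force(a_eff, fl_eff, vf / p.l_opt, p.v_max, c);
      ft = (fce_full + fpe) * cosp;
    } else {
      vf = fiber_velocity(a_i, lmt_i, lf, p, c);
      double lt = lmt_i - lf * cosp;
      ft = tendon_f(lt / p.l_slack - 1.0, c) * p.f_max;
      fce_full = p.f_max * ce_force(a_eff, fl_eff, vf / p.l_opt, p.v_max, c);
    }
    if (ft < 0) ft = 0;
    double fce_active =
        p.f_max * a_i * fl * force_velocity(vf / p.l_opt, p.v_max, c);
    out(i, 0) = lf;
    out(i, 1) = vf;
    out(i, 2) = a_i;
    out(i, 3) = fce_active;
    out(i, 4) = fpe;
    out(i, 5) = ft;
    out(i, 6) = cosp;
    out(i, 7) = std::fabs(ft - (fce_full + fpe) * cosp);

    if (i + 1 >= n || rigid_tendon) continue;

    // advance fiber length over [i, i+1] with RK4 substeps; inputs
    // interpolated linearly in time
    for (int s = 0; s < substeps; ++s) {
      double t0 = i + (double)s / substeps;
      double t1 = i + (double)(s + 1) / substeps;
      double tm = 0.5 * (t0 + t1);
      double a0 = lerp(activation, t0), am = lerp(activation, tm),
             a1 = lerp(activation, t1);
      double m0 = lerp(lmt, t0), mm = lerp(lmt, tm), m1 = lerp(lmt, t1);
      double k1 = fiber_velocity(a0, m0, lf, p, c);
      double k2 = fiber_velocity(am, mm, lf + 0.5 * hsub * k1, p, c);
      double k3 = fiber_velocity(am, mm, lf + 0.5 * hsub * k2, p, c);
      double k4 = fiber_velocity(a1, m1, lf + hsub * k3, p, c);
      lf += hsub * (k1 + 2 * k2 + 2 * k3 + k4) / 6.0;
      if (lf < lf_min) lf = lf_min;
      if (!std::isfinite(lf))
        stop("muscle state integration diverged at sample %d", i + 1);
    }
  }
  return out;
}
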