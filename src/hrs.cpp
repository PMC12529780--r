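// Constrained-Langevin (BAOAB + SHAKE) engine for the magnetic-field-vector
// stochastic dynamics with flat-bottom RDC restraining on exponentially
// averaged P2 values. Mirrors the R reference stepper (.hrs_run_r) draw for
// draw: the only RNG consumption is 6 normal deviates per step in the O part.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double KB = 8.31446261815324e-3; // kJ mol^-1 K^-1

struct Vec3 {
  double x, y, z;
  Vec3(double a = 0, double b = 0, double c = 0) : x(a), y(b), z(c) {}
};
static inline Vec3 operator+(const Vec3& a, const Vec3& b) { return Vec3(a.x + b.x, a.y + b.y, a.z + b.z); }
static inline Vec3 operator-(const Vec3& a, const Vec3& b) { return Vec3(a.x - b.x, a.y - b.y, a.z - b.z); }
static inline Vec3 operator*(double s, const Vec3& a) { return Vec3(s * a.x, s * a.y, s * a.z); }
static inline double dot(const Vec3& a, const Vec3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline double norm(const Vec3& a) { return std::sqrt(dot(a, a)); }

// remove the radial component of the relative velocity (equal masses)
static void rattle_v(const Vec3& r1, const Vec3& r2, Vec3& v1, Vec3& v2) {
  Vec3 d = r1 - r2;
  double n = norm(d);
  d = (1.0 / n) * d;
  double c = dot(v1 - v2, d);
  v1 = v1 - (0.5 * c) * d;
  v2 = v2 + (0.5 * c) * d;
}

// iterative SHAKE on the single bond; tol is relative geometric precision
static void shake(Vec3& r1, Vec3& r2, const Vec3& ref1, const Vec3& ref2,
                  double bond, double mass, double tol, int maxit) {
  Vec3 dref = ref1 - ref2;
  for (int it = 0; it < maxit; ++it) {
    Vec3 d = r1 - r2;
    double len = norm(d);
    if (std::fabs(len - bond) / bond < tol) return;
    double g = (dot(d, d) - bond * bond) / (2.0 * (2.0 / mass) * dot(d, dref));
    r1 = r1 - (g / mass) * dref;
    r2 = r2 + (g / mass) * dref;
  }
  stop("SHAKE failed to converge within %d iterations", maxit);
}

// flat-bottom restraint force wrt the averaged coupling (kJ mol^-1 Hz^-1)
static inline double f_restraint(double x, double K, double fb, double h) {
  if (std::fabs(x) <= fb) return 0.0;
  if (x > 0) return (x <= fb + h) ? -K * (x - fb) : -K * h;
  return (x >= -fb - h) ? -K * (x + fb) : K * h;
}

// [[Rcpp::export]]
List hrs_run_cpp(NumericMatrix u_rdc, NumericVector scale_Hz, NumericVector D0,
                 LogicalVector restrained, double K, double fb, double hw,
                 double tau, double dt, double Temp, double gamma, double mass,
                 double bond, int n_steps, int traj_stride, int trace_stride,
                 bool renormalize, NumericVector v1_init, NumericVector v2_init) {
  const int N = u_rdc.nrow();
  const double a = std::exp(-dt / tau);
  const double wP = 1.0 - a;              // dPbar/dP, used in the chain rule
  const double shake_tol = 1e-4;
  const int shake_maxit = 1000;

  Vec3 r1(0, 0, bond / 2), r2(0, 0, -bond / 2);
  Vec3 v1(v1_init[0], v1_init[1], v1_init[2]);
  Vec3 v2(v2_init[0], v2_init[1], v2_init[2]);
  rattle_v(r1, r2, v1, v2);

  std::vector<double> P(N), acc(N), bar(N), P_eff(N), P_sum(N, 0.0);
  double wsum;

  RNGScope scope;

  // orientation factors at the initial configuration
  {
    Vec3 u = (1.0 / norm(r1 - r2)) * (r1 - r2);
    for (int k = 0; k < N; ++k) {
      double ct = u.x * u_rdc(k, 0) + u.y * u_rdc(k, 1) + u.z * u_rdc(k, 2);
      P[k] = 0.5 * (3.0 * ct * ct - 1.0);
      acc[k] = (1.0 - a) * P[k];
      bar[k] = P[k];  // bare recursion initializes at the first sample
    }
    wsum = 1.0 - a;
    for (int k = 0; k < N; ++k) P_eff[k] = renormalize ? acc[k] / wsum : bar[k];
  }

  Vec3 f1(0, 0, 0);
  auto compute_force = [&](void) {
    f1 = Vec3(0, 0, 0);
    if (K == 0.0) return;
    Vec3 d = r1 - r2;
    double bn = norm(d);
    Vec3 u = (1.0 / bn) * d;
    for (int k = 0; k < N; ++k) {
      if (!restrained[k]) continue;
      double Dbar = scale_Hz[k] * P_eff[k];
      double fD = f_restraint(Dbar - D0[k], K, fb, hw);
      if (fD == 0.0) continue;
      Vec3 uk(u_rdc(k, 0), u_rdc(k, 1), u_rdc(k, 2));
      double ct = dot(u, uk);
      Vec3 grad = (3.0 * ct / bn) * (uk - ct * u);
      double s = fD * scale_Hz[k] * wP;
      f1 = f1 + s * grad;
    }
  };
  compute_force();

  const double h = dt;
  const double c1 = std::exp(-gamma * h);
  const double c2 = std::sqrt((1.0 - c1 * c1) * KB * Temp / mass);

  int n_traj = (traj_stride > 0) ? n_steps / traj_stride : 0;
  NumericMatrix traj(std::max(n_traj, 0), 3);
  int n_trace = (trace_stride > 0) ? n_steps / trace_stride : 0;
  NumericMatrix trace(std::max(n_trace, 0), N);
  NumericVector trace_t(std::max(n_trace, 0));
  int i_traj = 0, i_trace = 0;

  for (int n = 1; n <= n_steps; ++n) {
    // B: half kick with force at current positions (f2 = -f1)
    v1 = v1 + (0.5 * h / mass) * f1;
    v2 = v2 - (0.5 * h / mass) * f1;
    rattle_v(r1, r2, v1, v2);
    // A: half drift + SHAKE (velocity corrected by the constraint displacement)
    {
      Vec3 p1 = r1 + (0.5 * h) * v1, p2 = r2 + (0.5 * h) * v2;
      Vec3 q1 = p1, q2 = p2;
      shake(q1, q2, r1, r2, bond, mass, shake_tol, shake_maxit);
      v1 = v1 + (1.0 / (0.5 * h)) * (q1 - p1);
      v2 = v2 + (1.0 / (0.5 * h)) * (q2 - p2);
      r1 = q1; r2 = q2;
    }
    // O: exact Ornstein-Uhlenbeck refresh (6 normal deviates)
    {
      double g1x = norm_rand(), g1y = norm_rand(), g1z = norm_rand();
      v1 = Vec3(c1 * v1.x + c2 * g1x, c1 * v1.y + c2 * g1y, c1 * v1.z + c2 * g1z);
      double g2x = norm_rand(), g2y = norm_rand(), g2z = norm_rand();
      v2 = Vec3(c1 * v2.x + c2 * g2x, c1 * v2.y + c2 * g2y, c1 * v2.z + c2 * g2z);
    }
    rattle_v(r1, r2, v1, v2);
    // A: second half drift + SHAKE
    {
      Vec3 p1 = r1 + (0.5 * h) * v1, p2 = r2 + (0.5 * h) * v2;
      Vec3 q1 = p1, q2 = p2;
      shake(q1, q2, r1, r2, bond, mass, shake_tol, shake_maxit);
      v1 = v1 + (1.0 / (0.5 * h)) * (q1 - p1);
      v2 = v2 + (1.0 / (0.5 * h)) * (q2 - p2);
      r1 = q1; r2 = q2;
    }
    // sample orientation factors, update exponential averages
    Vec3 u = (1.0 / norm(r1 - r2)) * (r1 - r2);
    for (int k = 0; k < N; ++k) {
      double ct = u.x * u_rdc(k, 0) + u.y * u_rdc(k, 1) + u.z * u_rdc(k, 2);
      P[k] = 0.5 * (3.0 * ct * ct - 1.0);
      acc[k] = (1.0 - a) * P[k] + a * acc[k];
      bar[k] = (1.0 - a) * P[k] + a * bar[k];
      P_sum[k] += P[k];
    }
    wsum = 1.0 - a + a * wsum;
    for (int k = 0; k < N; ++k) P_eff[k] = renormalize ? acc[k] / wsum : bar[k];
    // B: half kick with the force at the new positions
    compute_force();
    v1 = v1 + (0.5 * h / mass) * f1;
    v2 = v2 - (0.5 * h / mass) * f1;
    rattle_v(r1, r2, v1, v2);

    if (traj_stride > 0 && n % traj_stride == 0 && i_traj < n_traj) {
      traj(i_traj, 0) = u.x; traj(i_traj, 1) = u.y; traj(i_traj, 2) = u.z;
      ++i_traj;
    }
    if (trace_stride > 0 && n % trace_stride == 0 && i_trace < n_trace) {
      for (int k = 0; k < N; ++k) trace(i_trace, k) = scale_Hz[k] * P_sum[k] / n;
      trace_t[i_trace] = n * dt;
      ++i_trace;
    }
    if (n % 100000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector P_mean(N), P_bar(N);
  for (int k = 0; k < N; ++k) {
    P_mean[k] = P_sum[k] / n_steps;
    P_bar[k] = P_eff[k];
  }
  return List::create(
    _["P_mean"] = P_mean, _["P_bar"] = P_bar,
    _["traj"] = traj, _["trace"] = trace, _["trace_t"] = trace_t,
    _["r1"] = NumericVector::create(r1.x, r1.y, r1.z),
    _["r2"] = NumericVector::create(r2.x, r2.y, r2.z),
    _["v1"] = NumericVector::create(v1.x, v1.y, v1.z),
    _["v2"] = NumericVector::create(v2.x, v2.y, v2.z));
}

// Force-free diagnostics: propagate and return bond-length extrema and the
// mean kinetic energy; used for the SHAKE-precision and equipartition checks.
// [[Rcpp::export]]
List mfv_free_diagnostics_cpp(double dt, double Temp, double gamma, double mass,
                              double bond, int n_steps,
                              NumericVector v1_init, NumericVector v2_init) {
  Vec3 r1(0, 0, bond / 2), r2(0, 0, -bond / 2);
  Vec3 v1(v1_init[0], v1_init[1], v1_init[2]);
  Vec3 v2(v2_init[0], v2_init[1], v2_init[2]);
  rattle_v(r1, r2, v1, v2);
  RNGScope scope;
  const double h = dt;
  const double c1 = std::exp(-gamma * h);
  const double c2 = std::sqrt((1.0 - c1 * c1) * KB * Temp / mass);
  double min_b = bond, max_b = bond, ke_sum = 0.0;
  for (int n = 1; n <= n_steps; ++n) {
    rattle_v(r1, r2, v1, v2);
    Vec3 p1 = r1 + (0.5 * h) * v1, p2 = r2 + (0.5 * h) * v2;
    Vec3 q1 = p1, q2 = p2;
    shake(q1, q2, r1, r2, bond, mass, 1e-4, 1000);
    v1 = v1 + (1.0 / (0.5 * h)) * (q1 - p1); v2 = v2 + (1.0 / (0.5 * h)) * (q2 - p2);
    r1 = q1; r2 = q2;
    {
      double g1x = norm_rand(), g1y = norm_rand(), g1z = norm_rand();
      v1 = Vec3(c1 * v1.x + c2 * g1x, c1 * v1.y + c2 * g1y, c1 * v1.z + c2 * g1z);
      double g2x = norm_rand(), g2y = norm_rand(), g2z = norm_rand();
      v2 = Vec3(c1 * v2.x + c2 * g2x, c1 * v2.y + c2 * g2y, c1 * v2.z + c2 * g2z);
    }
    rattle_v(r1, r2, v1, v2);
    p1 = r1 + (0.5 * h) * v1; p2 = r2 + (0.5 * h) * v2;
    q1 = p1; q2 = p2;
    shake(q1, q2, r1, r2, bond, mass, 1e-4, 1000);
    v1 = v1 + (1.0 / (0.5 * h)) * (q1 - p1); v2 = v2 + (1.0 / (0.5 * h)) * (q2 - p2);
    r1 = q1; r2 = q2;
    double b = norm(r1 - r2);
    if (b < min_b) min_b = b;
    if (b > max_b) max_b = b;
    ke_sum += 0.5 * mass * (dot(v1, v1) + dot(v2, v2));
  }
  return List::create(_["min_bond"] = min_b, _["max_bond"] = max_b,
                      _["mean_kinetic"] = ke_sum / n_steps);
}
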