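// Hybrid dynamics core for the push-off-powered simplest dynamic walker.
//
// State during stance: y = (theta, thetadot, phi, phidot), dimensionless
// (lengths by leg length l, time by sqrt(l/g), impulse by m*sqrt(g*l)).
// Stance leg is an inverted pendulum; the massless swing leg does not affect
// it.  Heel strike is the root of phi - 2*theta subject to the legitimacy
// conditions (theta <= 0, thetadot <= 0, phidot >= 2*thetadot); the spurious
// mid-swing crossing (legs parallel, scuffing) fails those and is skipped.

#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double PI_ = 3.14159265358979323846;

// stance outcome codes (subset of the step failure enum)
enum StanceCode { ST_HEELSTRIKE = 0, ST_STUCK = 1, ST_FALL = 2 };

static inline void rhs(const double* y, double* dy) {
  dy[0] = y[1];
  dy[1] = std::sin(y[0]);
  dy[2] = y[3];
  dy[3] = std::sin(y[0]) + (y[1] * y[1] - std::cos(y[0])) * std::sin(y[2]);
}

// One Dormand-Prince 5(4) step from y with size h. Returns 5th-order solution
// in ynew and the embedded error estimate in err (per component).
static void dp45_step(const double* y, double h, double* ynew, double* err) {
  static const double a21 = 1.0 / 5;
  static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
  static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
  static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                      a53 = 64448.0 / 6561, a54 = -212.0 / 729;
  static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                      a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                      a65 = -5103.0 / 18656;
  static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                      b5 = -2187.0 / 6784, b6 = 11.0 / 84;
  static const double e1 = 5179.0 / 57600, e3 = 7571.0 / 16695,
                      e4 = 393.0 / 640, e5 = -92097.0 / 339200,
                      e6 = 187.0 / 2100, e7 = 1.0 / 40;
  double k1[4], k2[4], k3[4], k4[4], k5[4], k6[4], k7[4], yt[4];
  rhs(y, k1);
  for (int i = 0; i < 4; i++) yt[i] = y[i] + h * a21 * k1[i];
  rhs(yt, k2);
  for (int i = 0; i < 4; i++) yt[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
  rhs(yt, k3);
  for (int i = 0; i < 4; i++)
    yt[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
  rhs(yt, k4);
  for (int i = 0; i < 4; i++)
    yt[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] + a54 * k4[i]);
  rhs(yt, k5);
  for (int i = 0; i < 4; i++)
    yt[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] + a64 * k4[i] +
                        a65 * k5[i]);
  rhs(yt, k6);
  for (int i = 0; i < 4; i++)
    ynew[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] + b5 * k5[i] +
                          b6 * k6[i]);
  rhs(ynew, k7);
  for (int i = 0; i < 4; i++) {
    double y4 = y[i] + h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] +
                            e6 * k6[i] + e7 * k7[i]);
    err[i] = ynew[i] - y4;
  }
}

static inline double evfun(const double* y) { return y[2] - 2.0 * y[0]; }
static inline double grf_margin(const double* y) {
  return std::cos(y[0]) - y[1] * y[1];
}
static inline double grf2(double th, double thd) {
  return std::cos(th) - thd * thd;
}

struct StanceOpts {
  double reltol, abstol, tcap, fall_angle;
};

struct StanceRes {
  int code;
  double th_m, thd_m, phi_m, phid_m, tau, min_grf, e_drift;
};

// Integrate one stance phase from section state (theta+, thetadot+) with the
// swing-leg reset phi+ = 2 theta+, phidot+ = (1 - cos 2 theta+) * thetadot+.
static StanceRes stance_core(double th, double thd, const StanceOpts& o) {
  StanceRes R;
  double y[4] = {th, thd, 2.0 * th, (1.0 - std::cos(2.0 * th)) * thd};
  double E0 = 0.5 * thd * thd + std::cos(th);
  double t = 0.0, h = 1e-3;
  const double hmin = 1e-13, hmax = 0.5;
  double mingrf = grf_margin(y);
  bool armed = false;
  double e_prev = 0.0;

  // immediate stuck: nonneg rate with stance leg ahead of vertical
  if (thd >= 0.0 && th > 0.0) {
    R.code = ST_STUCK;
    R.th_m = th; R.thd_m = thd; R.phi_m = y[2]; R.phid_m = y[3];
    R.tau = 0.0; R.e_drift = 0.0;
    return R;
  }

  double ynew[4], err[4];
  int nreject = 0;
  while (t < o.tcap) {
    if (h > hmax) h = hmax;
    if (t + h > o.tcap) h = o.tcap - t;
    dp45_step(y, h, ynew, err);
    double enorm = 0.0;
    for (int i = 0; i < 4; i++) {
      double sc = o.abstol + o.reltol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
      double r = err[i] / sc;
      enorm += r * r;
    }
    enorm = std::sqrt(enorm / 4.0);
    if (enorm > 1.0 && h > hmin) {  // reject
      h *= std::max(0.2, 0.9 * std::pow(enorm, -0.2));
      if (++nreject > 1000) break;
      continue;
    }
    nreject = 0;

    double e_new = evfun(ynew);
    bool crossing = armed && ((e_prev > 0.0 && e_new <= 0.0) ||
                              (e_prev < 0.0 && e_new >= 0.0));
    if (crossing) {
      // localize by bisection with fixed internal steps
      double ys[4], ymid[4], emid2[4];
      for (int i = 0; i < 4; i++) ys[i] = y[i];
      double ts = t, ha = h;
      double es = e_prev;
      while (ha > 1e-12) {
        dp45_step(ys, ha / 2.0, ymid, emid2);
        double em = evfun(ymid);
        bool cross_first = (es > 0.0 && em <= 0.0) || (es < 0.0 && em >= 0.0);
        if (!cross_first) {
          for (int i = 0; i < 4; i++) ys[i] = ymid[i];
          ts += ha / 2.0;
          es = em;
        }
        ha /= 2.0;
      }
      // legitimacy (heel strike vs mid-swing scuff)
      const double tol = 1e-9;
      if (ys[0] <= tol && ys[1] <= tol && (ys[3] - 2.0 * ys[1]) >= -tol) {
        double Ee = 0.5 * ys[1] * ys[1] + std::cos(ys[0]);
        if (grf_margin(ys) < mingrf) mingrf = grf_margin(ys);
        R.code = ST_HEELSTRIKE;
        R.th_m = ys[0]; R.thd_m = ys[1]; R.phi_m = ys[2]; R.phid_m = ys[3];
        R.tau = ts; R.min_grf = mingrf; R.e_drift = std::fabs(Ee - E0);
        return R;
      }
      // scuff: nudge just past the crossing and continue
      dp45_step(ys, 2e-9, ymid, emid2);
      for (int i = 0; i < 4; i++) y[i] = ymid[i];
      t = ts + 2e-9;
      e_prev = evfun(y);
      armed = std::fabs(e_prev) > 1e-11;
      continue;
    }

    // accept
    t += h;
    for (int i = 0; i < 4; i++) y[i] = ynew[i];
    e_prev = e_new;
    if (!armed && std::fabs(e_prev) > 1e-10) armed = true;
    double g = grf_margin(y);
    if (g < mingrf) mingrf = g;

    if (y[0] <= o.fall_angle) {
      R.code = ST_FALL;
      break;
    }
    if (y[1] >= 0.0 && y[0] > 0.0) {
      R.code = ST_STUCK;
      break;
    }
    h *= std::min(5.0, std::max(0.2, 0.9 * std::pow(std::max(enorm, 1e-10), -0.2)));
  }
  if (t >= o.tcap) R.code = ST_STUCK;  // never reached a legitimate heel strike
  R.th_m = y[0]; R.thd_m = y[1]; R.phi_m = y[2]; R.phid_m = y[3];
  R.tau = t; R.min_grf = mingrf;
  R.e_drift = std::fabs(0.5 * y[1] * y[1] + std::cos(y[0]) - E0);
  return R;
}

static inline void pushoff_limits_core(double th_m, double thd_m,
                                       double* pmin, double* pmax) {
  if (th_m > -PI_ / 4.0) {
    *pmin = 0.0;
    *pmax = thd_m * std::tan(2.0 * th_m);
  } else {
    *pmin = -thd_m / std::tan(2.0 * th_m);
    *pmax = std::numeric_limits<double>::infinity();
  }
}

static inline void heelstrike_core(double th_m, double thd_m, double P,
                                   double* th_p, double* thd_p) {
  *th_p = -th_m;
  *thd_p = thd_m * std::cos(2.0 * th_m) + P * std::sin(2.0 * th_m);
}

// [[Rcpp::export]]
NumericVector cpp_stance(double theta, double thetadot, double reltol,
                         double abstol, double tcap, double fall_angle) {
  StanceOpts o = {reltol, abstol, tcap, fall_angle};
  StanceRes r = stance_core(theta, thetadot, o);
  NumericVector out = NumericVector::create(
      _["code"] = r.code, _["theta_minus"] = r.th_m,
      _["thetadot_minus"] = r.thd_m, _["phi_minus"] = r.phi_m,
      _["phidot_minus"] = r.phid_m, _["tau"] = r.tau,
      _["min_grf"] = r.min_grf, _["energy_drift"] = r.e_drift);
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_stance_batch(NumericMatrix states, double reltol,
                               double abstol, double tcap, double fall_angle) {
  StanceOpts o = {reltol, abstol, tcap, fall_angle};
  int n = states.nrow();
  NumericMatrix out(n, 8);
  colnames(out) = CharacterVector::create("code", "theta_minus",
                                          "thetadot_minus", "phi_minus",
                                          "phidot_minus", "tau", "min_grf",
                                          "energy_drift");
  for (int i = 0; i < n; i++) {
    StanceRes r = stance_core(states(i, 0), states(i, 1), o);
    out(i, 0) = r.code; out(i, 1) = r.th_m; out(i, 2) = r.thd_m;
    out(i, 3) = r.phi_m; out(i, 4) = r.phid_m; out(i, 5) = r.tau;
    out(i, 6) = r.min_grf; out(i, 7) = r.e_drift;
    if (i % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_heelstrike(double theta_minus, double thetadot_minus,
                             double P) {
  double thp, thdp;
  heelstrike_core(theta_minus, thetadot_minus, P, &thp, &thdp);
  return NumericVector::create(_["theta_plus"] = thp,
                               _["thetadot_plus"] = thdp);
}

// [[Rcpp::export]]
NumericVector cpp_pushoff_limits(double theta_minus, double thetadot_minus) {
  double pmin, pmax;
  pushoff_limits_core(theta_minus, thetadot_minus, &pmin, &pmax);
  return NumericVector::create(_["p_min"] = pmin, _["p_max"] = pmax);
}

// step failure codes
enum StepCode {
  SC_NONE = 0, SC_STUCK = 1, SC_FALL = 2,
  SC_GRF_START = 3, SC_GRF_END = 4, SC_PUSHOFF = 5
};

// One step of the hybrid Poincare map F(x; P).
// Returns: code, theta_next, thetadot_next, theta_minus, thetadot_minus,
//          phidot_minus, tau, step_length, step_speed, min_grf, energy_drift
static void step_core(double th, double thd, double P, const StanceOpts& o,
                      double* out, bool enforce_limits = true) {
  for (int i = 0; i < 11; i++) out[i] = NA_REAL;
  out[0] = SC_NONE;
  if (grf2(th, thd) < 0.0) { out[0] = SC_GRF_START; return; }
  StanceRes r = stance_core(th, thd, o);
  out[3] = r.th_m; out[4] = r.thd_m; out[5] = r.phid_m; out[6] = r.tau;
  out[9] = r.min_grf; out[10] = r.e_drift;
  if (r.code != ST_HEELSTRIKE) { out[0] = r.code; return; }
  if (grf2(r.th_m, r.thd_m) < 0.0) { out[0] = SC_GRF_END; return; }
  double pmin, pmax;
  pushoff_limits_core(r.th_m, r.thd_m, &pmin, &pmax);
  if (enforce_limits && (P < pmin - 1e-12 || P > pmax + 1e-12)) {
    out[0] = SC_PUSHOFF;
    return;
  }
  double thp, thdp;
  heelstrike_core(r.th_m, r.thd_m, P, &thp, &thdp);
  out[1] = thp; out[2] = thdp;
  out[7] = 2.0 * std::sin(thp);         // step length (feet 2*sin(theta+) apart)
  out[8] = out[7] / r.tau;              // step speed V = L / tau
}

// [[Rcpp::export]]
NumericVector cpp_step(double theta, double thetadot, double P, double reltol,
                       double abstol, double tcap, double fall_angle,
                       bool enforce_limits = true) {
  StanceOpts o = {reltol, abstol, tcap, fall_angle};
  double out[11];
  step_core(theta, thetadot, P, o, out, enforce_limits);
  NumericVector v(out, out + 11);
  v.names() = CharacterVector::create(
      "code", "theta_next", "thetadot_next", "theta_minus", "thetadot_minus",
      "phidot_minus", "tau", "step_length", "step_speed", "min_grf",
      "energy_drift");
  return v;
}

// ---- basin simulation ------------------------------------------------------

struct SpeedTable {
  int n_th, n_sc;
  double th0, dth, dsc;          // theta columns th0 + j*dth, sc rows -i*dsc
  const double* omlow;           // per column
  const double* omhigh;
  const double* V;               // n_sc x n_th column-major (R matrix)
};

static inline double lin_col(const SpeedTable& T, const double* tab, double th) {
  double u = (th - T.th0) / T.dth;
  if (u < 0.0) u = 0.0;
  if (u > T.n_th - 1.0) u = T.n_th - 1.0;
  int j = (int)std::floor(u);
  if (j > T.n_th - 2) j = T.n_th - 2;
  double f = u - j;
  return tab[j] * (1.0 - f) + tab[j + 1] * f;
}

static inline double sc_of(const SpeedTable& T, double th, double thd) {
  double lo = lin_col(T, T.omlow, th), hi = lin_col(T, T.omhigh, th);
  return (thd - lo) / (lo - hi);
}

// bilinear speed lookup at (theta, sc); NaN if off-table or near failed cells
static double speed_lookup(const SpeedTable& T, double th, double sc) {
  double u = (th - T.th0) / T.dth;
  double v = -sc / T.dsc;
  if (u < 0.0 || u > T.n_th - 1.0 || v < 0.0 || v > T.n_sc - 1.0)
    return NA_REAL;
  int j = (int)std::floor(u); if (j > T.n_th - 2) j = T.n_th - 2;
  int i = (int)std::floor(v); if (i > T.n_sc - 2) i = T.n_sc - 2;
  double fu = u - j, fv = v - i;
  double v00 = T.V[i + j * T.n_sc], v10 = T.V[i + 1 + j * T.n_sc];
  double v01 = T.V[i + (j + 1) * T.n_sc], v11 = T.V[i + 1 + (j + 1) * T.n_sc];
  if (ISNAN(v00) || ISNAN(v10) || ISNAN(v01) || ISNAN(v11)) return NA_REAL;
  return (1 - fu) * ((1 - fv) * v00 + fv * v10) +
         fu * ((1 - fv) * v01 + fv * v11);
}

// Pick the regulated push-off for pre-impact state (th_m, thd_m): minimize
// (V_next - Vstar)^2 over the admissible push-offs on the feasible branch
// connected to the minimal push-off, using the interpolated speed table;
// smallest minimizer first (left-to-right scan + golden-section refinement).
// The regulator is myopic in the minimal-intervention sense: it does not
// cross an infeasible (stuck-landing) gap in search of a slower landing, so
// when even the least admissible push-off lands the walker unable to pass
// vertical, the minimal push-off is applied and the step fails naturally.
// anchor_mode: 0 = global argmin over all admissible P (the literal
// one-step-optimal reading); 1 = continuation-anchored: the search is
// restricted to the contiguous feasible run of push-offs containing the
// previously applied P (the precomputed-manifold simulation strategy); if
// the anchor itself lands the walker infeasibly, the minimiser is treated
// as saturated at p_min and the step fails on its own.
static double regulator_pushoff(const SpeedTable& T, double th_m, double thd_m,
                                double Vstar, double Pcap, bool* ok,
                                int anchor_mode, double P_prev) {
  double pmin, pmax;
  pushoff_limits_core(th_m, thd_m, &pmin, &pmax);
  double phi_ = std::min(pmax, Pcap);
  *ok = true;
  if (pmin > phi_) { *ok = false; return NA_REAL; }
  double c2 = std::cos(2.0 * th_m), s2 = std::sin(2.0 * th_m);
  double thn = -th_m;
  const int N = 129;
  double dP = (phi_ - pmin) / (N - 1);
  double cvals[N];
  bool feas[N];
  for (int i = 0; i < N; i++) {
    double P = pmin + i * dP;
    double w = thd_m * c2 + P * s2;
    double V = speed_lookup(T, thn, sc_of(T, thn, w));
    feas[i] = !ISNAN(V);
    cvals[i] = feas[i] ? (V - Vstar) * (V - Vstar) : R_PosInf;
  }
  int lo = 0, hi = N - 1;
  if (anchor_mode == 1) {
    int ia = (int)std::round((std::min(std::max(P_prev, pmin), phi_) - pmin) / dP);
    if (ia < 0) ia = 0;
    if (ia > N - 1) ia = N - 1;
    // allow a one-cell slop when locating the anchor's feasible run
    if (!feas[ia] && ia > 0 && feas[ia - 1]) ia--;
    else if (!feas[ia] && ia < N - 1 && feas[ia + 1]) ia++;
    if (!feas[ia]) return pmin;    // anchor infeasible: saturate and fail
    lo = ia; while (lo > 0 && feas[lo - 1]) lo--;
    hi = ia; while (hi < N - 1 && feas[hi + 1]) hi++;
  }
  double bestP = NA_REAL, bestc = R_PosInf;
  int besti = -1;
  for (int i = lo; i <= hi; i++) {
    if (!feas[i]) continue;
    if (cvals[i] < bestc - 1e-14) { bestc = cvals[i]; bestP = pmin + i * dP; besti = i; }
  }
  if (besti < 0) return pmin;   // saturate: the walker fails on its own
  // golden-section refine within the bracketing neighbours
  double a = pmin + std::max(lo, besti - 1) * dP;
  double b = pmin + std::min(hi, besti + 1) * dP;
  const double gr = 0.6180339887498949;
  double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
  auto cost = [&](double P) {
    double w = thd_m * c2 + P * s2;
    double V = speed_lookup(T, thn, sc_of(T, thn, w));
    return ISNAN(V) ? R_PosInf : (V - Vstar) * (V - Vstar);
  };
  double f1 = cost(x1), f2 = cost(x2);
  for (int it = 0; it < 60 && (b - a) > 1e-11; it++) {
    if (f1 <= f2) { b = x2; x2 = x1; f2 = f1; x1 = b - gr * (b - a); f1 = cost(x1); }
    else { a = x1; x1 = x2; f1 = f2; x2 = a + gr * (b - a); f2 = cost(x2); }
  }
  double Pr = 0.5 * (a + b);
  if (cost(Pr) <= bestc + 1e-14) bestP = Pr;
  return bestP;
}

// Simulate basins from many starts.  mode 0: open loop with P = param;
// mode 1: speed-regulated toward Vstar = param (table-based regulator).
// Returns n x 3: member flag, failure/step code info, steps simulated.
// [[Rcpp::export]]
NumericMatrix cpp_basin(NumericMatrix states, int mode, double param,
                        int n_steps, double th0, double dth,
                        NumericVector omlow, NumericVector omhigh,
                        NumericMatrix Vtab, double attr_theta,
                        double attr_sc, double term_tol, double early_tol,
                        double Pcap, double reltol, double abstol, double tcap,
                        double fall_angle, double theta_cap,
                        int anchor_mode = 1, double P_anchor = 0.0) {
  StanceOpts o = {reltol, abstol, tcap, fall_angle};
  SpeedTable T;
  T.n_th = omlow.size(); T.n_sc = Vtab.nrow();
  T.th0 = th0; T.dth = dth; T.dsc = 1.0 / (Vtab.nrow() - 1.0);
  T.omlow = REAL(omlow); T.omhigh = REAL(omhigh); T.V = REAL(Vtab);
  int n = states.nrow();
  NumericMatrix out(n, 4);
  colnames(out) = CharacterVector::create("member", "code", "steps", "dist");
  for (int s = 0; s < n; s++) {
    double th = states(s, 0), thd = states(s, 1);
    double dist = NA_REAL;
    double P_prev = P_anchor;
    int member = 0, code = SC_NONE, k = 0;
    for (k = 0; k < n_steps; k++) {
      if (grf2(th, thd) < 0.0) { code = SC_GRF_START; break; }
      StanceRes r = stance_core(th, thd, o);
      if (r.code != ST_HEELSTRIKE) { code = r.code; break; }
      if (grf2(r.th_m, r.thd_m) < 0.0) { code = SC_GRF_END; break; }
      double P;
      if (mode == 0) {
        double pmin, pmax;
        pushoff_limits_core(r.th_m, r.thd_m, &pmin, &pmax);
        if (param < pmin - 1e-12 || param > pmax + 1e-12) {
          code = SC_PUSHOFF; break;
        }
        P = param;
      } else {
        bool ok;
        P = regulator_pushoff(T, r.th_m, r.thd_m, param, Pcap, &ok,
                              anchor_mode, P_prev);
        if (!ok) { code = SC_PUSHOFF; break; }
        P_prev = P;
      }
      heelstrike_core(r.th_m, r.thd_m, P, &th, &thd);
      if (th > theta_cap || th < 0.0 || thd > 0.0) { code = SC_FALL; break; }
      double d1 = th - attr_theta, d2 = sc_of(T, th, thd) - attr_sc;
      dist = std::sqrt(d1 * d1 + d2 * d2);
      if (dist < early_tol) { member = 1; break; }
      if (k == n_steps - 1 && dist < term_tol) member = 1;
    }
    out(s, 0) = member; out(s, 1) = code; out(s, 2) = k + 1;
    out(s, 3) = dist;
    if (s % 512 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Table-regulated trajectory trace (diagnostic / switching support).
// [[Rcpp::export]]
NumericMatrix cpp_regulated_traj(double theta, double thetadot, double Vstar,
                                 int n_steps, double th0, double dth,
                                 NumericVector omlow, NumericVector omhigh,
                                 NumericMatrix Vtab, double Pcap,
                                 double reltol, double abstol, double tcap,
                                 double fall_angle, double theta_cap,
                                 int anchor_mode, double P_anchor) {
  StanceOpts o = {reltol, abstol, tcap, fall_angle};
  SpeedTable T;
  T.n_th = omlow.size(); T.n_sc = Vtab.nrow();
  T.th0 = th0; T.dth = dth; T.dsc = 1.0 / (Vtab.nrow() - 1.0);
  T.omlow = REAL(omlow); T.omhigh = REAL(omhigh); T.V = REAL(Vtab);
  NumericMatrix out(n_steps, 7);
  colnames(out) = CharacterVector::create("theta", "thetadot", "P", "V",
                                          "theta_minus", "code", "tau");
  double th = theta, thd = thetadot, P_prev = P_anchor;
  for (int k = 0; k < n_steps; k++) {
    out(k, 0) = th; out(k, 1) = thd;
    for (int c = 2; c < 7; c++) out(k, c) = NA_REAL;
    if (grf2(th, thd) < 0.0) { out(k, 5) = SC_GRF_START; break; }
    StanceRes r = stance_core(th, thd, o);
    out(k, 4) = r.th_m; out(k, 6) = r.tau;
    if (r.code != ST_HEELSTRIKE) { out(k, 5) = r.code; break; }
    if (grf2(r.th_m, r.thd_m) < 0.0) { out(k, 5) = SC_GRF_END; break; }
    out(k, 3) = 2.0 * std::sin(-r.th_m) / r.tau;
    bool ok;
    double P = regulator_pushoff(T, r.th_m, r.thd_m, Vstar, Pcap, &ok,
                                 anchor_mode, P_prev);
    if (!ok) { out(k, 5) = SC_PUSHOFF; break; }
    out(k, 2) = P; out(k, 5) = SC_NONE;
    P_prev = P;
    heelstrike_core(r.th_m, r.thd_m, P, &th, &thd);
    if (th > theta_cap || th < 0.0 || thd > 0.0) { out(k, 5) = SC_FALL; break; }
  }
  return out;
}

// Direct (integration-based) regulated push-off for a single pre-impact state:
// coarse scan over admissible P then golden-section refinement; each cost
// evaluation applies the heel-strike map and integrates the next stance.
// [[Rcpp::export]]
NumericVector cpp_regulator_direct(double theta_minus, double thetadot_minus,
                                   double Vstar, double Pcap, double reltol,
                                   double abstol, double tcap,
                                   double fall_angle) {
  StanceOpts o = {reltol, abstol, tcap, fall_angle};
  double pmin, pmax;
  pushoff_limits_core(theta_minus, thetadot_minus, &pmin, &pmax);
  // The cost is finite only for push-offs whose landing rate lies inside
  // the next column's wedge (stuck above the slow boundary, falling beyond
  // the fast one).  The scan starts at the slow-boundary crossing so the
  // feasible window is densely resolved.
  double c2 = std::cos(2.0 * theta_minus), s2 = std::sin(2.0 * theta_minus);
  double thn = -theta_minus;
  double olo = -std::sqrt(2.0 * (1.0 - std::cos(thn)));
  double plo = 0.0;
  if (s2 < -1e-12) {
    double pw = (olo - thetadot_minus * c2) / s2;
    if (pw > 0.0) plo = pw;
  }
  double phi_ = std::isfinite(pmax) ? std::min(std::max(pmax, Pcap), 2.0 * Pcap)
                                    : Pcap;
  if (phi_ <= plo) plo = 0.0;
  auto cost = [&](double P) {
    double thp, thdp;
    heelstrike_core(theta_minus, thetadot_minus, P, &thp, &thdp);
    if (thp < 0.0 || thdp > 0.0 || grf2(thp, thdp) < 0.0) return R_PosInf;
    StanceRes r = stance_core(thp, thdp, o);
    if (r.code != ST_HEELSTRIKE) return R_PosInf;
    double V = 2.0 * std::sin(-r.th_m) / r.tau;
    return (V - Vstar) * (V - Vstar);
  };
  const int N = 101;
  double dP = (phi_ - plo) / (N - 1);
  double bestc = R_PosInf; int besti = -1;
  for (int i = 0; i < N; i++) {
    double c = cost(plo + i * dP);
    if (c < bestc - 1e-14) { bestc = c; besti = i; }
  }
  if (besti < 0)
    return NumericVector::create(_["p_opt"] = NA_REAL,
                                 _["p_applied"] = NA_REAL,
                                 _["p_min"] = pmin, _["p_max"] = pmax);
  double a = plo + std::max(0, besti - 1) * dP;
  double b = plo + std::min(N - 1, besti + 1) * dP;
  const double gr = 0.6180339887498949;
  double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
  double f1 = cost(x1), f2 = cost(x2);
  for (int it = 0; it < 80 && (b - a) > 1e-12; it++) {
    if (f1 <= f2) { b = x2; x2 = x1; f2 = f1; x1 = b - gr * (b - a); f1 = cost(x1); }
    else { a = x1; x1 = x2; f1 = f2; x2 = a + gr * (b - a); f2 = cost(x2); }
  }
  double popt = 0.5 * (a + b);
  if (cost(popt) > bestc + 1e-14) popt = plo + besti * dP;
  double papp = std::min(std::max(popt, pmin), pmax);
  return NumericVector::create(_["p_opt"] = popt, _["p_applied"] = papp,
                               _["p_min"] = pmin, _["p_max"] = pmax,
                               _["cost"] = cost(papp));
}
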