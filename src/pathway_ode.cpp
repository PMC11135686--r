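// Mass-action ODE core for the extended TGF-beta/SMAD pathway model and an
// adaptive Dormand-Prince 5(4) integrator.  State amounts are in arbitrary
// abundance-units except the medium ligand L (nM); time is in minutes.
//
// State layout (shared with R/pathway-sim.R — keep in sync):
//   0 L, 1 R1m, 2 R2m, 3 R1e, 4 R2e, 5 LRCm, 6 LRCe,
//   7 S2c, 8 S2n, 9 pS2c, 10 pS2n
// Parameter layout:
//   0 pR1, 1 pR2, 2 pS2, 3 kdeg_R1, 4 kdeg_R2, 5 kdeg_S2, 6 ki, 7 kr,
//   8 ka, 9 k_NFR, 10 kphos, 11 kdephos, 12 kin, 13 kex, 14 kin_p,
//   15 vol_ratio_nc (unused in the RHS), 16 med_scale
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const int NS = 11;

static inline void rhs(const double* y, const double* p, double* dy) {
  const double L = y[0], R1m = y[1], R2m = y[2], R1e = y[3], R2e = y[4];
  const double LRCm = y[5], LRCe = y[6];
  const double S2c = y[7], S2n = y[8], pS2c = y[9], pS2n = y[10];

  const double pR1 = p[0], pR2 = p[1], pS2 = p[2];
  const double kdeg_R1 = p[3], kdeg_R2 = p[4], kdeg_S2 = p[5];
  const double ki = p[6], kr = p[7], ka = p[8], k_NFR = p[9];
  const double kphos = p[10], kdephos = p[11];
  const double kin = p[12], kex = p[13], kin_p = p[14];
  const double med_scale = p[16];

  const double bind = ka * L * R1m * R2m;    // one complex consumes one R1 + one R2
  const double phos = kphos * LRCe * S2c;

  dy[0]  = -med_scale * bind;
  dy[1]  = pR1 - (ki + kdeg_R1) * R1m + kr * R1e - bind;
  dy[2]  = pR2 - (ki + kdeg_R2) * R2m + kr * R2e - bind;
  dy[3]  = ki * R1m - (kr + kdeg_R1) * R1e;
  dy[4]  = ki * R2m - (kr + kdeg_R2) * R2e;
  dy[5]  = bind - ki * LRCm;
  dy[6]  = ki * LRCm - k_NFR * LRCe;
  dy[7]  = pS2 - kdeg_S2 * S2c - phos - kin * S2c + kex * S2n;
  dy[8]  = kin * S2c - kex * S2n + kdephos * pS2n;
  dy[9]  = phos - kin_p * pS2c;
  dy[10] = kin_p * pS2c - kdephos * pS2n;
}

// [[Rcpp::export]]
NumericVector cpp_pathway_rhs(NumericVector state, NumericVector pars) {
  if (state.size() != NS) stop("state must have %d components", NS);
  if (pars.size() < 17) stop("pars must have 17 components");
  NumericVector dy(NS);
  rhs(state.begin(), pars.begin(), dy.begin());
  return dy;
}

// Dormand-Prince RK5(4)7M coefficients
static const double c2 = 1.0/5, c3 = 3.0/10, c4 = 4.0/5, c5 = 8.0/9;
static const double a21 = 1.0/5;
static const double a31 = 3.0/40, a32 = 9.0/40;
static const double a41 = 44.0/45, a42 = -56.0/15, a43 = 32.0/9;
static const double a51 = 19372.0/6561, a52 = -25360.0/2187,
                    a53 = 64448.0/6561, a54 = -212.0/729;
static const double a61 = 9017.0/3168, a62 = -355.0/33, a63 = 46732.0/5247,
                    a64 = 49.0/176, a65 = -5103.0/18656;
static const double b1 = 35.0/384, b3 = 500.0/1113, b4 = 125.0/192,
                    b5 = -2187.0/6784, b6 = 11.0/84;
// embedded 4th-order weights
static const double e1 = 5179.0/57600, e3 = 7571.0/16695, e4 = 393.0/640,
                    e5 = -92097.0/339200, e6 = 187.0/2100, e7 = 1.0/40;

// Integrate from t0 to t1 (t1 > t0), overwriting y.  Returns false on failure.
static bool integrate_segment(double t0, double t1, double* y,
                              const double* p, double rtol, double atol,
                              double* h_io, long* steps_left) {
  double t = t0, h = *h_io;
  double k1[NS], k2[NS], k3[NS], k4[NS], k5[NS], k6[NS], k7[NS];
  double ytmp[NS], y5[NS];
  bool have_k1 = false;
  while (t < t1) {
    if (h > t1 - t) h = t1 - t;
    if (h < 1e-14 * std::max(1.0, std::fabs(t))) return false;
    if (--(*steps_left) < 0) return false;
    if (!have_k1) { rhs(y, p, k1); have_k1 = true; }
    for (int i = 0; i < NS; ++i) ytmp[i] = y[i] + h * a21 * k1[i];
    rhs(ytmp, p, k2);
    for (int i = 0; i < NS; ++i) ytmp[i] = y[i] + h * (a31*k1[i] + a32*k2[i]);
    rhs(ytmp, p, k3);
    for (int i = 0; i < NS; ++i) ytmp[i] = y[i] + h * (a41*k1[i] + a42*k2[i] + a43*k3[i]);
    rhs(ytmp, p, k4);
    for (int i = 0; i < NS; ++i) ytmp[i] = y[i] + h * (a51*k1[i] + a52*k2[i] + a53*k3[i] + a54*k4[i]);
    rhs(ytmp, p, k5);
    for (int i = 0; i < NS; ++i) ytmp[i] = y[i] + h * (a61*k1[i] + a62*k2[i] + a63*k3[i] + a64*k4[i] + a65*k5[i]);
    rhs(ytmp, p, k6);
    for (int i = 0; i < NS; ++i)
      y5[i] = y[i] + h * (b1*k1[i] + b3*k3[i] + b4*k4[i] + b5*k5[i] + b6*k6[i]);
    rhs(y5, p, k7);  // FSAL
    double err = 0.0;
    for (int i = 0; i < NS; ++i) {
      double y4 = y[i] + h * (e1*k1[i] + e3*k3[i] + e4*k4[i] + e5*k5[i] + e6*k6[i] + e7*k7[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(y5[i]));
      double d = (y5[i] - y4) / sc;
      err += d * d;
    }
    err = std::sqrt(err / NS);
    if (!std::isfinite(err)) return false;
    if (err <= 1.0) {
      t += h;
      for (int i = 0; i < NS; ++i) { y[i] = y5[i]; k1[i] = k7[i]; }
      have_k1 = true;
    } else {
      have_k1 = true;  // k1 still valid at unchanged y
    }
    double fac = 0.9 * std::pow(std::max(err, 1e-10), -0.2);
    fac = std::min(5.0, std::max(0.2, fac));
    h *= fac;
    if (h > 1e6) h = 1e6;
  }
  *h_io = h;
  return true;
}

//' @noRd
// [[Rcpp::export]]
List cpp_simulate(NumericVector pars, NumericVector y0, NumericVector times,
                  NumericVector event_times, NumericVector event_ligand,
                  double rtol, double atol, double max_steps) {
  if (y0.size() != NS) stop("y0 must have %d components", NS);
  const int nt = times.size();
  NumericMatrix out(nt, NS);
  double y[NS];
  for (int i = 0; i < NS; ++i) y[i] = y0[i];
  long steps_left = (long) max_steps;
  double h = 1e-3;
  double t = times[0];
  int ev = 0;
  const int nev = event_times.size();
  // apply any events at or before the start
  while (ev < nev && event_times[ev] <= t) { y[0] = event_ligand[ev]; ++ev; }
  for (int i = 0; i < NS; ++i) out(0, i) = y[i];
  bool ok = true;
  double t_fail = NA_REAL;
  for (int k = 1; k < nt && ok; ++k) {
    double target = times[k];
    if (!(target > t)) stop("times must be strictly increasing");
    while (t < target && ok) {
      double stop_at = target;
      if (ev < nev && event_times[ev] < stop_at) stop_at = event_times[ev];
      if (stop_at > t) {
        ok = integrate_segment(t, stop_at, y, pars.begin(), rtol, atol,
                               &h, &steps_left);
        if (!ok) { t_fail = t; break; }
        t = stop_at;
      }
      if (ev < nev && event_times[ev] <= t) { y[0] = event_ligand[ev]; ++ev; }
    }
    if (ok) for (int i = 0; i < NS; ++i) out(k, i) = y[i];
  }
  return List::create(_["y"] = out, _["success"] = ok, _["t_fail"] = t_fail);
}
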