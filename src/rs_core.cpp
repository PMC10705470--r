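#include <Rcpp.h>
#include "oxygen.h"
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static const double PI = 3.14159265358979323846;

static std::vector<double> shell_volumes(int n, double dr) {
  std::vector<double> v(n);
  for (int i = 0; i < n; ++i)
    v[i] = 4.0 / 3.0 * PI * dr * dr * dr *
           (std::pow(i + 1.0, 3) - std::pow((double)i, 3));
  return v;
}

// outermost shell whose total concentration exceeds the detection threshold
static int surface_index(const std::vector<double>& tot, double thr = 0.1) {
  int i0 = -1;
  for (int i = 0; i < (int)tot.size(); ++i)
    if (tot[i] > thr) i0 = i;
  return i0;
}

struct RSPars {
  double gamma, a_h, eps, del, lam, rho_h, rho_an, rho0, D, dr, sigma;
  bool mc_gated, eps_on_damaged;
  int oxy_max_iter;
};

// Oxygen gates. With sigma > 0 the hard indicators are replaced by smooth
// exponential shoulders of width sigma (mmHg), which removes the sliding-mode
// discontinuity at the anoxic free boundary that otherwise forces the
// adaptive integrator into vanishing steps; sigma = 0 recovers the exact
// indicator forms.
static inline double gate_oxic(double rho, double rho_h, double sigma) {
  if (sigma <= 0) return rho > rho_h ? 1.0 : 0.0;
  double x = rho - rho_h;
  return x <= 0 ? 0.0 : 1.0 - std::exp(-x / sigma);
}
static inline double gate_anoxic(double rho, double rho_an, double sigma) {
  if (sigma <= 0) return rho <= rho_an ? 1.0 : 0.0;
  double x = rho - rho_an;
  return x <= 0 ? 1.0 : std::exp(-x / sigma);
}

static RSPars pars_from_list(const List& p) {
  RSPars P;
  P.gamma = as<double>(p["gamma"]);
  P.a_h = as<double>(p["a_h"]);       // mmHg per hour
  P.eps = as<double>(p["epsilon"]);
  P.del = as<double>(p["delta"]);
  P.lam = as<double>(p["lambda"]);
  P.rho_h = as<double>(p["rho_h"]);
  P.rho_an = as<double>(p["rho_an"]);
  P.rho0 = as<double>(p["rho0"]);
  P.D = as<double>(p["D_um2_h"]);
  P.dr = as<double>(p["dr"]);
  P.sigma = as<double>(p["gate_width"]);
  P.mc_gated = as<bool>(p["mc_loss_gated"]);
  P.eps_on_damaged = as<bool>(p["eps_on_damaged"]);
  P.oxy_max_iter = as<int>(p["oxy_max_iter"]);
  return P;
}

// ---------------------------------------------------------------------------
// oxygen profile for an R-level state
// [[Rcpp::export]]
List cpp_solve_oxygen(NumericVector cons, int i0, double dr, double D,
                      double rho0, double rho_an, double a_h, int max_iter) {
  std::vector<double> c(cons.begin(), cons.end()), rho;
  std::vector<char> chi;
  int it = rs_oxygen_core(c, i0, dr, D, rho0, rho_an, a_h, max_iter, rho, chi);
  if (it < 0) stop("oxygen solver did not converge within %d iterations", max_iter);
  // discrete balance: total consumption vs diffusive influx through surface face
  double cons_tot = 0.0, influx = 0.0;
  std::vector<double> vol = shell_volumes(c.size(), dr);
  for (int i = 0; i < i0; ++i)
    if (chi[i]) cons_tot += a_h * c[i] * vol[i];
  if (i0 > 0) {
    double rf = i0 * dr;
    influx = D * 4.0 * PI * rf * rf / dr * (rho0 - rho[i0 - 1]);
  }
  return List::create(_["rho"] = NumericVector(rho.begin(), rho.end()),
                      _["consuming"] = LogicalVector(chi.begin(), chi.end()),
                      _["r_an"] = rs_anoxic_radius(chi, i0, dr),
                      _["iterations"] = it,
                      _["consumption_total"] = cons_tot,
                      _["surface_influx"] = influx);
}

// ---------------------------------------------------------------------------
// per-shell volume-rate components of the dynamics (single source of truth,
// used both by the R-level *_terms() accessors and by the integrator)
struct Terms {
  std::vector<double> gain_p, gain_d, loss_mc, conv_p, conv_d, decay_n,
      trans_p, trans_d, trans_n;
};

static void rs_terms_core(const std::vector<double>& cp,
                          const std::vector<double>& cd,
                          const std::vector<double>& cn,
                          const std::vector<double>& rho,
                          const std::vector<double>& vol, const RSPars& P,
                          double Pmc, Terms& T) {
  const int n = (int)cp.size();
  T.gain_p.assign(n, 0.0); T.gain_d.assign(n, 0.0); T.loss_mc.assign(n, 0.0);
  T.conv_p.assign(n, 0.0); T.conv_d.assign(n, 0.0); T.decay_n.assign(n, 0.0);
  T.trans_p.assign(n, 0.0); T.trans_d.assign(n, 0.0); T.trans_n.assign(n, 0.0);
  std::vector<double> tot(n);
  for (int i = 0; i < n; ++i) tot[i] = cp[i] + cd[i] + cn[i];

  // proliferation: offspring volume spread over {i-1, i, i+1}, proportional
  // to local free volume, normalised by the neighborhood volume (logistic cap)
  for (int i = 0; i < n; ++i) {
    double oxic = gate_oxic(rho[i], P.rho_h, P.sigma);
    if (oxic > 0.0 && (cp[i] > 0.0 || cd[i] > 0.0)) {
      int j0 = std::max(0, i - 1), j1 = std::min(n - 1, i + 1);
      double sumV = 0.0;
      for (int j = j0; j <= j1; ++j) sumV += vol[j];
      double src_p = oxic * P.gamma * cp[i] * vol[i];
      double src_d = oxic * P.gamma * (1.0 - Pmc) * cd[i] * vol[i];
      for (int j = j0; j <= j1; ++j) {
        double F = std::max(0.0, 1.0 - tot[j]) * vol[j];
        T.gain_p[j] += src_p * F / sumV;
        T.gain_d[j] += src_d * F / sumV;
      }
    }
    // mitotic catastrophe: damaged cells break up at divisions
    if (cd[i] > 0.0)
      T.loss_mc[i] = (P.mc_gated ? oxic : 1.0) *
                     P.gamma * Pmc * cd[i] * vol[i];
  }

  // anoxic death (volume-conserving conversion to membrane-defect cells)
  // and decay of necrotic material
  for (int i = 0; i < n; ++i) {
    double anox = gate_anoxic(rho[i], P.rho_an, P.sigma);
    if (anox > 0.0) {
      T.conv_p[i] = anox * P.eps * cp[i] * vol[i];
      if (P.eps_on_damaged) T.conv_d[i] = anox * P.eps * cd[i] * vol[i];
    }
    T.decay_n[i] = P.del * cn[i] * vol[i];
  }

  // compact inward transport: flux i -> i-1 limited by inner free volume
  for (int i = 1; i < n; ++i) {
    if (tot[i] <= 0.0) continue;
    double F = std::max(0.0, 1.0 - tot[i - 1]) * vol[i - 1];
    double J = P.lam * tot[i] * F;
    double jp = J * cp[i] / tot[i], jd = J * cd[i] / tot[i],
           jn = J * cn[i] / tot[i];
    T.trans_p[i] -= jp; T.trans_p[i - 1] += jp;
    T.trans_d[i] -= jd; T.trans_d[i - 1] += jd;
    T.trans_n[i] -= jn; T.trans_n[i - 1] += jn;
  }
}

// [[Rcpp::export]]
List cpp_rs_terms(NumericMatrix conc, NumericVector rho, List pars, double Pmc) {
  RSPars P = pars_from_list(pars);
  const int n = conc.nrow();
  std::vector<double> cp(n), cd(n), cn(n), rh(rho.begin(), rho.end());
  for (int i = 0; i < n; ++i) {
    cp[i] = conc(i, 0); cd[i] = conc(i, 1); cn[i] = conc(i, 2);
  }
  std::vector<double> vol = shell_volumes(n, P.dr);
  Terms T;
  rs_terms_core(cp, cd, cn, rh, vol, P, Pmc, T);
  return List::create(
      _["prolif_gain_p"] = NumericVector(T.gain_p.begin(), T.gain_p.end()),
      _["prolif_gain_d"] = NumericVector(T.gain_d.begin(), T.gain_d.end()),
      _["mc_loss_d"] = NumericVector(T.loss_mc.begin(), T.loss_mc.end()),
      _["conv_p_to_n"] = NumericVector(T.conv_p.begin(), T.conv_p.end()),
      _["conv_d_to_n"] = NumericVector(T.conv_d.begin(), T.conv_d.end()),
      _["decay_n"] = NumericVector(T.decay_n.begin(), T.decay_n.end()),
      _["transport_p"] = NumericVector(T.trans_p.begin(), T.trans_p.end()),
      _["transport_d"] = NumericVector(T.trans_d.begin(), T.trans_d.end()),
      _["transport_n"] = NumericVector(T.trans_n.begin(), T.trans_n.end()));
}

// ---------------------------------------------------------------------------
// full right-hand side: quasi-steady oxygen, then concentration rates
static void rs_rhs_core(const std::vector<double>& cp,
                        const std::vector<double>& cd,
                        const std::vector<double>& cn,
                        const std::vector<double>& vol, const RSPars& P,
                        double Pmc, std::vector<double>& rho,
                        std::vector<char>& chi, std::vector<double>& dcp,
                        std::vector<double>& dcd, std::vector<double>& dcn,
                        bool& oxy_fail) {
  const int n = (int)cp.size();
  std::vector<double> tot(n), cons(n);
  for (int i = 0; i < n; ++i) {
    tot[i] = cp[i] + cd[i] + cn[i];
    cons[i] = cp[i] + cd[i];
  }
  int i0 = surface_index(tot);
  int it = rs_oxygen_core(cons, i0, P.dr, P.D, P.rho0, P.rho_an, P.a_h,
                          P.oxy_max_iter, rho, chi);
  oxy_fail = (it < 0);
  if (oxy_fail) return;
  Terms T;
  rs_terms_core(cp, cd, cn, rho, vol, P, Pmc, T);
  dcp.resize(n); dcd.resize(n); dcn.resize(n);
  for (int i = 0; i < n; ++i) {
    dcp[i] = (T.gain_p[i] + T.trans_p[i] - T.conv_p[i]) / vol[i];
    dcd[i] = (T.gain_d[i] + T.trans_d[i] - T.conv_d[i] - T.loss_mc[i]) / vol[i];
    dcn[i] = (T.conv_p[i] + T.conv_d[i] + T.trans_n[i] - T.decay_n[i]) / vol[i];
  }
}

// [[Rcpp::export]]
List cpp_rs_rhs(NumericMatrix conc, List pars, double Pmc) {
  RSPars P = pars_from_list(pars);
  const int n = conc.nrow();
  std::vector<double> cp(n), cd(n), cn(n);
  for (int i = 0; i < n; ++i) {
    cp[i] = conc(i, 0); cd[i] = conc(i, 1); cn[i] = conc(i, 2);
  }
  std::vector<double> vol = shell_volumes(n, P.dr);
  std::vector<double> rho, dcp, dcd, dcn;
  std::vector<char> chi;
  bool fail = false;
  rs_rhs_core(cp, cd, cn, vol, P, Pmc, rho, chi, dcp, dcd, dcn, fail);
  if (fail) stop("oxygen solver did not converge");
  NumericMatrix d(n, 3);
  for (int i = 0; i < n; ++i) {
    d(i, 0) = dcp[i]; d(i, 1) = dcd[i]; d(i, 2) = dcn[i];
  }
  colnames(d) = CharacterVector::create("p", "d", "n");
  return List::create(_["dconc"] = d,
                      _["rho"] = NumericVector(rho.begin(), rho.end()));
}

// ---------------------------------------------------------------------------
// instantaneous irradiation: LQ survival with oxygen-dependent effective dose
static double eff_dose(double d, double rho, double m, double K) {
  return d * (m * rho + K) / (m * (rho + K));
}
static double lq_surv(double deff, double alpha, double beta) {
  return std::exp(-(alpha * deff + beta * deff * deff));
}

// [[Rcpp::export]]
NumericMatrix cpp_irradiate(NumericMatrix conc, NumericVector rho, double dose,
                            double alpha, double beta, double m, double K) {
  const int n = conc.nrow();
  NumericMatrix out(clone(conc));
  for (int i = 0; i < n; ++i) {
    double S = lq_surv(eff_dose(dose, rho[i], m, K), alpha, beta);
    double hit = (1.0 - S) * out(i, 0);
    out(i, 0) -= hit;
    out(i, 1) += hit;
  }
  colnames(out) = CharacterVector::create("p", "d", "n");
  return out;
}

// ---------------------------------------------------------------------------
// Dormand-Prince 5(4) embedded step on the concatenated state
struct StateVec {
  std::vector<double> cp, cd, cn;
};

static void axpy(StateVec& y, const StateVec& y0, double h,
                 const std::vector<const StateVec*>& k,
                 const std::vector<double>& a) {
  const int n = (int)y0.cp.size();
  y.cp = y0.cp; y.cd = y0.cd; y.cn = y0.cn;
  for (size_t s = 0; s < k.size(); ++s) {
    if (a[s] == 0.0) continue;
    for (int i = 0; i < n; ++i) {
      y.cp[i] += h * a[s] * k[s]->cp[i];
      y.cd[i] += h * a[s] * k[s]->cd[i];
      y.cn[i] += h * a[s] * k[s]->cn[i];
    }
  }
}

struct RhsCtx {
  const RSPars* P;
  const std::vector<double>* vol;
  double Pmc;
  bool fail;
};

static void eval_rhs(const StateVec& y, RhsCtx& ctx, StateVec& dy) {
  std::vector<double> rho;
  std::vector<char> chi;
  bool fail = false;
  rs_rhs_core(y.cp, y.cd, y.cn, *(ctx.vol), *(ctx.P), ctx.Pmc, rho, chi,
              dy.cp, dy.cd, dy.cn, fail);
  if (fail) ctx.fail = true;
}

// single DP45 step; returns error norm (scaled), fills y5
static double dp45_step(const StateVec& y0, double h, RhsCtx& ctx,
                        const StateVec& k1, StateVec& y5, double rtol,
                        double atol) {
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

  StateVec k2, k3, k4, k5, k6, k7, ytmp;
  std::vector<const StateVec*> ks;
  std::vector<double> as;

  ks = {&k1}; as = {a21};
  axpy(ytmp, y0, h, ks, as); eval_rhs(ytmp, ctx, k2);
  ks = {&k1, &k2}; as = {a31, a32};
  axpy(ytmp, y0, h, ks, as); eval_rhs(ytmp, ctx, k3);
  ks = {&k1, &k2, &k3}; as = {a41, a42, a43};
  axpy(ytmp, y0, h, ks, as); eval_rhs(ytmp, ctx, k4);
  ks = {&k1, &k2, &k3, &k4}; as = {a51, a52, a53, a54};
  axpy(ytmp, y0, h, ks, as); eval_rhs(ytmp, ctx, k5);
  ks = {&k1, &k2, &k3, &k4, &k5}; as = {a61, a62, a63, a64, a65};
  axpy(ytmp, y0, h, ks, as); eval_rhs(ytmp, ctx, k6);
  ks = {&k1, &k2, &k3, &k4, &k5, &k6}; as = {b1, 0.0, b3, b4, b5, b6};
  axpy(y5, y0, h, ks, as); eval_rhs(y5, ctx, k7);
  if (ctx.fail) return -1.0;

  // embedded 4th-order solution for the error estimate
  StateVec y4;
  ks = {&k1, &k2, &k3, &k4, &k5, &k6, &k7};
  as = {e1, 0.0, e3, e4, e5, e6, e7};
  axpy(y4, y0, h, ks, as);

  const int n = (int)y0.cp.size();
  double err2 = 0.0;
  int cnt = 0;
  for (int i = 0; i < n; ++i) {
    double sc, e;
    sc = atol + rtol * std::max(std::fabs(y0.cp[i]), std::fabs(y5.cp[i]));
    e = (y5.cp[i] - y4.cp[i]) / sc; err2 += e * e; ++cnt;
    sc = atol + rtol * std::max(std::fabs(y0.cd[i]), std::fabs(y5.cd[i]));
    e = (y5.cd[i] - y4.cd[i]) / sc; err2 += e * e; ++cnt;
    sc = atol + rtol * std::max(std::fabs(y0.cn[i]), std::fabs(y5.cn[i]));
    e = (y5.cn[i] - y4.cn[i]) / sc; err2 += e * e; ++cnt;
  }
  return std::sqrt(err2 / cnt);
}

static double radius_of(const StateVec& y, const std::vector<double>& vol) {
  double V = 0.0;
  for (size_t i = 0; i < y.cp.size(); ++i)
    V += vol[i] * (y.cp[i] + y.cd[i] + y.cn[i]);
  return std::cbrt(3.0 * V / (4.0 * PI));
}
static double radius_n(const StateVec& y, const std::vector<double>& vol) {
  double V = 0.0;
  for (size_t i = 0; i < y.cp.size(); ++i) V += vol[i] * y.cn[i];
  return std::cbrt(3.0 * V / (4.0 * PI));
}

// bounds violation beyond the clip tolerance?
static bool violates(const StateVec& y, double tol) {
  for (size_t i = 0; i < y.cp.size(); ++i) {
    if (y.cp[i] < -tol || y.cd[i] < -tol || y.cn[i] < -tol) return true;
    if (y.cp[i] > 1 + tol || y.cd[i] > 1 + tol || y.cn[i] > 1 + tol)
      return true;
    if (y.cp[i] + y.cd[i] + y.cn[i] > 1 + tol) return true;
  }
  return false;
}

static void clip(StateVec& y) {
  for (size_t i = 0; i < y.cp.size(); ++i) {
    if (y.cp[i] < 0) y.cp[i] = 0;
    if (y.cd[i] < 0) y.cd[i] = 0;
    if (y.cn[i] < 0) y.cn[i] = 0;
  }
}

// [[Rcpp::export]]
List cpp_simulate(NumericMatrix conc0, double t0, List pars, List rad,
                  NumericMatrix events, NumericVector sample_times,
                  double t_end, double stop_radius, double last_irr,
                  List control) {
  RSPars P = pars_from_list(pars);
  const double alpha = as<double>(rad["alpha"]), beta = as<double>(rad["beta"]);
  const double oer_m = as<double>(rad["oer_m"]), oer_K = as<double>(rad["oer_K"]);
  const double Pmc1 = as<double>(rad["Pmc1"]), Pmc2 = as<double>(rad["Pmc2"]);
  const double tau_mc = as<double>(rad["tau_mc"]);
  const double rtol = as<double>(control["rtol"]),
               atol = as<double>(control["atol"]);
  const double hmin = as<double>(control["h_min"]);
  const double clip_tol = as<double>(control["clip_tol"]);
  const double ext_thr = as<double>(control["extend_threshold"]);
  const int ext_chunk = as<int>(control["extend_chunk"]);
  const long max_steps = (long)as<double>(control["max_steps"]);
  const bool record_profiles = as<bool>(control["record_profiles"]);

  StateVec y;
  int n = conc0.nrow();
  y.cp.resize(n); y.cd.resize(n); y.cn.resize(n);
  for (int i = 0; i < n; ++i) {
    y.cp[i] = conc0(i, 0); y.cd[i] = conc0(i, 1); y.cn[i] = conc0(i, 2);
  }
  std::vector<double> vol = shell_volumes(n, P.dr);

  // breakpoints: samples, events, mitotic-catastrophe switches, horizon
  struct BP { double t; int kind; double dose; };  // kind: 0 plain, 1 sample, 2 event
  std::vector<BP> bps;
  for (int i = 0; i < sample_times.size(); ++i)
    if (sample_times[i] > t0 + 1e-12 && sample_times[i] <= t_end + 1e-9)
      bps.push_back({sample_times[i], 1, 0.0});
  for (int i = 0; i < events.nrow(); ++i) {
    double te = events(i, 0);
    if (te >= t0 - 1e-12 && te <= t_end + 1e-9) {
      bps.push_back({std::max(te, t0), 2, events(i, 1)});
      if (te + tau_mc < t_end) bps.push_back({te + tau_mc, 0, 0.0});
    }
  }
  if (R_finite(last_irr) && last_irr + tau_mc > t0 && last_irr + tau_mc < t_end)
    bps.push_back({last_irr + tau_mc, 0, 0.0});
  bps.push_back({t_end, 0, 0.0});
  std::stable_sort(bps.begin(), bps.end(),
                   [](const BP& a, const BP& b) { return a.t < b.t; });

  std::vector<double> out_t, out_R, out_Rn, out_Vp, out_Vd, out_Vn;
  List out_conc, out_rho;

  auto vol_of = [&](int type) {
    double V = 0.0;
    for (int i = 0; i < (int)y.cp.size(); ++i)
      V += vol[i] * (type == 0 ? y.cp[i] : type == 1 ? y.cd[i] : y.cn[i]);
    return V;
  };
  auto record = [&](double t) {
    out_t.push_back(t);
    out_R.push_back(radius_of(y, vol));
    out_Rn.push_back(radius_n(y, vol));
    out_Vp.push_back(vol_of(0));
    out_Vd.push_back(vol_of(1));
    out_Vn.push_back(vol_of(2));
    if (record_profiles) {
      int nn = (int)y.cp.size();
      NumericMatrix cm(nn, 3);
      std::vector<double> tot(nn), cons(nn);
      for (int i = 0; i < nn; ++i) {
        cm(i, 0) = y.cp[i]; cm(i, 1) = y.cd[i]; cm(i, 2) = y.cn[i];
        tot[i] = y.cp[i] + y.cd[i] + y.cn[i];
        cons[i] = y.cp[i] + y.cd[i];
      }
      colnames(cm) = CharacterVector::create("p", "d", "n");
      std::vector<double> rho; std::vector<char> chi;
      rs_oxygen_core(cons, surface_index(tot), P.dr, P.D, P.rho0, P.rho_an,
                     P.a_h, P.oxy_max_iter, rho, chi);
      out_conc.push_back(cm);
      out_rho.push_back(NumericVector(rho.begin(), rho.end()));
    }
  };
  auto extend_if_needed = [&]() {
    int nn = (int)y.cp.size();
    double tot_last = y.cp[nn - 1] + y.cd[nn - 1] + y.cn[nn - 1];
    if (tot_last > ext_thr) {
      y.cp.resize(nn + ext_chunk, 0.0);
      y.cd.resize(nn + ext_chunk, 0.0);
      y.cn.resize(nn + ext_chunk, 0.0);
      vol = shell_volumes(nn + ext_chunk, P.dr);
    }
  };
  auto pmc_now = [&](double t) {
    if (!R_finite(last_irr)) return Pmc1;
    return (t - last_irr < tau_mc) ? Pmc1 : Pmc2;
  };

  extend_if_needed();
  if (sample_times.size() > 0 && sample_times[0] <= t0 + 1e-12) record(t0);

  double t = t0;
  double h = as<double>(control["h_init"]);
  long nacc = 0, nrej = 0, nsteps = 0;
  std::string status = "ok";
  double stop_time = NA_REAL;
  bool stopped = false;

  RhsCtx ctx; ctx.P = &P; ctx.vol = &vol; ctx.fail = false;

  for (size_t ib = 0; ib < bps.size() && !stopped; ++ib) {
    double t_target = bps[ib].t;
    while (t < t_target - 1e-9 && !stopped) {
      if (++nsteps > max_steps) { status = "max_steps"; goto done; }
      double hs = std::min(h, t_target - t);
      ctx.Pmc = pmc_now(t);
      StateVec k1, y5;
      ctx.fail = false;
      eval_rhs(y, ctx, k1);
      if (ctx.fail) { status = "oxygen_failure"; goto done; }
      double err = dp45_step(y, hs, ctx, k1, y5, rtol, atol);
      if (err < 0) { status = "oxygen_failure"; goto done; }
      bool ok = err <= 1.0 && !violates(y5, clip_tol);
      if (ok) {
        // stopping on a target radius: bisect the step
        if (R_finite(stop_radius) && radius_of(y5, vol) >= stop_radius) {
          double lo = 0.0, hi = hs;
          StateVec ymid;
          while (hi - lo > 1e-4 * std::max(1.0, t + hi)) {
            double mid = 0.5 * (lo + hi);
            dp45_step(y, mid, ctx, k1, ymid, rtol, atol);
            if (radius_of(ymid, vol) >= stop_radius) hi = mid; else lo = mid;
          }
          dp45_step(y, hi, ctx, k1, ymid, rtol, atol);
          y = ymid; clip(y);
          t += hi;
          stop_time = t;
          stopped = true;
          status = "stopped";
          break;
        }
        y = y5; clip(y);
        t += hs;
        ++nacc;
        extend_if_needed();
        ctx.vol = &vol;
        double fac = (err > 1e-12) ? 0.9 * std::pow(err, -0.2) : 5.0;
        fac = std::min(5.0, std::max(0.2, fac));
        h = hs * fac;
        if (h < hmin) h = hmin;
      } else {
        ++nrej;
        h = hs / 2.0;
        if (h < hmin) { status = "step_underflow"; goto done; }
      }
    }
    if (stopped) break;
    t = t_target;
    if (bps[ib].kind == 2) {  // irradiation event
      int nn = (int)y.cp.size();
      std::vector<double> tot(nn), cons(nn);
      for (int i = 0; i < nn; ++i) {
        tot[i] = y.cp[i] + y.cd[i] + y.cn[i];
        cons[i] = y.cp[i] + y.cd[i];
      }
      std::vector<double> rho; std::vector<char> chi;
      rs_oxygen_core(cons, surface_index(tot), P.dr, P.D, P.rho0, P.rho_an,
                     P.a_h, P.oxy_max_iter, rho, chi);
      for (int i = 0; i < nn; ++i) {
        double S = lq_surv(eff_dose(bps[ib].dose, rho[i], oer_m, oer_K),
                           alpha, beta);
        double hit = (1.0 - S) * y.cp[i];
        y.cp[i] -= hit;
        y.cd[i] += hit;
      }
      last_irr = t;
    }
    if (bps[ib].kind == 1) record(t);
  }
done:;
  int nn = (int)y.cp.size();
  NumericMatrix cf(nn, 3);
  for (int i = 0; i < nn; ++i) {
    cf(i, 0) = y.cp[i]; cf(i, 1) = y.cd[i]; cf(i, 2) = y.cn[i];
  }
  colnames(cf) = CharacterVector::create("p", "d", "n");
  return List::create(
      _["time"] = NumericVector(out_t.begin(), out_t.end()),
      _["R"] = NumericVector(out_R.begin(), out_R.end()),
      _["Rn"] = NumericVector(out_Rn.begin(), out_Rn.end()),
      _["Vp"] = NumericVector(out_Vp.begin(), out_Vp.end()),
      _["Vd"] = NumericVector(out_Vd.begin(), out_Vd.end()),
      _["Vn"] = NumericVector(out_Vn.begin(), out_Vn.end()),
      _["conc_snapshots"] = out_conc, _["rho_snapshots"] = out_rho,
      _["conc_final"] = cf, _["t_final"] = t, _["n_shells"] = nn,
      _["status"] = status, _["n_accept"] = (double)nacc,
      _["n_reject"] = (double)nrej, _["stop_time"] = stop_time,
      _["last_irr"] = last_irr);
}
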