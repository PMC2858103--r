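#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Sigmoidal pancreatic response (G/G*)^gamma / (1 + (G/G*)^gamma).
// gamma == 0 degenerates to the constant 1/2 (no response to glucose).
static inline double phi_resp(double G, double Gstar, double gamma) {
  if (gamma == 0.0) return 0.5;
  double r = std::pow(G / Gstar, gamma);
  return r / (1.0 + r);
}

// Dense solution history for the lagged glucose term: node times, values and
// derivatives appended at every accepted RK step; cubic Hermite between nodes.
struct History {
  std::vector<double> t, g, dg;
  double g_pre;  // constant pre-bolus history G_b on [-tau, 0)

  // The solution jumps at t = 0, so the lagged term is two-valued at s == 0:
  // a step ending at t = tau must see the pre-bolus limit (from_left), while
  // the step starting at t = tau already sees the post-bolus value.
  double lag(double s, bool from_left) const {
    if (s < 0.0 || (from_left && s == 0.0)) return g_pre;
    // binary search for the interval containing s
    size_t lo = 0, hi = t.size() - 1;
    if (s >= t[hi]) return g[hi];
    while (hi - lo > 1) {
      size_t mid = (lo + hi) / 2;
      if (t[mid] <= s) lo = mid; else hi = mid;
    }
    double h = t[hi] - t[lo];
    if (h <= 0.0) return g[lo];
    double u = (s - t[lo]) / h;
    double h00 = (1.0 + 2.0 * u) * (1.0 - u) * (1.0 - u);
    double h10 = u * (1.0 - u) * (1.0 - u);
    double h01 = u * u * (3.0 - 2.0 * u);
    double h11 = u * u * (u - 1.0);
    return h00 * g[lo] + h * h10 * dg[lo] + h01 * g[hi] + h * h11 * dg[hi];
  }
};

struct SDMPars {
  double kxgi, kxi, tau, gamma, gstar, gb, ib;
  double tgh_vg;     // T_gh / V_g  = K_xgI * I_b * G_b
  double tig_vi;     // T_igmax / V_i = K_xi * I_b / phi(G_b)
};

static inline void sdm_rhs_c(double G, double I, double Glag, const SDMPars &p,
                             double &dG, double &dI) {
  dG = -p.kxgi * I * G + p.tgh_vg;
  dI = -p.kxi * I + p.tig_vi * phi_resp(Glag, p.gstar, p.gamma);
}

//' @noRd
// [[Rcpp::export(name = ".sdm_integrate_cpp")]]
NumericMatrix sdm_integrate_cpp(NumericVector out_times,
                                double kxgi, double kxi, double tau,
                                double gamma, double gdelta, double ideltag,
                                double gstar, double gb, double ib,
                                double hmax) {
  SDMPars p;
  p.kxgi = kxgi; p.kxi = kxi; p.tau = tau; p.gamma = gamma;
  p.gstar = gstar; p.gb = gb; p.ib = ib;
  p.tgh_vg = kxgi * ib * gb;
  double phib = phi_resp(gb, gstar, gamma);
  if (phib <= 0.0) stop("degenerate baseline: pancreatic response is zero at G_b");
  p.tig_vi = kxi * ib / phib;

  int nout = out_times.size();
  double t_end = 0.0;
  for (int i = 0; i < nout; ++i) t_end = std::max(t_end, out_times[i]);

  // node set: output times plus breakpoints at the first multiples of tau.
  // The initial jump propagates a discontinuity whose order rises by one at
  // each multiple (C^{k-1} at k*tau), so after 8 multiples the solution is
  // far smoother than the scheme's order and breakpoints are unnecessary —
  // this also keeps the node count bounded as tau -> 0.
  std::vector<double> nodes(out_times.begin(), out_times.end());
  nodes.push_back(0.0);
  if (tau > 0.0) {
    int kmax = 8;
    for (double b = tau; b < t_end && kmax > 0; b += tau, --kmax)
      nodes.push_back(b);
  }
  std::sort(nodes.begin(), nodes.end());
  nodes.erase(std::unique(nodes.begin(), nodes.end(),
                          [](double a, double b) { return std::abs(a - b) < 1e-12; }),
              nodes.end());

  History H;
  H.g_pre = gb;
  double G = gb + gdelta, I = ib + ideltag * gdelta;
  double t = 0.0;
  double dG0, dI0;
  double glag0 = (tau > 0.0) ? gb : G;
  sdm_rhs_c(G, I, glag0, p, dG0, dI0);
  H.t.push_back(0.0); H.g.push_back(G); H.dg.push_back(dG0);

  NumericMatrix out(nout, 2);
  for (int i = 0; i < nout; ++i) {
    if (out_times[i] <= 0.0) { out(i, 0) = G; out(i, 1) = I; }
  }

  for (size_t k = 0; k + 1 < nodes.size(); ++k) {
    double t0 = nodes[k], t1 = nodes[k + 1];
    if (t1 <= 0.0) continue;
    int nstep = std::max(1, (int)std::ceil((t1 - t0) / hmax));
    double h = (t1 - t0) / nstep;
    for (int s = 0; s < nstep; ++s) {
      double k1G, k1I, k2G, k2I, k3G, k3I, k4G, k4I;
      double lag1, lag2, lag4;
      if (tau > 0.0) {
        lag1 = H.lag(t - tau, false);
        lag2 = H.lag(t + 0.5 * h - tau, false);
        lag4 = H.lag(t + h - tau, true);
      } else {
        lag1 = lag2 = lag4 = 0.0;  // overwritten below with current G
      }
      if (tau > 0.0) {
        sdm_rhs_c(G, I, lag1, p, k1G, k1I);
        sdm_rhs_c(G + 0.5 * h * k1G, I + 0.5 * h * k1I, lag2, p, k2G, k2I);
        sdm_rhs_c(G + 0.5 * h * k2G, I + 0.5 * h * k2I, lag2, p, k3G, k3I);
        sdm_rhs_c(G + h * k3G, I + h * k3I, lag4, p, k4G, k4I);
      } else {
        double Ga;
        sdm_rhs_c(G, I, G, p, k1G, k1I);
        Ga = G + 0.5 * h * k1G;
        sdm_rhs_c(Ga, I + 0.5 * h * k1I, Ga, p, k2G, k2I);
        Ga = G + 0.5 * h * k2G;
        sdm_rhs_c(Ga, I + 0.5 * h * k2I, Ga, p, k3G, k3I);
        Ga = G + h * k3G;
        sdm_rhs_c(Ga, I + h * k3I, Ga, p, k4G, k4I);
      }
      G += h / 6.0 * (k1G + 2.0 * k2G + 2.0 * k3G + k4G);
      I += h / 6.0 * (k1I + 2.0 * k2I + 2.0 * k3I + k4I);
      t = t0 + (s + 1) * h;
      if (!R_finite(G) || !R_finite(I))
        stop("SDM integration failed near t = %f min", t);
      double dG, dI;
      double lagn = (tau > 0.0) ? H.lag(t - tau, false) : G;
      sdm_rhs_c(G, I, lagn, p, dG, dI);
      H.t.push_back(t); H.g.push_back(G); H.dg.push_back(dG);
    }
    for (int i = 0; i < nout; ++i) {
      if (std::abs(out_times[i] - t1) < 1e-12) { out(i, 0) = G; out(i, 1) = I; }
    }
  }
  return out;
}

// piecewise-linear forcing held constant outside the knot range
static inline double interp_lin(const std::vector<double> &xt,
                                const std::vector<double> &xv, double s) {
  size_t n = xt.size();
  if (s <= xt[0]) return xv[0];
  if (s >= xt[n - 1]) return xv[n - 1];
  size_t lo = 0, hi = n - 1;
  while (hi - lo > 1) {
    size_t mid = (lo + hi) / 2;
    if (xt[mid] <= s) lo = mid; else hi = mid;
  }
  double u = (s - xt[lo]) / (xt[hi] - xt[lo]);
  return (1.0 - u) * xv[lo] + u * xv[hi];
}

//' @noRd
// [[Rcpp::export(name = ".mm_integrate_cpp")]]
NumericVector mm_integrate_cpp(NumericVector out_times,
                               double p1, double p2, double p3, double g0,
                               double gb, double ib,
                               NumericVector ins_t, NumericVector ins_v,
                               double t_start, double hmax) {
  std::vector<double> it(ins_t.begin(), ins_t.end());
  std::vector<double> iv(ins_v.begin(), ins_v.end());
  int nout = out_times.size();
  double t_end = t_start;
  for (int i = 0; i < nout; ++i) t_end = std::max(t_end, out_times[i]);

  // nodes: output times and insulin knots (kinks in the forcing function)
  std::vector<double> nodes(out_times.begin(), out_times.end());
  nodes.push_back(t_start);
  for (double k : it) if (k > t_start && k < t_end) nodes.push_back(k);
  std::sort(nodes.begin(), nodes.end());
  nodes.erase(std::unique(nodes.begin(), nodes.end(),
                          [](double a, double b) { return std::abs(a - b) < 1e-12; }),
              nodes.end());

  double G = g0, X = 0.0, t = t_start;
  NumericVector out(nout);
  for (int i = 0; i < nout; ++i) {
    if (std::abs(out_times[i] - t_start) < 1e-12) out[i] = G;
  }
  auto rhs = [&](double tt, double Gc, double Xc, double &dG, double &dX) {
    double ins = interp_lin(it, iv, tt);
    dG = -(p1 + Xc) * Gc + p1 * gb;
    dX = -p2 * Xc + p3 * (ins - ib);
  };
  for (size_t k = 0; k + 1 < nodes.size(); ++k) {
    double t0 = nodes[k], t1 = nodes[k + 1];
    if (t1 <= t_start) continue;
    int nstep = std::max(1, (int)std::ceil((t1 - t0) / hmax));
    double h = (t1 - t0) / nstep;
    for (int s = 0; s < nstep; ++s) {
      double k1G, k1X, k2G, k2X, k3G, k3X, k4G, k4X;
      rhs(t, G, X, k1G, k1X);
      rhs(t + 0.5 * h, G + 0.5 * h * k1G, X + 0.5 * h * k1X, k2G, k2X);
      rhs(t + 0.5 * h, G + 0.5 * h * k2G, X + 0.5 * h * k2X, k3G, k3X);
      rhs(t + h, G + h * k3G, X + h * k3X, k4G, k4X);
      G += h / 6.0 * (k1G + 2.0 * k2G + 2.0 * k3G + k4G);
      X += h / 6.0 * (k1X + 2.0 * k2X + 2.0 * k3X + k4X);
      t = t0 + (s + 1) * h;
      if (!R_finite(G) || !R_finite(X))
        stop("Minimal Model integration failed near t = %f min", t);
    }
    for (int i = 0; i < nout; ++i) {
      if (std::abs(out_times[i] - t1) < 1e-12) out[i] = G;
    }
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".sdm_objective_cpp")]]
double sdm_objective_cpp(NumericVector ltheta, NumericVector times,
                         NumericVector y_glucose, NumericVector y_insulin,
                         double cv_g, double cv_i,
                         double gstar, double gb, double ib, double hmax) {
  // ltheta: log of (K_xgI, K_xi, tau_g, gamma, G_delta, I_deltaG)
  NumericMatrix m;
  try {
    m = sdm_integrate_cpp(times, std::exp(ltheta[0]), std::exp(ltheta[1]),
                          std::exp(ltheta[2]), std::exp(ltheta[3]),
                          std::exp(ltheta[4]), std::exp(ltheta[5]),
                          gstar, gb, ib, hmax);
  } catch (...) {
    return 1e12;
  }
  int n = times.size();
  double ss = 0.0;
  for (int i = 0; i < n; ++i) {
    double gh = m(i, 0), ih = m(i, 1);
    if (!R_finite(gh) || !R_finite(ih) || gh <= 0.0 || ih <= 0.0) return 1e12;
    double rg = (y_glucose[i] - gh) / (cv_g * gh);
    double ri = (y_insulin[i] - ih) / (cv_i * ih);
    ss += rg * rg + ri * ri;
  }
  return R_finite(ss) ? ss : 1e12;
}

//' @noRd
// [[Rcpp::export(name = ".sdm_gradient_cpp")]]
NumericVector sdm_gradient_cpp(NumericVector ltheta, NumericVector times,
                               NumericVector y_glucose, NumericVector y_insulin,
                               double cv_g, double cv_i,
                               double gstar, double gb, double ib, double hmax,
                               double step) {
  int p = ltheta.size();
  NumericVector g(p);
  for (int k = 0; k < p; ++k) {
    NumericVector lp = clone(ltheta), lm = clone(ltheta);
    lp[k] += step; lm[k] -= step;
    double fp = sdm_objective_cpp(lp, times, y_glucose, y_insulin, cv_g, cv_i,
                                  gstar, gb, ib, hmax);
    double fm = sdm_objective_cpp(lm, times, y_glucose, y_insulin, cv_g, cv_i,
                                  gstar, gb, ib, hmax);
    g[k] = (fp - fm) / (2.0 * step);
  }
  return g;
}
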