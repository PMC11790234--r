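// Compiled right-hand sides for the surrogate families, exposed to deSolve
// through its compiled-function interface. The active model specification is
// staged in file-static storage by .stage_rhs_config() immediately before an
// integration; solvers run single-threaded so this is race-free.
#include <Rcpp.h>
#include <R_ext/Rdynload.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Spec {
  int family = 0; // 1 gma, 2 ssystem, 3 taylor, 4 mechanistic
  int n = 0, m = 0, order = 1;
  std::vector<double> alpha, beta, g, h;      // gma/ssystem (row-major m x n / n x n)
  std::vector<double> stoich;                 // n x m row-major
  std::vector<double> x0, J, H;               // taylor (J row-major, H: n blocks)
  // mechanistic: per process k: kind, and packed params
  std::vector<int> pkind, psub, pinh, pvar;
  std::vector<double> pv1, pv2, pv3;          // vmax/km/ki or alpha or k1/k2
  std::vector<double> pg;                     // power-law orders, m x n row-major
  // control
  int ctrl = 0;                               // 0 none, 1 removal, 2 inflow
  std::vector<double> kappa;                  // length n
  int qvar = 0;
  double Q = 0, outflow = 0;
  std::vector<int> outmask;
};

Spec spec;

inline double powx(double x, double g) {
  if (g == 0.0) return 1.0;
  if (x == 0.0) return g > 0 ? 0.0 : R_NaN;
  return std::pow(x, g);
}

} // namespace

// [[Rcpp::export(name = ".stage_rhs_config")]]
void stage_rhs_config(List s) {
  Spec sp;
  sp.family = as<int>(s["family"]);
  sp.n = as<int>(s["n"]);
  if (s.containsElementNamed("m")) sp.m = as<int>(s["m"]);
  if (s.containsElementNamed("order")) sp.order = as<int>(s["order"]);
  auto getv = [&](const char *name, std::vector<double> &out) {
    if (s.containsElementNamed(name)) {
      NumericVector v = s[name];
      out.assign(v.begin(), v.end());
    }
  };
  auto geti = [&](const char *name, std::vector<int> &out) {
    if (s.containsElementNamed(name)) {
      IntegerVector v = s[name];
      out.assign(v.begin(), v.end());
    }
  };
  getv("alpha", sp.alpha); getv("beta", sp.beta);
  getv("g", sp.g); getv("h", sp.h);
  getv("stoich", sp.stoich);
  getv("x0", sp.x0); getv("J", sp.J); getv("H", sp.H);
  geti("pkind", sp.pkind); geti("psub", sp.psub); geti("pinh", sp.pinh);
  geti("pvar", sp.pvar);
  getv("pv1", sp.pv1); getv("pv2", sp.pv2); getv("pv3", sp.pv3);
  getv("pg", sp.pg);
  sp.ctrl = as<int>(s["ctrl"]);
  getv("kappa", sp.kappa);
  if (s.containsElementNamed("qvar")) sp.qvar = as<int>(s["qvar"]);
  if (s.containsElementNamed("Q")) sp.Q = as<double>(s["Q"]);
  if (s.containsElementNamed("outflow")) sp.outflow = as<double>(s["outflow"]);
  geti("outmask", sp.outmask);
  spec = sp;
}

extern "C" void abmctrl_deriv(int *neq, double *t, double *y, double *ydot,
                              double *yout, int *ip) {
  const int n = spec.n;
  for (int i = 0; i < n; ++i) ydot[i] = 0.0;

  if (spec.family == 1) { // GMA
    for (int j = 0; j < spec.m; ++j) {
      double f = spec.alpha[j];
      for (int k = 0; k < n; ++k) f *= powx(y[k], spec.g[j * n + k]);
      for (int i = 0; i < n; ++i) ydot[i] += spec.stoich[i * spec.m + j] * f;
    }
  } else if (spec.family == 2) { // S-system
    for (int i = 0; i < n; ++i) {
      double in = spec.alpha[i], out = spec.beta[i];
      for (int k = 0; k < n; ++k) {
        in *= powx(y[k], spec.g[i * n + k]);
        out *= powx(y[k], spec.h[i * n + k]);
      }
      ydot[i] = in - out;
    }
  } else if (spec.family == 3) { // Taylor
    std::vector<double> d(n);
    for (int k = 0; k < n; ++k) d[k] = y[k] - spec.x0[k];
    for (int i = 0; i < n; ++i) {
      double v = 0;
      for (int k = 0; k < n; ++k) v += spec.J[i * n + k] * d[k];
      if (spec.order == 2) {
        double q = 0;
        const double *Hi = &spec.H[(size_t)i * n * n];
        for (int a = 0; a < n; ++a)
          for (int b = 0; b < n; ++b) q += d[a] * Hi[a * n + b] * d[b];
        v += 0.5 * q;
      }
      ydot[i] = v;
    }
  } else if (spec.family == 4) { // mechanistic
    for (int j = 0; j < spec.m; ++j) {
      double f = 0;
      if (spec.pkind[j] == 0) { // power law
        f = spec.pv1[j];
        for (int k = 0; k < n; ++k) f *= powx(y[k], spec.pg[j * n + k]);
      } else if (spec.pkind[j] == 1) { // Michaelis-Menten
        double sY = y[spec.psub[j]];
        f = spec.pv1[j] * sY / (spec.pv2[j] + sY);
        if (spec.pinh[j] >= 0) {
          f *= spec.pv3[j] / (spec.pv3[j] + y[spec.pinh[j]]);
        }
      } else { // logistic growth
        double xv = y[spec.pvar[j]];
        f = spec.pv1[j] * xv - spec.pv2[j] * xv * xv;
      }
      for (int i = 0; i < n; ++i) ydot[i] += spec.stoich[i * spec.m + j] * f;
    }
  }

  if (spec.ctrl == 1) {
    for (int i = 0; i < n; ++i) ydot[i] -= spec.kappa[i] * y[i];
  } else if (spec.ctrl == 2) {
    ydot[spec.qvar] += spec.Q;
    if (spec.outflow > 0) {
      for (int i = 0; i < n; ++i) {
        if (spec.outmask.empty() || spec.outmask[i]) {
          ydot[i] -= spec.outflow * y[i];
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".rhs_func_ptr")]]
SEXP rhs_func_ptr() {
  return R_MakeExternalPtrFn((DL_FUNC)&abmctrl_deriv, R_NilValue, R_NilValue);
}
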