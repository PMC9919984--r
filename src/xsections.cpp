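// R-facing wrappers around the closed-form channel formulas in xsections.h.
// All energies in eV, cross sections in m^2, dipoles already converted to
// atomic units (squared) by the R layer.

#include <Rcpp.h>
#include "xsections.h"

using namespace Rcpp;

static std::vector<double> as_vec(const NumericVector& x) {
  return std::vector<double>(x.begin(), x.end());
}

// [[Rcpp::export]]
NumericVector xs_dipole_total_cpp(NumericVector E, NumericVector d2au, NumericVector dw) {
  const int n = E.size(), m = d2au.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < m; ++j) s += seymc::dipole_sigma(E[i], d2au[j], dw[j]);
    out[i] = s;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector xs_dipole_terms_cpp(double E, NumericVector d2au, NumericVector dw) {
  const int m = d2au.size();
  NumericVector out(m);
  for (int j = 0; j < m; ++j) out[j] = seymc::dipole_sigma(E, d2au[j], dw[j]);
  return out;
}

// [[Rcpp::export]]
NumericVector dcs_dipole_cpp(NumericVector theta, double E, NumericVector d2au,
                             NumericVector dw) {
  const int n = theta.size(), m = d2au.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double h = std::sin(0.5 * theta[i]);  // t = 1 - cos = 2 sin^2(theta/2),
    const double t = 2.0 * h * h;               // full relative precision near 0
    double s = 0.0;
    for (int j = 0; j < m; ++j) s += seymc::dipole_dcs(t, E, d2au[j], dw[j]);
    out[i] = s;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cum_dipole_cpp(NumericVector theta, double E, NumericVector d2au,
                             NumericVector dw) {
  const int n = theta.size();
  const std::vector<double> d2 = as_vec(d2au), w = as_vec(dw);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double h = std::sin(0.5 * theta[i]);  // t = 1 - cos = 2 sin^2(theta/2),
    const double t = 2.0 * h * h;               // full relative precision near 0
    const double p = seymc::dipole_cum_t(t, E, d2, w);
    if (p < 0.0) stop("no open channel at this energy");
    out[i] = p;
  }
  return out;
}

// Inverse-transform sampling of the polar angle for the summed multi-axis
// dipole channel: bisection on log(1 - cos(theta)). At keV energies the
// forward peak concentrates half of the probability at 1 - cos(theta) below
// 1e-12, so bisecting cos(theta) directly would stall at machine precision.
// [[Rcpp::export]]
NumericVector sample_dipole_angle_cpp(NumericVector mu, double E, NumericVector d2au,
                                      NumericVector dw) {
  const int n = mu.size();
  const std::vector<double> d2 = as_vec(d2au), w = as_vec(dw);
  if (seymc::dipole_cum_t(2.0, E, d2, w) < 0.0)
    stop("no open channel at this energy");

  // lower end of the log-bracket: far below the narrowest forward peak
  double qmax = 0.0;
  for (std::size_t j = 0; j < d2.size(); ++j) {
    if (d2[j] <= 0.0 || E <= w[j] || w[j] <= 0.0) continue;
    qmax = std::max(qmax, seymc::dipole_qfactor(E, w[j]));
  }
  const double s_lo0 = std::log(1e-18 / qmax), s_hi0 = std::log(2.0);

  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double u = mu[i];
    if (u < 0.0 || u > 1.0) stop("mu must lie in [0, 1]");
    if (u == 0.0) { out[i] = 0.0; continue; }
    if (u == 1.0) { out[i] = M_PI; continue; }
    double lo = s_lo0, hi = s_hi0;
    for (int it = 0; it < 300; ++it) {
      const double mid = 0.5 * (lo + hi);
      const double p = seymc::dipole_cum_t(std::exp(mid), E, d2, w);
      if (p < u) lo = mid; else hi = mid;
      if (hi - lo < 1e-14) break;
    }
    const double t = std::exp(0.5 * (lo + hi));
    out[i] = 2.0 * std::asin(std::sqrt(0.5 * t));  // theta from t = 1 - cos(theta)
  }
  return out;
}

// [[Rcpp::export]]
NumericVector xs_beb_cpp(NumericVector E, double B, double U, double Nocc, double Q) {
  const int n = E.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = seymc::beb_sigma(E[i], B, U, Nocc, Q);
  return out;
}

// [[Rcpp::export]]
NumericVector xs_ionization_cpp(NumericVector E, NumericVector B, NumericVector U,
                                NumericVector Nocc, NumericVector Q) {
  const int n = E.size(), m = B.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < m; ++j) s += seymc::beb_sigma(E[i], B[j], U[j], Nocc[j], Q[j]);
    out[i] = s;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cum_beb_cpp(NumericVector W, double E, double B, double Q) {
  const int n = W.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = seymc::beb_cum(W[i], E, B, Q);
  return out;
}

// [[Rcpp::export]]
NumericVector sample_beb_cpp(NumericVector mu, double E, double B, double Q) {
  const int n = mu.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = seymc::beb_invert(mu[i], E, B, Q);
  return out;
}

// [[Rcpp::export]]
NumericVector xs_phonon_cpp(NumericVector E, double ndens, double hw, double eps0,
                            double epsinf, double T) {
  const int n = E.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = seymc::phonon_sigma(E[i], ndens, hw, eps0, epsinf, T);
  return out;
}

// [[Rcpp::export]]
NumericVector phonon_costheta_cpp(NumericVector mu, double E, double Ep) {
  const int n = mu.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = seymc::phonon_costheta(mu[i], E, Ep);
  return out;
}

// [[Rcpp::export]]
NumericVector xs_polaron_cpp(NumericVector E, double ndens, double strap, double gtrap) {
  const int n = E.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = seymc::polaron_sigma(E[i], ndens, strap, gtrap);
  return out;
}
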