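#ifndef SEYMC_XSECTIONS_H
#define SEYMC_XSECTIONS_H

#include <cmath>
#include <vector>

namespace seymc {

// Single source of truth for the constants used by the closed-form channel
// formulas. a0 and the Rydberg energy are the rounded values the model is
// defined with; the Hartree energy is only used to form wavenumbers in
// atomic units.
constexpr double A0_M = 0.529e-10;           // Bohr radius, m
constexpr double A0SQ_M2 = A0_M * A0_M;      // m^2 per a0^2
constexpr double RYDBERG_EV = 13.6;          // eV
constexpr double HARTREE_EV = 27.211386245988; // eV
constexpr double KBOLTZ_EV = 8.617333262e-5; // eV / K

// ---------------------------------------------------------------------------
// Born charge--dipole channel (elastic rotational and electronic excitation
// share the same closed form: sigma = (8 pi / 3 k^2) D^2 ln[(k+k')/(k-k')]).
// d2au: squared dipole (or transition dipole) in atomic units; dw: channel
// threshold / energy transfer in eV. Energies in eV, cross sections in m^2.
// ---------------------------------------------------------------------------

// ln[(k + k')/(k - k')] computed cancellation-free via x = dw/E:
// (k+k')/(k-k') = (1+s)^2 / x with s = k'/k = sqrt(1-x).
inline double dipole_lnratio(double E, double dw) {
  const double x = dw / E;
  const double s = std::sqrt(1.0 - x);
  return 2.0 * std::log1p(s) - std::log(x);
}

inline double dipole_sigma(double E, double d2au, double dw) {
  if (d2au <= 0.0 || E <= dw || dw <= 0.0) return 0.0;
  const double k2 = 2.0 * E / HARTREE_EV;  // k^2 in 1/a0^2
  return 8.0 * M_PI / (3.0 * k2) * d2au * dipole_lnratio(E, dw) * A0SQ_M2;
}

// q = 2 k k' / (k - k')^2, so that the per-axis angular factor is
// ln[(k^2 + k'^2 - 2 k k' cos(theta)) / (k - k')^2] = log1p(q * t), t = 1 - cos(theta).
inline double dipole_qfactor(double E, double dw) {
  const double x = dw / E;
  const double s = std::sqrt(1.0 - x);
  const double onep = 1.0 + s;
  return 2.0 * s * onep * onep / (x * x);
}

// Differential cross section d sigma / d Omega for one axis, m^2 / sr.
// (4 D^2 / 3) (k'/k) / (k^2 + k'^2 - 2 k k' cos(theta)); the denominator is
// written as k^2 [x^2/(1+s)^2 + 2 s t] to stay accurate in the forward peak.
inline double dipole_dcs(double t, double E, double d2au, double dw) {
  if (d2au <= 0.0 || E <= dw || dw <= 0.0) return 0.0;
  const double x = dw / E;
  const double s = std::sqrt(1.0 - x);
  const double onep = 1.0 + s;
  const double k2 = 2.0 * E / HARTREE_EV;
  const double denom = k2 * (x * x / (onep * onep) + 2.0 * s * t);
  return (4.0 * d2au / 3.0) * s / denom * A0SQ_M2;
}

// Normalized cumulative probability of the polar deflection angle for the
// summed multi-axis channel, as a function of t = 1 - cos(theta).
inline double dipole_cum_t(double t, double E,
                           const std::vector<double>& d2au,
                           const std::vector<double>& dw) {
  double num = 0.0, den = 0.0;
  for (std::size_t i = 0; i < d2au.size(); ++i) {
    if (d2au[i] <= 0.0 || E <= dw[i] || dw[i] <= 0.0) continue;
    const double q = dipole_qfactor(E, dw[i]);
    num += d2au[i] * std::log1p(q * t);
    den += d2au[i] * std::log1p(2.0 * q);
  }
  if (den <= 0.0) return -1.0;  // no open channel; caller must handle
  return num / den;
}

// Exact single-axis inversion: t such that log1p(q t) = P * log1p(2 q).
inline double dipole_invert_single(double P, double E, double dw) {
  const double q = dipole_qfactor(E, dw);
  return std::expm1(P * std::log1p(2.0 * q)) / q;
}

// ---------------------------------------------------------------------------
// Binary-Encounter Bethe ionization channel.
// ---------------------------------------------------------------------------

inline double beb_sigma(double E, double B, double U, double Nocc, double Q) {
  const double t = E / B;
  if (t <= 1.0) return 0.0;
  const double u = U / B;
  const double S = 4.0 * M_PI * A0SQ_M2 * Nocc * (RYDBERG_EV / B) * (RYDBERG_EV / B);
  const double lnt = std::log(t);
  const double bracket = (2.0 - Q) * (1.0 - 1.0 / t - lnt / (t + 1.0))
                       + 0.5 * Q * lnt * (1.0 - 1.0 / (t * t));
  return S / (t + u + 1.0) * bracket;
}

// Cumulative probability of the ejected-electron energy W (HOMO sampling in
// the transport engine); the S/(t+u+1) prefactor cancels in the ratio.
inline double beb_cum(double W, double E, double B, double Q) {
  const double t = E / B;
  const double w = W / B;
  const double lnt = std::log(t);
  const double f1 = (Q - 2.0) / (t + 1.0) * (std::log((w + 1.0) / (t - w)) + lnt);
  const double f2 = (2.0 - Q) * (1.0 / (t - w) - 1.0 / (w + 1.0) + 1.0 - 1.0 / t);
  const double f3 = 0.5 * Q * lnt
      * (1.0 / ((t - w) * (t - w)) - 1.0 / ((w + 1.0) * (w + 1.0)) + 1.0 - 1.0 / (t * t));
  const double norm = (2.0 - Q) * (1.0 - 1.0 / t - lnt / (t + 1.0))
                    + 0.5 * Q * lnt * (1.0 - 1.0 / (t * t));
  return (f1 + f2 + f3) / norm;
}

// Bisection inversion of beb_cum on W in [0, (E - B)/2].
inline double beb_invert(double mu, double E, double B, double Q) {
  double lo = 0.0, hi = 0.5 * (E - B);
  if (mu <= 0.0) return lo;
  if (mu >= 1.0) return hi;
  for (int it = 0; it < 200; ++it) {
    const double mid = 0.5 * (lo + hi);
    const double p = beb_cum(mid, E, B, Q);
    if (p < mu) lo = mid; else hi = mid;
    if (hi - lo <= 1e-10 * (1.0 + hi)) break;
  }
  return 0.5 * (lo + hi);
}

// ---------------------------------------------------------------------------
// Froehlich electron--phonon channel.
// ---------------------------------------------------------------------------

inline double bose_n(double hw, double T) {
  return 1.0 / std::expm1(hw / (KBOLTZ_EV * T));
}

inline double phonon_sigma(double E, double ndens, double hw,
                           double eps0, double epsinf, double T) {
  if (E <= hw) return 0.0;
  const double coupling = (eps0 - epsinf) / (eps0 * epsinf);
  return (1.0 / ndens) * (1.0 / A0_M) * 0.5 * (bose_n(hw, T) + 1.0)
       * coupling * (hw / E) * dipole_lnratio(E, hw);
}

// Deflection cosine after phonon creation; exact endpoints cos=1 at mu=0 and
// cos=-1 at mu=1. sqrt(E) - sqrt(E') is formed as (E - E')/(sqrt E + sqrt E')
// to avoid cancellation for small energy transfer.
inline double phonon_costheta(double mu, double E, double Ep) {
  const double rt = std::sqrt(E), rtp = std::sqrt(Ep);
  const double diff = (E - Ep) / (rt + rtp);
  const double ratio = (rt + rtp) / diff;
  const double B = ratio * ratio;
  const double Bmu = std::pow(B, mu);
  double c = (E + Ep) / (2.0 * rt * rtp) * (1.0 - Bmu) + Bmu;
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return c;
}

// ---------------------------------------------------------------------------
// Ganachaud--Mokrani polaron trapping channel.
// ---------------------------------------------------------------------------

inline double polaron_sigma(double E, double ndens, double strap, double gtrap) {
  return strap / ndens * std::exp(-gtrap * E);
}

}  // namespace seymc

#endif
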