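// Energy-straggling Monte Carlo transport engine: exponential step sampling,
// cumulative-probability process selection, secondary-electron cascade over a
// LIFO stack, surface escape through z = 0 of a semi-infinite slab.
//
// Cross sections are cached on a log-spaced energy grid (linear-in-log-E
// interpolation of the mean free path, the cumulative process probabilities
// and the per-axis elastic weights); angle and ejected-energy sampling use
// the exact closed forms at the current energy.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include "xsections.h"

using namespace Rcpp;

namespace {

// splitmix64: one independent, reproducible stream per trajectory,
// seeded with (global seed + trajectory index).
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed) {}
  uint64_t next() {
    s += 0x9E3779B97F4A7C15ULL;
    uint64_t z = s;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * 0x1.0p-53; }  // [0, 1)
};

struct Pars {
  std::vector<double> el_d2, el_dw;          // elastic: D_d^2 (a.u.), 2*h*B_d (eV)
  std::vector<double> ex_d2, ex_de;          // excitation: D_0f^2 (a.u.), dE_0f (eV)
  std::vector<double> orb_b, orb_u, orb_n, orb_q;
  double e_ion, homo_b, homo_q;
  double ndens, hw, eps0, epsinf, temp, strap, gtrap;
};

Pars parse_pars(const List& L) {
  Pars P;
  P.el_d2 = as<std::vector<double>>(L["el_d2"]);
  P.el_dw = as<std::vector<double>>(L["el_dw"]);
  P.ex_d2 = as<std::vector<double>>(L["ex_d2"]);
  P.ex_de = as<std::vector<double>>(L["ex_de"]);
  P.orb_b = as<std::vector<double>>(L["orb_b"]);
  P.orb_u = as<std::vector<double>>(L["orb_u"]);
  P.orb_n = as<std::vector<double>>(L["orb_n"]);
  P.orb_q = as<std::vector<double>>(L["orb_q"]);
  P.e_ion = as<double>(L["e_ion"]);
  P.ndens = as<double>(L["ndens"]);
  P.hw = as<double>(L["hw_ph"]);
  P.eps0 = as<double>(L["eps0"]);
  P.epsinf = as<double>(L["epsinf"]);
  P.temp = as<double>(L["temp"]);
  P.strap = as<double>(L["strap"]);
  P.gtrap = as<double>(L["gtrap"]);
  std::size_t h = 0;
  for (std::size_t j = 1; j < P.orb_b.size(); ++j)
    if (P.orb_b[j] < P.orb_b[h]) h = j;
  P.homo_b = P.orb_b[h];
  P.homo_q = P.orb_q[h];
  return P;
}

// exact per-channel cross sections at energy E: el, elec, ion, phonon, polaron
void channels(const Pars& P, double E, double out[5]) {
  double s = 0.0;
  for (std::size_t j = 0; j < P.el_d2.size(); ++j)
    s += seymc::dipole_sigma(E, P.el_d2[j], P.el_dw[j]);
  out[0] = s;
  s = 0.0;
  for (std::size_t j = 0; j < P.ex_d2.size(); ++j)
    s += seymc::dipole_sigma(E, P.ex_d2[j], P.ex_de[j]);
  out[1] = s;
  s = 0.0;
  for (std::size_t j = 0; j < P.orb_b.size(); ++j)
    s += seymc::beb_sigma(E, P.orb_b[j], P.orb_u[j], P.orb_n[j], P.orb_q[j]);
  out[2] = s;
  out[3] = seymc::phonon_sigma(E, P.ndens, P.hw, P.eps0, P.epsinf, P.temp);
  out[4] = seymc::polaron_sigma(E, P.ndens, P.strap, P.gtrap);
}

struct Grid {
  int ng;
  double l0, dl;
  std::vector<double> lam, p1, p2, p3, c1, c2;  // c1, c2: elastic axis weights
  void build(const Pars& P, double elo, double ehi, int n) {
    ng = n;
    l0 = std::log(elo);
    dl = (std::log(ehi) - l0) / (ng - 1);
    lam.resize(ng); p1.resize(ng); p2.resize(ng); p3.resize(ng);
    c1.resize(ng); c2.resize(ng);
    double xs[5];
    for (int i = 0; i < ng; ++i) {
      const double E = std::exp(l0 + i * dl);
      channels(P, E, xs);
      const double tot = xs[0] + xs[1] + xs[2] + xs[3] + xs[4];
      lam[i] = 1.0 / (P.ndens * tot);
      p1[i] = xs[0] / tot;
      p2[i] = p1[i] + (xs[1] + xs[2]) / tot;
      p3[i] = p2[i] + xs[3] / tot;
      double a0 = seymc::dipole_sigma(E, P.el_d2[0], P.el_dw[0]);
      double a1 = seymc::dipole_sigma(E, P.el_d2[1], P.el_dw[1]);
      if (xs[0] > 0.0) {
        c1[i] = a0 / xs[0];
        c2[i] = (a0 + a1) / xs[0];
      } else {
        c1[i] = 1.0; c2[i] = 1.0;
      }
    }
  }
  // linear interpolation in log(E), clamped to the grid ends
  inline void lookup(double E, double& lm, double& q1, double& q2, double& q3,
                     double& w1, double& w2) const {
    double u = (std::log(E) - l0) / dl;
    if (u <= 0.0) u = 0.0;
    if (u >= ng - 1) u = ng - 1 - 1e-9;
    const int i = static_cast<int>(u);
    const double f = u - i;
    lm = lam[i] + f * (lam[i + 1] - lam[i]);
    q1 = p1[i] + f * (p1[i + 1] - p1[i]);
    q2 = p2[i] + f * (p2[i + 1] - p2[i]);
    q3 = p3[i] + f * (p3[i + 1] - p3[i]);
    w1 = c1[i] + f * (c1[i + 1] - c1[i]);
    w2 = c2[i] + f * (c2[i + 1] - c2[i]);
  }
};

struct Electron {
  double x, y, z, dx, dy, dz, E;
  int gen;
};

inline void rotate_dir(double& dx, double& dy, double& dz,
                       double ct, double st, double phi) {
  const double cp = std::cos(phi), sp = std::sin(phi);
  double ux, uy, uz;
  const double nxy = std::sqrt(dx * dx + dy * dy);
  if (nxy > 1e-12) {  // u = zhat x d, normalized
    ux = -dy / nxy; uy = dx / nxy; uz = 0.0;
  } else {
    ux = 1.0; uy = 0.0; uz = 0.0;
  }
  // v = d x u
  const double vx = dy * uz - dz * uy;
  const double vy = dz * ux - dx * uz;
  const double vz = dx * uy - dy * ux;
  double nx = ct * dx + st * (cp * ux + sp * vx);
  double ny = ct * dy + st * (cp * uy + sp * vy);
  double nz = ct * dz + st * (cp * uz + sp * vz);
  const double inv = 1.0 / std::sqrt(nx * nx + ny * ny + nz * nz);
  dx = nx * inv; dy = ny * inv; dz = nz * inv;
}

enum Proc { ELASTIC = 1, EXCITATION = 2, IONIZATION = 3, PHONON = 4,
            POLARON = 5, EMITTED = 6, ABSORBED = 7, CAPPED = 8, NULLEVT = 9 };

}  // namespace

// [[Rcpp::export]]
List run_engine_cpp(List pars, double e_beam, double n_traj, double seed,
                    double cutoff, double max_events, int grid_n,
                    bool trace, bool residuals, double max_trace) {
  const Pars P = parse_pars(pars);
  const int ntr = static_cast<int>(n_traj);
  const uint64_t base = static_cast<uint64_t>(seed);

  const double elo = std::max(cutoff, 1e-3);
  const bool live = e_beam > elo && e_beam > cutoff;
  Grid G;
  if (live) G.build(P, elo * 0.999, e_beam * 1.000001, grid_n);

  std::vector<double> em_E;  std::vector<int> em_gen;
  std::vector<double> resid;
  if (residuals) resid.reserve(ntr);
  // trace columns
  std::vector<double> tr_traj, tr_proc, tr_E0, tr_E1, tr_z;
  std::vector<int> tr_gen;
  const double trace_cap = max_trace;

  double n_secondary = 0, n_emit = 0, n_trap = 0, n_abs = 0, n_cap = 0,
         n_null = 0, total_events = 0;

  const std::size_t nf = P.ex_d2.size();
  std::vector<double> sf(nf);

  // Transport-table values and per-axis elastic inversion constants depend
  // only on the current energy; elastic collisions (the dominant event type)
  // leave E unchanged, so cache them until an energy-changing event.
  double cE = -1.0, lam = 0, p1 = 0, p2 = 0, p3 = 0, w1 = 0, w2 = 0;
  double qax[3] = {0, 0, 0}, Lax[3] = {0, 0, 0};
  bool qok = false;

  for (int traj = 0; traj < ntr; ++traj) {
    Rng rng(base + static_cast<uint64_t>(traj));
    double ledger = e_beam;
    std::vector<Electron> stack;
    stack.push_back({0.0, 0.0, 0.0, 0.0, 0.0, 1.0, e_beam, 0});

    while (!stack.empty()) {
      Electron e = stack.back();
      stack.pop_back();
      double events = 0;

      for (;;) {
        if (e.E < cutoff || !live) {
          n_abs += 1; ledger -= e.E;
          if (trace && tr_traj.size() < trace_cap) {
            tr_traj.push_back(traj + 1); tr_gen.push_back(e.gen);
            tr_proc.push_back(ABSORBED); tr_E0.push_back(e.E);
            tr_E1.push_back(e.E); tr_z.push_back(e.z);
          }
          break;
        }
        if (e.E != cE) {
          G.lookup(e.E, lam, p1, p2, p3, w1, w2);
          cE = e.E;
          qok = false;
        }

        double mu = rng.unif();
        while (mu == 0.0) mu = rng.unif();      // reject exact 0 (log divergence)
        const double ds = -lam * std::log(mu);  // exponential step, mu in (0,1)
        const double znew = e.z + e.dz * ds;
        if (znew < 0.0) {
          n_emit += 1; ledger -= e.E;
          em_E.push_back(e.E); em_gen.push_back(e.gen);
          if (trace && tr_traj.size() < trace_cap) {
            tr_traj.push_back(traj + 1); tr_gen.push_back(e.gen);
            tr_proc.push_back(EMITTED); tr_E0.push_back(e.E);
            tr_E1.push_back(e.E); tr_z.push_back(0.0);
          }
          break;
        }
        e.x += e.dx * ds; e.y += e.dy * ds; e.z = znew;
        events += 1; total_events += 1;

        const double E0 = e.E;
        int proc;
        bool terminal = false;
        const double mut = rng.unif();
        if (mut < p1) {
          // elastic: pick inertia axis ~ sigma_d, invert its cumulative exactly
          proc = ELASTIC;
          const double ua = rng.unif();
          int ax = (ua < w1) ? 0 : (ua < w2 ? 1 : 2);
          if (P.el_d2[ax] <= 0.0 || e.E <= P.el_dw[ax]) {
            int found = -1;
            for (int j = 0; j < 3; ++j)
              if (P.el_d2[j] > 0.0 && e.E > P.el_dw[j]) { found = j; break; }
            ax = found;
          }
          if (ax < 0) { proc = NULLEVT; n_null += 1; }
          else {
            if (!qok) {
              for (int j = 0; j < 3; ++j) {
                if (P.el_d2[j] > 0.0 && cE > P.el_dw[j]) {
                  qax[j] = seymc::dipole_qfactor(cE, P.el_dw[j]);
                  Lax[j] = std::log1p(2.0 * qax[j]);
                } else {
                  qax[j] = 0.0; Lax[j] = 0.0;
                }
              }
              qok = true;
            }
            const double t = std::expm1(rng.unif() * Lax[ax]) / qax[ax];
            const double ct = 1.0 - t;
            const double st = std::sqrt(t * (2.0 - t));
            rotate_dir(e.dx, e.dy, e.dz, ct, st, 2.0 * M_PI * rng.unif());
          }
        } else if (mut < p2) {
          if (e.E < P.e_ion) {
            // electronic excitation: state f ~ sigma_f among open states
            double tot = 0.0;
            for (std::size_t j = 0; j < nf; ++j) {
              sf[j] = seymc::dipole_sigma(e.E, P.ex_d2[j], P.ex_de[j]);
              tot += sf[j];
            }
            if (tot <= 0.0) { proc = NULLEVT; n_null += 1; }
            else {
              proc = EXCITATION;
              double r = rng.unif() * tot;
              std::size_t f = 0;
              for (; f + 1 < nf; ++f) { if (r < sf[f]) break; r -= sf[f]; }
              if (sf[f] <= 0.0) {  // fp edge: fall back to widest open state
                std::size_t best = 0;
                for (std::size_t j = 1; j < nf; ++j) if (sf[j] > sf[best]) best = j;
                f = best;
              }
              e.E -= P.ex_de[f]; ledger -= P.ex_de[f];
            }
          } else if (e.E > P.homo_b) {
            // ionization from the HOMO; secondary takes kinetic energy W
            proc = IONIZATION;
            const double W = seymc::beb_invert(rng.unif(), e.E, P.homo_b, P.homo_q);
            e.E -= W + P.homo_b;
            ledger -= P.homo_b;
            n_secondary += 1;
            const double c = 1.0 - 2.0 * rng.unif();
            const double s = std::sqrt(std::max(0.0, 1.0 - c * c));
            const double ph = 2.0 * M_PI * rng.unif();
            stack.push_back({e.x, e.y, e.z,
                             s * std::cos(ph), s * std::sin(ph), c, W, e.gen + 1});
          } else { proc = NULLEVT; n_null += 1; }
        } else if (mut < p3) {
          if (e.E > P.hw) {
            proc = PHONON;
            const double Ep = e.E - P.hw;
            const double ct = seymc::phonon_costheta(rng.unif(), e.E, Ep);
            const double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
            rotate_dir(e.dx, e.dy, e.dz, ct, st, 2.0 * M_PI * rng.unif());
            e.E = Ep; ledger -= P.hw;
          } else { proc = NULLEVT; n_null += 1; }
        } else {
          proc = POLARON;
          terminal = true;
          n_trap += 1; ledger -= e.E;
        }

        if (trace && tr_traj.size() < trace_cap) {
          tr_traj.push_back(traj + 1); tr_gen.push_back(e.gen);
          tr_proc.push_back(proc); tr_E0.push_back(E0);
          tr_E1.push_back(terminal ? 0.0 : e.E); tr_z.push_back(e.z);
        }
        if (terminal) break;
        if (events >= max_events) {
          n_cap += 1; ledger -= e.E;
          break;
        }
      }
    }
    if (residuals) resid.push_back(ledger);
  }

  List out = List::create(
      _["emitted_energy"] = wrap(em_E),
      _["emitted_generation"] = wrap(em_gen),
      _["counters"] = List::create(
          _["primaries"] = static_cast<double>(ntr),
          _["secondaries_created"] = n_secondary,
          _["emitted"] = n_emit,
          _["trapped"] = n_trap,
          _["absorbed"] = n_abs,
          _["cap_terminated"] = n_cap,
          _["null_events"] = n_null,
          _["total_events"] = total_events));
  if (residuals) out["residuals"] = wrap(resid);
  if (trace)
    out["trace"] = DataFrame::create(
        _["trajectory"] = wrap(tr_traj), _["generation"] = wrap(tr_gen),
        _["process"] = wrap(tr_proc), _["E_before"] = wrap(tr_E0),
        _["E_after"] = wrap(tr_E1), _["z"] = wrap(tr_z));
  return out;
}

// Diagnostics: interpolated transport-table values at arbitrary energies,
// for verifying the cache against exact evaluation.
// [[Rcpp::export]]
DataFrame engine_interp_cpp(List pars, double e_beam, double cutoff, int grid_n,
                            NumericVector E) {
  const Pars P = parse_pars(pars);
  const double elo = std::max(cutoff, 1e-3);
  Grid G;
  G.build(P, elo * 0.999, e_beam * 1.000001, grid_n);
  const int n = E.size();
  NumericVector lam(n), p1(n), p2(n), p3(n);
  for (int i = 0; i < n; ++i) {
    double w1, w2;
    G.lookup(E[i], lam[i], p1[i], p2[i], p3[i], w1, w2);
  }
  return DataFrame::create(_["E_eV"] = E, _["lambda_m"] = lam,
                           _["p1"] = p1, _["p2"] = p2, _["p3"] = p3);
}
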