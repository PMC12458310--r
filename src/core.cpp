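// Force-field evaluation and integrators for the 2D bead-spring cell model.
//
// Energy terms (reduced units: sigma = length, kT = energy, gamma = drag):
//   stretch    E = 1/2 k (r - r0)^2                      (all springs)
//   bend       E = kb (1 - cos(theta - theta0))          (theta0 = pi on chains,
//                                                         polygon angle on rings)
//   attraction 4 u3 [(s/r)^12 - (s/r)^6], truncated and shifted to 0 at 2.5 s,
//              ACTIN_HEAD <-> MEMBRANE pairs only
//   repulsion  WCA: 4 eps [(s/r)^12 - (s/r)^6] + eps for r < 2^(1/6) s
//   area       E = 1/2 kA (A - A0)^2 / A0, A = signed shoelace area of a ring
//
// Nonbonded exclusions: pairs sharing a structure id (same ring or same
// filament) and an explicit pair list (anchor bonds). Pair search is an
// exhaustive O(n^2) loop with an early distance cutoff.

#include <Rcpp.h>
#include <array>
#include <unordered_set>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Model {
  int n;
  std::vector<double> px, py;
  std::vector<int> bi, bj;              // stretch bonds (0-based)
  std::vector<double> bk, br0;
  std::vector<int> ai, aj, ak;          // bend triples, j = apex
  std::vector<double> akb, ath0;
  std::vector<int> group;               // structure id, -1 = none
  std::vector<double> group_core;       // intra-structure soft-core range
                                        // per structure id (0 = none)
  double k_core;                        // soft-core stiffness
  std::vector<int> role;                // 0 MEM, 1 NUC, 2 ACTIN, 3 HEAD
  std::unordered_set<long long> excl;   // excluded pairs (bonded, anchors)
  std::vector<std::vector<int>> rings;  // area groups (ordered cycles)
  std::vector<double> ringK, ringA0;
  double u3, eps, sigma;
};

inline long long pkey(int i, int j) {
  if (i > j) std::swap(i, j);
  return (static_cast<long long>(i) << 32) | static_cast<unsigned int>(j);
}

Model unpack(const NumericMatrix& pos, const List& topo, const List& par) {
  Model m;
  m.n = pos.nrow();
  m.px.resize(m.n); m.py.resize(m.n);
  for (int i = 0; i < m.n; ++i) { m.px[i] = pos(i, 0); m.py[i] = pos(i, 1); }
  IntegerVector bi = topo["bond_i"], bj = topo["bond_j"];
  NumericVector bk = topo["bond_k"], br0 = topo["bond_r0"];
  m.bi.assign(bi.begin(), bi.end());
  m.bj.assign(bj.begin(), bj.end());
  m.bk.assign(bk.begin(), bk.end());
  m.br0.assign(br0.begin(), br0.end());
  IntegerVector ai = topo["ang_i"], aj = topo["ang_j"], ak = topo["ang_k"];
  NumericVector akb = topo["ang_kb"], ath0 = topo["ang_th0"];
  m.ai.assign(ai.begin(), ai.end());
  m.aj.assign(aj.begin(), aj.end());
  m.ak.assign(ak.begin(), ak.end());
  m.akb.assign(akb.begin(), akb.end());
  m.ath0.assign(ath0.begin(), ath0.end());
  IntegerVector grp = topo["group"], role = topo["role"];
  m.group.assign(grp.begin(), grp.end());
  m.role.assign(role.begin(), role.end());
  NumericVector gs = topo["group_core"];
  m.group_core.assign(gs.begin(), gs.end());
  IntegerVector ei = topo["excl_i"], ej = topo["excl_j"];
  for (int q = 0; q < ei.size(); ++q) m.excl.insert(pkey(ei[q], ej[q]));
  List rings = topo["rings"];
  NumericVector rk = topo["ring_k"], ra0 = topo["ring_a0"];
  for (int q = 0; q < rings.size(); ++q) {
    IntegerVector idx = rings[q];
    m.rings.emplace_back(idx.begin(), idx.end());
    m.ringK.push_back(rk[q]);
    m.ringA0.push_back(ra0[q]);
  }
  m.u3 = as<double>(par["u3"]);
  m.eps = as<double>(par["eps_rep"]);
  m.sigma = as<double>(par["sigma"]);
  m.k_core = as<double>(par["k_core"]);
  return m;
}

// ecomp: stretch, bend, attraction, repulsion, area (bonded + area part)
void eval_bonded(const Model& m, std::vector<double>& fx, std::vector<double>& fy,
             double* ecomp) {
  const int n = m.n;
  fx.assign(n, 0.0); fy.assign(n, 0.0);
  for (int q = 0; q < 5; ++q) ecomp[q] = 0.0;

  // stretch
  for (size_t b = 0; b < m.bi.size(); ++b) {
    int i = m.bi[b], j = m.bj[b];
    double dx = m.px[i] - m.px[j], dy = m.py[i] - m.py[j];
    double r = std::sqrt(dx * dx + dy * dy);
    if (r < 1e-12) stop("stretch bond between overlapping beads %d and %d", i + 1, j + 1);
    double dr = r - m.br0[b];
    ecomp[0] += 0.5 * m.bk[b] * dr * dr;
    double fmag = -m.bk[b] * dr / r;  // force on i along (dx,dy)
    fx[i] += fmag * dx; fy[i] += fmag * dy;
    fx[j] -= fmag * dx; fy[j] -= fmag * dy;
  }

  // bend: E = kb (1 - cos(theta - theta0)), theta in [0, pi] at apex j
  for (size_t t = 0; t < m.ai.size(); ++t) {
    int i = m.ai[t], j = m.aj[t], k = m.ak[t];
    double ax = m.px[i] - m.px[j], ay = m.py[i] - m.py[j];
    double bx = m.px[k] - m.px[j], by = m.py[k] - m.py[j];
    double la2 = ax * ax + ay * ay, lb2 = bx * bx + by * by;
    if (la2 < 1e-24 || lb2 < 1e-24)
      stop("bend triple with overlapping beads at apex %d", j + 1);
    double dot = ax * bx + ay * by;
    double crs = ax * by - ay * bx;
    double th = std::atan2(std::fabs(crs), dot);
    ecomp[1] += m.akb[t] * (1.0 - std::cos(th - m.ath0[t]));
    double dEdth = m.akb[t] * std::sin(th - m.ath0[t]);
    double s = (crs >= 0.0) ? 1.0 : -1.0;
    // grad_i theta = s * ( ay, -ax) / la2 ; grad_k theta = s * (-by,  bx) / lb2
    double gix = s * ay / la2, giy = -s * ax / la2;
    double gkx = -s * by / lb2, gky = s * bx / lb2;
    fx[i] -= dEdth * gix; fy[i] -= dEdth * giy;
    fx[k] -= dEdth * gkx; fy[k] -= dEdth * gky;
    fx[j] += dEdth * (gix + gkx); fy[j] += dEdth * (giy + gky);
  }

  // nonbonded terms are added by eval_nonbonded_* below
  // area: E = 1/2 kA (A - A0)^2 / A0, signed shoelace area
  for (size_t q = 0; q < m.rings.size(); ++q) {
    const std::vector<int>& idx = m.rings[q];
    int nr = static_cast<int>(idx.size());
    double A = 0.0;
    for (int v = 0; v < nr; ++v) {
      int a = idx[v], b = idx[(v + 1) % nr];
      A += m.px[a] * m.py[b] - m.px[b] * m.py[a];
    }
    A *= 0.5;
    double A0 = m.ringA0[q], kA = m.ringK[q];
    ecomp[4] += 0.5 * kA * (A - A0) * (A - A0) / A0;
    double c = -kA * (A - A0) / A0;
    for (int v = 0; v < nr; ++v) {
      int a = idx[v];
      int prev = idx[(v - 1 + nr) % nr], next = idx[(v + 1) % nr];
      fx[a] += c * 0.5 * (m.py[next] - m.py[prev]);
      fy[a] += c * 0.5 * (m.px[prev] - m.px[next]);
    }
  }
}


// shared pair kernels -------------------------------------------------------

inline void pair_attr(const Model& m, int i, int j, double eshift,
                      std::vector<double>& fx, std::vector<double>& fy,
                      double* ecomp) {
  double dx = m.px[i] - m.px[j], dy = m.py[i] - m.py[j];
  double r2 = dx * dx + dy * dy;
  if (r2 >= 6.25 * m.sigma * m.sigma) return;
  if (r2 < 1e-12) stop("overlapping nonbonded beads %d and %d", i + 1, j + 1);
  double s2 = m.sigma * m.sigma;
  double sr2 = s2 / r2, sr6 = sr2 * sr2 * sr2, sr12 = sr6 * sr6;
  ecomp[2] += 4.0 * m.u3 * (sr12 - sr6) - eshift;
  double fmag = 24.0 * m.u3 * (2.0 * sr12 - sr6) / r2;
  fx[i] += fmag * dx; fy[i] += fmag * dy;
  fx[j] -= fmag * dx; fy[j] -= fmag * dy;
}

inline void pair_wca(const Model& m, int i, int j,
                     std::vector<double>& fx, std::vector<double>& fy,
                     double* ecomp) {
  double dx = m.px[i] - m.px[j], dy = m.py[i] - m.py[j];
  double r2 = dx * dx + dy * dy;
  double s2 = m.sigma * m.sigma;
  if (r2 >= std::cbrt(2.0) * s2) return;
  if (r2 < 1e-12) stop("overlapping nonbonded beads %d and %d", i + 1, j + 1);
  double sr2 = s2 / r2, sr6 = sr2 * sr2 * sr2, sr12 = sr6 * sr6;
  ecomp[3] += 4.0 * m.eps * (sr12 - sr6) + m.eps;
  double fmag = 24.0 * m.eps * (2.0 * sr12 - sr6) / r2;
  fx[i] += fmag * dx; fy[i] += fmag * dy;
  fx[j] -= fmag * dx; fy[j] -= fmag * dy;
}

inline void pair_core(const Model& m, int i, int j, double rc,
                      std::vector<double>& fx, std::vector<double>& fy,
                      double* ecomp) {
  double dx = m.px[i] - m.px[j], dy = m.py[i] - m.py[j];
  double r2 = dx * dx + dy * dy;
  if (r2 >= rc * rc) return;
  if (r2 < 1e-12) stop("overlapping nonbonded beads %d and %d", i + 1, j + 1);
  double r = std::sqrt(r2);
  double dr = r - rc;
  ecomp[3] += 0.5 * m.k_core * dr * dr;
  double fmag = -m.k_core * dr / r;
  fx[i] += fmag * dx; fy[i] += fmag * dy;
  fx[j] -= fmag * dx; fy[j] -= fmag * dy;
}

// pair classification shared by the exhaustive loop and the neighbor list:
// type 0 = none, 1 = attraction, 2 = cross-structure WCA, 3 = soft core
inline int pair_type(const Model& m, int i, int j) {
  if (m.group[i] >= 0 && m.group[i] == m.group[j])
    return m.group_core[m.group[i]] > 0.0 ? 3 : 0;
  if (!m.excl.empty() && m.excl.count(pkey(i, j))) return 0;
  bool attr = (m.role[i] == 3 && m.role[j] == 0) ||
              (m.role[i] == 0 && m.role[j] == 3);
  if (attr) return m.u3 > 0.0 ? 1 : 2;
  return 2;
}

// exhaustive O(n^2) evaluation (single-point calls, NVE validation)
void eval_nonbonded_full(const Model& m, std::vector<double>& fx,
                         std::vector<double>& fy, double* ecomp) {
  const double sr6c = std::pow(1.0 / 2.5, 6);
  const double eshift = 4.0 * m.u3 * (sr6c * sr6c - sr6c);
  const double rmax2 = 6.25 * m.sigma * m.sigma;
  for (int i = 0; i < m.n - 1; ++i) {
    for (int j = i + 1; j < m.n; ++j) {
      double dx = m.px[i] - m.px[j], dy = m.py[i] - m.py[j];
      double r2 = dx * dx + dy * dy;
      if (r2 >= rmax2) continue;
      switch (pair_type(m, i, j)) {
      case 1: pair_attr(m, i, j, eshift, fx, fy, ecomp); break;
      case 2: pair_wca(m, i, j, fx, fy, ecomp); break;
      case 3: pair_core(m, i, j, m.group_core[m.group[i]], fx, fy, ecomp); break;
      default: break;
      }
    }
  }
}

// Verlet neighbor list for the production integrator
struct NeighborList {
  std::vector<int> pi, pj, ptype;
  std::vector<double> rx, ry;  // positions at last rebuild
  double skin = 0.4;
  void build(const Model& m) {
    pi.clear(); pj.clear(); ptype.clear();
    double s = m.sigma;
    double range[4] = {0.0, 2.5 * s, std::pow(2.0, 1.0 / 6.0) * s, 0.0};
    double limmax = 2.5 * s + skin, limmax2 = limmax * limmax;
    for (int i = 0; i < m.n - 1; ++i) {
      for (int j = i + 1; j < m.n; ++j) {
        double dx = m.px[i] - m.px[j], dy = m.py[i] - m.py[j];
        double r2 = dx * dx + dy * dy;
        if (r2 >= limmax2) continue;
        int t = pair_type(m, i, j);
        if (t == 0) continue;
        double cut = (t == 3) ? m.group_core[m.group[i]] : range[t];
        double lim = cut + skin;
        if (r2 < lim * lim) {
          pi.push_back(i); pj.push_back(j); ptype.push_back(t);
        }
      }
    }
    rx.assign(m.px.begin(), m.px.end());
    ry.assign(m.py.begin(), m.py.end());
  }
  // true max displacement of any bead since the last rebuild
  double max_disp(const Model& m) const {
    double w = 0.0;
    for (int i = 0; i < m.n; ++i) {
      double dx = m.px[i] - rx[i], dy = m.py[i] - ry[i];
      double d2 = dx * dx + dy * dy;
      if (d2 > w) w = d2;
    }
    return std::sqrt(w);
  }
  void eval(const Model& m, std::vector<double>& fx, std::vector<double>& fy,
            double* ecomp) const {
    const double sr6c = std::pow(1.0 / 2.5, 6);
    const double eshift = 4.0 * m.u3 * (sr6c * sr6c - sr6c);
    for (size_t q = 0; q < pi.size(); ++q) {
      int i = pi[q], j = pj[q];
      switch (ptype[q]) {
      case 1: pair_attr(m, i, j, eshift, fx, fy, ecomp); break;
      case 2: pair_wca(m, i, j, fx, fy, ecomp); break;
      case 3: pair_core(m, i, j, m.group_core[m.group[i]], fx, fy, ecomp); break;
      }
    }
  }
};

NumericMatrix snapshot(const Model& m) {
  NumericMatrix out(m.n, 2);
  for (int i = 0; i < m.n; ++i) { out(i, 0) = m.px[i]; out(i, 1) = m.py[i]; }
  return out;
}

} // namespace

// [[Rcpp::export]]
List cg_eval(NumericMatrix pos, List topo, List par) {
  Model m = unpack(pos, topo, par);
  std::vector<double> fx, fy;
  double e[5];
  eval_bonded(m, fx, fy, e);
  eval_nonbonded_full(m, fx, fy, e);
  NumericMatrix F(m.n, 2);
  for (int i = 0; i < m.n; ++i) { F(i, 0) = fx[i]; F(i, 1) = fy[i]; }
  return List::create(
    _["forces"] = F,
    _["stretch"] = e[0], _["bend"] = e[1], _["attraction"] = e[2],
    _["repulsion"] = e[3], _["area"] = e[4],
    _["total"] = e[0] + e[1] + e[2] + e[3] + e[4]);
}

// Overdamped Langevin (Euler-Maruyama):
//   dx = F dt / gamma + sqrt(2 kT dt / gamma) * xi,  xi ~ N(0,1)
// Noise is drawn from R's RNG (set.seed upstream) in bead index order,
// x before y, so trajectories are bit-reproducible for a given seed.
// [[Rcpp::export]]
List cg_run_od(NumericMatrix pos, List topo, List par,
               double dt, double gamma_, double kT,
               int n_steps, int save_every, int step_offset,
               double max_step = 0.25) {
  Model m = unpack(pos, topo, par);
  std::vector<double> fx, fy;
  double e[5];
  const double mob = dt / gamma_;
  const double amp = std::sqrt(2.0 * kT * dt / gamma_);
  List frames;
  std::vector<int> fsteps;
  std::vector<std::array<double, 6>> esave;
  NeighborList nl;
  nl.build(m);
  long long n_clamped = 0;
  RNGScope scope;
  for (int s = 1; s <= n_steps; ++s) {
    if (nl.max_disp(m) > 0.5 * nl.skin) nl.build(m);
    eval_bonded(m, fx, fy, e);
    nl.eval(m, fx, fy, e);
    for (int i = 0; i < m.n; ++i) {
      double nx = 0.0, ny = 0.0;
      if (kT > 0.0) { nx = norm_rand(); ny = norm_rand(); }
      double ddx = fx[i] * mob + amp * nx;
      double ddy = fy[i] * mob + amp * ny;
      if (!std::isfinite(ddx) || !std::isfinite(ddy))
        stop("non-finite displacement for bead %d at step %d", i + 1, step_offset + s);
      double d2 = ddx * ddx + ddy * ddy;
      if (d2 > max_step * max_step) {
        // safety valve against integrator overshoot in the steep adhesion
        // core; engages only on forces far outside the thermal range
        double sc = max_step / std::sqrt(d2);
        ddx *= sc; ddy *= sc;
        ++n_clamped;
      }
      m.px[i] += ddx; m.py[i] += ddy;
    }
    if ((step_offset + s) % save_every == 0) {
      nl.build(m);
      eval_bonded(m, fx, fy, e);
      nl.eval(m, fx, fy, e);
      frames.push_back(snapshot(m));
      fsteps.push_back(step_offset + s);
      esave.push_back({e[0], e[1], e[2], e[3], e[4],
                       e[0] + e[1] + e[2] + e[3] + e[4]});
    }
  }
  NumericMatrix E(static_cast<int>(esave.size()), 6);
  for (size_t q = 0; q < esave.size(); ++q)
    for (int c = 0; c < 6; ++c) E(q, c) = esave[q][c];
  colnames(E) = CharacterVector::create("stretch", "bend", "attraction",
                                        "repulsion", "area", "total");
  return List::create(_["pos"] = snapshot(m), _["frames"] = frames,
                      _["frame_steps"] = wrap(fsteps), _["energies"] = E,
                      _["n_clamped"] = static_cast<double>(n_clamped));
}

// Velocity Verlet at unit bead mass; validation mode (no thermostat).
// [[Rcpp::export]]
List cg_run_nve(NumericMatrix pos, NumericMatrix vel, List topo, List par,
                double dt, int n_steps, int save_every) {
  Model m = unpack(pos, topo, par);
  const int n = m.n;
  std::vector<double> vx(n), vy(n), fx, fy;
  for (int i = 0; i < n; ++i) { vx[i] = vel(i, 0); vy[i] = vel(i, 1); }
  double e[5];
  eval_bonded(m, fx, fy, e);
  eval_nonbonded_full(m, fx, fy, e);
  std::vector<double> etot, ekin_s, epot_s, tsave;
  for (int s = 1; s <= n_steps; ++s) {
    for (int i = 0; i < n; ++i) {
      vx[i] += 0.5 * dt * fx[i]; vy[i] += 0.5 * dt * fy[i];
      m.px[i] += dt * vx[i];     m.py[i] += dt * vy[i];
      if (!std::isfinite(m.px[i]) || !std::isfinite(m.py[i]))
        stop("non-finite position for bead %d at step %d", i + 1, s);
    }
    eval_bonded(m, fx, fy, e);
    eval_nonbonded_full(m, fx, fy, e);
    for (int i = 0; i < n; ++i) {
      vx[i] += 0.5 * dt * fx[i]; vy[i] += 0.5 * dt * fy[i];
    }
    if (s % save_every == 0) {
      double ek = 0.0;
      for (int i = 0; i < n; ++i) ek += 0.5 * (vx[i] * vx[i] + vy[i] * vy[i]);
      double ep = e[0] + e[1] + e[2] + e[3] + e[4];
      ekin_s.push_back(ek); epot_s.push_back(ep);
      etot.push_back(ek + ep); tsave.push_back(s * dt);
    }
  }
  NumericMatrix V(n, 2);
  for (int i = 0; i < n; ++i) { V(i, 0) = vx[i]; V(i, 1) = vy[i]; }
  return List::create(_["pos"] = snapshot(m), _["vel"] = V,
                      _["time"] = wrap(tsave), _["kinetic"] = wrap(ekin_s),
                      _["potential"] = wrap(epot_s), _["total"] = wrap(etot));
}
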