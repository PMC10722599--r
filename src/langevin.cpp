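// Langevin (BAOAB) dynamics of ligand beads around frozen nanoparticle cores,
// used to sample constrained mean forces on the cores.
//
// Reduced units: lengths in sigma_b, energies in k_B T, bead mass m = 1.
// Interactions:
//   - modified LJ between non-bonded bead pairs: repulsive branch
//     u_LJ(r) + (1-s) eps for r < 2^(1/6) sigma_b, attractive branch
//     s u_LJ(r) beyond, truncated at rc_bead (s = 0 -> WCA, s = 1 -> LJ);
//   - harmonic bonds K_b (b - b0)^2 between consecutive beads and between
//     each anchor bead and its fixed grafting site on the core surface;
//   - harmonic angles K_th (theta - theta0)^2 on consecutive bead triples;
//   - WCA repulsion between every bead and every core, acting on the
//     surface-shifted distance d = |r - R_core| - (sigma_c - sigma_b)/2.
// Cores are frozen rigid units; the instantaneous force on core i is the sum
// of reactions from bead-core repulsion and from grafting bonds.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct FGModel {
  double s, beta_eps, Kb, b0, Kth, th0, rc;
  double core_shift;  // (sigma_c - sigma_b)/2
  int n_beads, n_np;
  std::vector<double> cores;       // 3 * n_np (fixed)
  std::vector<double> grafts;      // 3 * n_graft (fixed)
  std::vector<int> graft_core;     // core index per graft
  std::vector<int> anchor_bead;    // bead index bonded to graft g
  std::vector<int> bond_i, bond_j; // bead-bead bonds
  std::vector<int> ang_a, ang_b, ang_c;
  std::vector<std::vector<int>> excl;  // per-bead sorted exclusion lists
};

static const double WCA_RMIN = 1.122462048309373;  // 2^(1/6)

// modified LJ force magnitude along r (positive = repulsive) and energy
static inline void mod_lj(double r, double s, double beta_eps,
                          double rc, double& e, double& fr) {
  if (r >= rc) { e = 0; fr = 0; return; }
  double inv2 = 1.0 / (r * r);
  double inv6 = inv2 * inv2 * inv2;
  double ulj = 4.0 * beta_eps * inv6 * (inv6 - 1.0);
  double flj = 24.0 * beta_eps * inv6 * (2.0 * inv6 - 1.0) / r;  // -du/dr
  if (r < WCA_RMIN) { e = ulj + (1.0 - s) * beta_eps; fr = flj; }
  else { e = s * ulj; fr = s * flj; }
}

// forces: accumulates bead forces into f (3*n_beads) and per-core reaction
// forces into fcore (3*n_np); returns potential energy
static double compute_forces(const FGModel& m, const std::vector<double>& x,
                             const std::vector<std::pair<int, int>>& nlist,
                             std::vector<double>& f, std::vector<double>& fcore) {
  std::fill(f.begin(), f.end(), 0.0);
  std::fill(fcore.begin(), fcore.end(), 0.0);
  double epot = 0.0;

  // nonbonded bead-bead
  for (const auto& pr : nlist) {
    int i = pr.first, j = pr.second;
    double u[3], r2 = 0;
    for (int d = 0; d < 3; ++d) { u[d] = x[3 * i + d] - x[3 * j + d]; r2 += u[d] * u[d]; }
    if (r2 >= m.rc * m.rc) continue;
    double r = std::sqrt(r2);
    if (r < 0.3) r = 0.3;  // overlap guard for the minimization phase
    double e, fr;
    mod_lj(r, m.s, m.beta_eps, m.rc, e, fr);
    epot += e;
    for (int d = 0; d < 3; ++d) {
      double fd = fr * u[d] / r;
      f[3 * i + d] += fd;
      f[3 * j + d] -= fd;
    }
  }

  // bead-core surface-shifted WCA
  for (int i = 0; i < m.n_beads; ++i) {
    for (int c = 0; c < m.n_np; ++c) {
      double u[3], r2 = 0;
      for (int d = 0; d < 3; ++d) {
        u[d] = x[3 * i + d] - m.cores[3 * c + d];
        r2 += u[d] * u[d];
      }
      double r = std::sqrt(r2);
      double del = r - m.core_shift;
      if (del >= WCA_RMIN) continue;
      if (del < 0.2) del = 0.2;  // finite cap inside the core
      double inv2 = 1.0 / (del * del);
      double inv6 = inv2 * inv2 * inv2;
      epot += 4.0 * m.beta_eps * inv6 * (inv6 - 1.0) + m.beta_eps;
      double fr = 24.0 * m.beta_eps * inv6 * (2.0 * inv6 - 1.0) / del;
      for (int d = 0; d < 3; ++d) {
        double fd = fr * u[d] / r;
        f[3 * i + d] += fd;
        fcore[3 * c + d] -= fd;
      }
    }
  }

  // bead-bead bonds
  for (size_t b = 0; b < m.bond_i.size(); ++b) {
    int i = m.bond_i[b], j = m.bond_j[b];
    double u[3], r2 = 0;
    for (int d = 0; d < 3; ++d) { u[d] = x[3 * i + d] - x[3 * j + d]; r2 += u[d] * u[d]; }
    double r = std::sqrt(r2);
    epot += m.Kb * (r - m.b0) * (r - m.b0);
    double fr = -2.0 * m.Kb * (r - m.b0);
    for (int d = 0; d < 3; ++d) {
      double fd = fr * u[d] / r;
      f[3 * i + d] += fd;
      f[3 * j + d] -= fd;
    }
  }

  // grafting bonds (bead to fixed site; reaction force on the core)
  for (size_t g = 0; g < m.anchor_bead.size(); ++g) {
    int i = m.anchor_bead[g];
    int c = m.graft_core[g];
    double u[3], r2 = 0;
    for (int d = 0; d < 3; ++d) {
      u[d] = x[3 * i + d] - m.grafts[3 * g + d];
      r2 += u[d] * u[d];
    }
    double r = std::sqrt(r2);
    if (r < 1e-12) continue;
    epot += m.Kb * (r - m.b0) * (r - m.b0);
    double fr = -2.0 * m.Kb * (r - m.b0);
    for (int d = 0; d < 3; ++d) {
      double fd = fr * u[d] / r;
      f[3 * i + d] += fd;
      fcore[3 * c + d] -= fd;
    }
  }

  // angles
  for (size_t a = 0; a < m.ang_a.size(); ++a) {
    int ia = m.ang_a[a], ib = m.ang_b[a], ic = m.ang_c[a];
    double u[3], v[3];
    double ru2 = 0, rv2 = 0, dot = 0;
    for (int d = 0; d < 3; ++d) {
      u[d] = x[3 * ia + d] - x[3 * ib + d];
      v[d] = x[3 * ic + d] - x[3 * ib + d];
      ru2 += u[d] * u[d]; rv2 += v[d] * v[d]; dot += u[d] * v[d];
    }
    double ru = std::sqrt(ru2), rv = std::sqrt(rv2);
    double c = dot / (ru * rv);
    if (c > 1.0) c = 1.0;
    if (c < -1.0) c = -1.0;
    double th = std::acos(c);
    epot += m.Kth * (th - m.th0) * (th - m.th0);
    double sth = std::sqrt(1.0 - c * c);
    if (sth < 1e-8) sth = 1e-8;
    double pref = 2.0 * m.Kth * (th - m.th0) / sth;  // dE/dc = -dE/dth / sin
    for (int d = 0; d < 3; ++d) {
      double dca = (v[d] / (ru * rv)) - c * u[d] / ru2;
      double dcc = (u[d] / (ru * rv)) - c * v[d] / rv2;
      f[3 * ia + d] += pref * dca;
      f[3 * ic + d] += pref * dcc;
      f[3 * ib + d] -= pref * (dca + dcc);
    }
  }
  return epot;
}

static void build_nlist(const FGModel& m, const std::vector<double>& x,
                        double rl, std::vector<std::pair<int, int>>& nlist) {
  nlist.clear();
  double rl2 = rl * rl;
  for (int i = 0; i < m.n_beads; ++i) {
    const auto& exi = m.excl[i];
    for (int j = i + 1; j < m.n_beads; ++j) {
      double r2 = 0;
      for (int d = 0; d < 3; ++d) {
        double dd = x[3 * i + d] - x[3 * j + d];
        r2 += dd * dd;
      }
      if (r2 < rl2 &&
          !std::binary_search(exi.begin(), exi.end(), j))
        nlist.emplace_back(i, j);
    }
  }
}

// [[Rcpp::export]]
List cpp_langevin_mean_forces(NumericMatrix beads0, NumericMatrix cores,
                              NumericMatrix grafts, IntegerVector graft_core,
                              IntegerVector anchor_bead, IntegerMatrix bonds,
                              IntegerMatrix angles, List params,
                              int n_min, int n_equil, int n_prod,
                              double dt, double gamma, int n_blocks) {
  FGModel m;
  m.s = as<double>(params["s"]);
  m.beta_eps = as<double>(params["beta_eps"]);
  m.Kb = as<double>(params["Kb"]);
  m.b0 = as<double>(params["b0"]);
  m.Kth = as<double>(params["Kth"]);
  m.th0 = as<double>(params["th0"]);
  m.rc = as<double>(params["rc_bead"]);
  m.core_shift = as<double>(params["core_shift"]);
  m.n_beads = beads0.nrow();
  m.n_np = cores.nrow();
  m.cores.resize(3 * m.n_np);
  for (int i = 0; i < m.n_np; ++i)
    for (int d = 0; d < 3; ++d) m.cores[3 * i + d] = cores(i, d);
  int n_graft = grafts.nrow();
  m.grafts.resize(3 * n_graft);
  for (int g = 0; g < n_graft; ++g)
    for (int d = 0; d < 3; ++d) m.grafts[3 * g + d] = grafts(g, d);
  m.graft_core.assign(graft_core.begin(), graft_core.end());
  m.anchor_bead.assign(anchor_bead.begin(), anchor_bead.end());
  for (int b = 0; b < bonds.nrow(); ++b) {
    m.bond_i.push_back(bonds(b, 0));
    m.bond_j.push_back(bonds(b, 1));
  }
  for (int a = 0; a < angles.nrow(); ++a) {
    m.ang_a.push_back(angles(a, 0));
    m.ang_b.push_back(angles(a, 1));
    m.ang_c.push_back(angles(a, 2));
  }
  // exclusions: directly bonded bead pairs
  m.excl.assign(m.n_beads, {});
  for (size_t b = 0; b < m.bond_i.size(); ++b) {
    m.excl[m.bond_i[b]].push_back(m.bond_j[b]);
    m.excl[m.bond_j[b]].push_back(m.bond_i[b]);
  }
  for (auto& e : m.excl) std::sort(e.begin(), e.end());

  std::vector<double> x(3 * m.n_beads), v(3 * m.n_beads, 0.0);
  for (int i = 0; i < m.n_beads; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = beads0(i, d);

  double skin = 0.4;
  double rl = m.rc + skin;
  std::vector<std::pair<int, int>> nlist;
  std::vector<double> xref = x;
  build_nlist(m, x, rl, nlist);
  std::vector<double> f(3 * m.n_beads), fcore(3 * m.n_np);

  auto maybe_rebuild = [&]() {
    double maxd2 = 0;
    for (int i = 0; i < m.n_beads; ++i) {
      double d2 = 0;
      for (int d = 0; d < 3; ++d) {
        double dd = x[3 * i + d] - xref[3 * i + d];
        d2 += dd * dd;
      }
      if (d2 > maxd2) maxd2 = d2;
    }
    if (maxd2 > 0.25 * skin * skin * 0.25) {  // (skin/2)^2 / ... conservative
      build_nlist(m, x, rl, nlist);
      xref = x;
    }
  };

  // steepest-descent overlap removal with capped displacement
  for (int it = 0; it < n_min; ++it) {
    compute_forces(m, x, nlist, f, fcore);
    for (int i = 0; i < 3 * m.n_beads; ++i) {
      double dx = 1e-4 * f[i];
      if (dx > 0.02) dx = 0.02;
      if (dx < -0.02) dx = -0.02;
      x[i] += dx;
    }
    maybe_rebuild();
  }

  double epot = compute_forces(m, x, nlist, f, fcore);
  double c1 = std::exp(-gamma * dt);
  double c2 = std::sqrt(1.0 - c1 * c1);

  // block accumulators for per-core mean forces
  if (n_blocks < 1) n_blocks = 1;
  std::vector<double> block_acc(3 * m.n_np * n_blocks, 0.0);
  std::vector<long> block_n(n_blocks, 0);
  long steps_per_block = std::max(1, n_prod / n_blocks);
  double e_acc = 0.0;
  long n_e = 0;

  long total = (long) n_equil + n_prod;
  for (long step = 0; step < total; ++step) {
    // BAOAB
    for (int i = 0; i < 3 * m.n_beads; ++i) v[i] += 0.5 * dt * f[i];
    for (int i = 0; i < 3 * m.n_beads; ++i) x[i] += 0.5 * dt * v[i];
    for (int i = 0; i < 3 * m.n_beads; ++i)
      v[i] = c1 * v[i] + c2 * norm_rand();
    for (int i = 0; i < 3 * m.n_beads; ++i) x[i] += 0.5 * dt * v[i];
    maybe_rebuild();
    epot = compute_forces(m, x, nlist, f, fcore);
    for (int i = 0; i < 3 * m.n_beads; ++i) v[i] += 0.5 * dt * f[i];

    if (!std::isfinite(epot))
      stop("thermostat instability: potential energy diverged");

    if (step >= n_equil) {
      long ps = step - n_equil;
      int blk = std::min((int) (ps / steps_per_block), n_blocks - 1);
      for (int i = 0; i < 3 * m.n_np; ++i)
        block_acc[blk * 3 * m.n_np + i] += fcore[i];
      ++block_n[blk];
      e_acc += epot;
      ++n_e;
    }
  }

  NumericMatrix mf(m.n_np, 3), mfse(m.n_np, 3);
  for (int c = 0; c < m.n_np; ++c) {
    for (int d = 0; d < 3; ++d) {
      double mean = 0.0;
      std::vector<double> bm(n_blocks);
      for (int b = 0; b < n_blocks; ++b) {
        bm[b] = block_acc[b * 3 * m.n_np + 3 * c + d] / std::max(block_n[b], 1L);
        mean += bm[b];
      }
      mean /= n_blocks;
      double var = 0.0;
      for (int b = 0; b < n_blocks; ++b) var += (bm[b] - mean) * (bm[b] - mean);
      var /= std::max(n_blocks - 1, 1);
      mf(c, d) = mean;
      mfse(c, d) = std::sqrt(var / n_blocks);
    }
  }

  NumericMatrix xf(m.n_beads, 3);
  for (int i = 0; i < m.n_beads; ++i)
    for (int d = 0; d < 3; ++d) xf(i, d) = x[3 * i + d];

  return List::create(_["mean_force"] = mf, _["mean_force_se"] = mfse,
                      _["beads"] = xf,
                      _["mean_epot"] = n_e ? e_acc / n_e : NA_REAL);
}
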