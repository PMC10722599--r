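// Metropolis Monte Carlo for coarse-grained particles in a cubic periodic box.
// Two interaction back-ends:
//   - a linear symmetry-function model (per-site contributions Phi_K, shared
//     code path with the descriptor evaluator), or
//   - a tabulated pair potential with linear interpolation (used for
//     cross-checks against analytic pair interactions).
// Energies in k_B T, lengths in sigma_c, pressure reduced (P sigma_c^3/kT).
#include "sf_common.h"
using namespace Rcpp;
using namespace cgpmf;

struct PairTable {
  bool active = false;
  std::vector<double> r, u;
  double rmax = 0, dr = 0;
  double eval(double x) const {
    if (x >= rmax) return 0.0;
    if (x <= r.front()) return u.front();
    double f = (x - r.front()) / dr;
    int i = (int) f;
    if (i >= (int) r.size() - 1) return u.back();
    double t = f - i;
    return u[i] * (1.0 - t) + u[i + 1] * t;
  }
};

struct MCSystem {
  int N;
  double L;          // cubic box edge
  std::vector<double> x;  // 3N
  std::vector<Spec> specs;
  std::vector<double> w;
  double rcm;
  PairTable tab;

  Box box() const {
    Box b;
    b.periodic = true;
    b.L[0] = b.L[1] = b.L[2] = L;
    return b;
  }

  double mindist2(int i, const double* p) const {
    Box b = box();
    double u[3], r;
    disp_xyz(p, &x[3 * i], b, u, r);
    return r;
  }

  double phi_site(int K) const {
    Box b = box();
    if (tab.active) {
      double u[3], r, e = 0.0;
      for (int J = 0; J < N; ++J) {
        if (J == K) continue;
        disp_xyz(&x[3 * K], &x[3 * J], b, u, r);
        if (r < R_DEGEN) stop("degenerate geometry: coincident particles");
        if (r < tab.rmax) e += 0.5 * tab.eval(r);
      }
      return e;
    }
    return site_energy(x.data(), N, K, b, specs, w.data(), rcm);
  }

  double interaction_range() const { return tab.active ? tab.rmax : rcm; }
};

// [[Rcpp::export]]
List cpp_mc_run(NumericMatrix pos0, double L0, NumericMatrix specmat,
                NumericVector weights, List pairtab, int npt, double pressure,
                int n_equil, int n_prod, double step0, double lnvstep0,
                int frame_stride, double gr_bin, double gr_rmax,
                double hard_core) {
  MCSystem sys;
  sys.N = pos0.nrow();
  sys.L = L0;
  sys.x.resize(3 * sys.N);
  for (int i = 0; i < sys.N; ++i)
    for (int d = 0; d < 3; ++d) sys.x[3 * i + d] = pos0(i, d);

  if (pairtab.size() > 0) {
    sys.tab.active = true;
    NumericVector tr = pairtab["r"], tu = pairtab["u"];
    sys.tab.r.assign(tr.begin(), tr.end());
    sys.tab.u.assign(tu.begin(), tu.end());
    sys.tab.rmax = sys.tab.r.back();
    sys.tab.dr = sys.tab.r[1] - sys.tab.r[0];
    sys.rcm = 0;
  } else {
    sys.specs = parse_specs(specmat);
    sys.w.assign(weights.begin(), weights.end());
    sys.rcm = max_rc(sys.specs);
  }
  double range = sys.interaction_range();
  if (sys.L < 2.0 * range)
    stop("box edge must be at least twice the interaction range");

  if (hard_core > 0) {
    Box b0 = sys.box();
    double u[3], r;
    for (int a = 0; a < sys.N; ++a)
      for (int c = a + 1; c < sys.N; ++c) {
        disp_xyz(&sys.x[3 * a], &sys.x[3 * c], b0, u, r);
        if (r < hard_core) stop("initial configuration has hard-core overlaps");
      }
  }

  std::vector<double> phi(sys.N);
  double etot = 0.0;
  for (int K = 0; K < sys.N; ++K) { phi[K] = sys.phi_site(K); etot += phi[K]; }

  double step = step0, lnvstep = lnvstep0;
  long tr_att = 0, tr_acc = 0, v_att = 0, v_acc = 0;
  long tr_att_win = 0, tr_acc_win = 0, v_att_win = 0, v_acc_win = 0;

  int n_gr = (gr_rmax > 0) ? (int) std::ceil(gr_rmax / gr_bin) : 0;
  std::vector<double> gr_hist(std::max(n_gr, 1), 0.0);
  long gr_frames = 0;
  double gr_rho_acc = 0.0;

  std::vector<NumericMatrix> frames;
  std::vector<double> frame_L;
  double dens_acc = 0.0, dens2_acc = 0.0, e_acc = 0.0;
  long n_obs = 0;
  std::vector<double> dens_series;

  std::vector<int> affected;
  affected.reserve(sys.N);

  int total_sweeps = n_equil + n_prod;
  for (int sweep = 0; sweep < total_sweeps; ++sweep) {
    bool prod = sweep >= n_equil;
    for (int mv = 0; mv < sys.N; ++mv) {
      int i = (int) std::floor(unif_rand() * sys.N);
      if (i == sys.N) --i;
      double oldp[3] = { sys.x[3 * i], sys.x[3 * i + 1], sys.x[3 * i + 2] };
      double newp[3];
      for (int d = 0; d < 3; ++d) {
        double xn = oldp[d] + step * (unif_rand() - 0.5);
        xn -= sys.L * std::floor(xn / sys.L);
        newp[d] = xn;
      }
      ++tr_att; ++tr_att_win;

      if (hard_core > 0) {
        Box b = sys.box();
        double u[3], r;
        bool overlap = false;
        for (int J = 0; J < sys.N && !overlap; ++J) {
          if (J == i) continue;
          disp_xyz(newp, &sys.x[3 * J], b, u, r);
          if (r < hard_core) overlap = true;
        }
        if (overlap) continue;  // reject
      }

      double de;
      if (sys.tab.active) {
        // direct pair-energy difference
        Box b = sys.box();
        double u[3], r;
        de = 0.0;
        for (int J = 0; J < sys.N; ++J) {
          if (J == i) continue;
          disp_xyz(newp, &sys.x[3 * J], b, u, r);
          if (r < sys.tab.rmax) de += sys.tab.eval(r);
          disp_xyz(oldp, &sys.x[3 * J], b, u, r);
          if (r < sys.tab.rmax) de -= sys.tab.eval(r);
        }
        if (de <= 0.0 || unif_rand() < std::exp(-de)) {
          for (int d = 0; d < 3; ++d) sys.x[3 * i + d] = newp[d];
          etot += de;
          ++tr_acc; ++tr_acc_win;
        }
      } else {
        // affected sites: within rcm of old or new position, plus i itself
        affected.clear();
        for (int K = 0; K < sys.N; ++K) {
          if (K == i) { affected.push_back(K); continue; }
          if (sys.mindist2(K, oldp) <= sys.rcm ||
              sys.mindist2(K, newp) <= sys.rcm)
            affected.push_back(K);
        }
        double old_sum = 0.0;
        for (int K : affected) old_sum += phi[K];
        for (int d = 0; d < 3; ++d) sys.x[3 * i + d] = newp[d];
        double new_sum = 0.0;
        std::vector<double> newphi(affected.size());
        for (size_t a = 0; a < affected.size(); ++a) {
          newphi[a] = sys.phi_site(affected[a]);
          new_sum += newphi[a];
        }
        de = new_sum - old_sum;
        if (de <= 0.0 || unif_rand() < std::exp(-de)) {
          for (size_t a = 0; a < affected.size(); ++a)
            phi[affected[a]] = newphi[a];
          etot += de;
          ++tr_acc; ++tr_acc_win;
        } else {
          for (int d = 0; d < 3; ++d) sys.x[3 * i + d] = oldp[d];
        }
      }
    }

    if (npt) {
      ++v_att; ++v_att_win;
      double V = sys.L * sys.L * sys.L;
      double lnVn = std::log(V) + lnvstep * (unif_rand() - 0.5);
      double Vn = std::exp(lnVn);
      double Ln = std::cbrt(Vn);
      if (Ln < 2.0 * range) {
        stop("NPT box shrank below twice the interaction range");
      } else {
        double scale = Ln / sys.L;
        std::vector<double> xold = sys.x;
        double Lold = sys.L;
        for (double& xx : sys.x) xx *= scale;
        sys.L = Ln;
        bool overlap = false;
        if (hard_core > 0 && scale < 1.0) {
          Box b = sys.box();
          double u[3], r;
          for (int a = 0; a < sys.N && !overlap; ++a)
            for (int c = a + 1; c < sys.N && !overlap; ++c) {
              disp_xyz(&sys.x[3 * a], &sys.x[3 * c], b, u, r);
              if (r < hard_core) overlap = true;
            }
        }
        if (overlap) {
          sys.x = xold;
          sys.L = Lold;
        } else {
          double enew = 0.0;
          std::vector<double> phinew(sys.N);
          for (int K = 0; K < sys.N; ++K) {
            phinew[K] = sys.phi_site(K);
            enew += phinew[K];
          }
          double arg = -(enew - etot) - pressure * (Vn - V) +
                       (sys.N + 1) * (lnVn - std::log(V));
          if (arg >= 0.0 || unif_rand() < std::exp(arg)) {
            phi = phinew;
            etot = enew;
            ++v_acc; ++v_acc_win;
          } else {
            sys.x = xold;
            sys.L = Lold;
          }
        }
      }
    }

    // step-size tuning during equilibration only
    if (!prod) {
      if (tr_att_win >= 200) {
        double ar = (double) tr_acc_win / tr_att_win;
        if (ar > 0.5) step = std::min(step * 1.1, sys.L / 4.0);
        else if (ar < 0.2) step *= 0.9;
        tr_att_win = tr_acc_win = 0;
      }
      if (npt && v_att_win >= 50) {
        double ar = (double) v_acc_win / v_att_win;
        if (ar > 0.5) lnvstep = std::min(lnvstep * 1.1, 0.5);
        else if (ar < 0.2) lnvstep *= 0.9;
        v_att_win = v_acc_win = 0;
      }
      if (sweep == n_equil - 1) { tr_att = tr_acc = v_att = v_acc = 0; }
    }

    if (prod) {
      double V = sys.L * sys.L * sys.L;
      double rho = sys.N / V;
      dens_acc += rho; dens2_acc += rho * rho; e_acc += etot;
      dens_series.push_back(rho);
      ++n_obs;
      int psweep = sweep - n_equil;
      if (n_gr > 0 && psweep % std::max(frame_stride, 1) == 0) {
        Box b = sys.box();
        double u[3], r;
        double rmax_eff = std::min(gr_rmax, sys.L / 2.0);
        for (int a = 0; a < sys.N; ++a)
          for (int c = a + 1; c < sys.N; ++c) {
            disp_xyz(&sys.x[3 * a], &sys.x[3 * c], b, u, r);
            if (r < rmax_eff) {
              int bin = (int) (r / gr_bin);
              if (bin < n_gr) gr_hist[bin] += 2.0;
            }
          }
        ++gr_frames;
        gr_rho_acc += rho;
      }
      if (frame_stride > 0 && psweep % frame_stride == 0) {
        NumericMatrix fr(sys.N, 3);
        for (int a = 0; a < sys.N; ++a)
          for (int d = 0; d < 3; ++d) fr(a, d) = sys.x[3 * a + d];
        frames.push_back(fr);
        frame_L.push_back(sys.L);
      }
    }
  }

  // full recomputation for the bookkeeping check
  double efull = 0.0;
  for (int K = 0; K < sys.N; ++K) efull += sys.phi_site(K);

  NumericMatrix posf(sys.N, 3);
  for (int i = 0; i < sys.N; ++i)
    for (int d = 0; d < 3; ++d) posf(i, d) = sys.x[3 * i + d];

  List frl(frames.size());
  for (size_t i = 0; i < frames.size(); ++i) frl[i] = frames[i];

  return List::create(
      _["positions"] = posf, _["L"] = sys.L,
      _["energy_tracked"] = etot, _["energy_recomputed"] = efull,
      _["mean_density"] = n_obs ? dens_acc / n_obs : NA_REAL,
      _["mean_energy"] = n_obs ? e_acc / n_obs : NA_REAL,
      _["density_series"] = wrap(dens_series),
      _["acc_translation"] = tr_att ? (double) tr_acc / tr_att : NA_REAL,
      _["acc_volume"] = v_att ? (double) v_acc / v_att : NA_REAL,
      _["step_final"] = step, _["lnvstep_final"] = lnvstep,
      _["gr_hist"] = wrap(gr_hist), _["gr_frames"] = (double) gr_frames,
      _["gr_rho_mean"] = gr_frames ? gr_rho_acc / gr_frames : NA_REAL,
      _["gr_bin"] = gr_bin,
      _["frames"] = frl, _["frame_L"] = wrap(frame_L));
}
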