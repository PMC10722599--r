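// Descriptor evaluation: symmetry-function values, force-matching design
// blocks (-sum_K grad_I G_J(K)) and dense gradient tensors for validation.
#include "sf_common.h"
using namespace Rcpp;
using namespace cgpmf;

// Rcpp matrices are column-major; gather a row into a contiguous triple.
static inline void row3(const NumericMatrix& pos, int i, double* out) {
  out[0] = pos(i, 0); out[1] = pos(i, 1); out[2] = pos(i, 2);
}

static std::vector<int> neighbors_row(const NumericMatrix& pos, int K,
                                      const Box& b, double rc) {
  std::vector<int> nb;
  int N = pos.nrow();
  double xk[3], xj[3], u[3], r;
  row3(pos, K, xk);
  for (int J = 0; J < N; ++J) {
    if (J == K) continue;
    row3(pos, J, xj);
    disp_xyz(xk, xj, b, u, r);
    if (r <= rc) {
      if (r < R_DEGEN) stop("degenerate geometry: coincident particles");
      nb.push_back(J);
    }
  }
  return nb;
}

static inline void pair_disp(const NumericMatrix& pos, int I, int J,
                             const Box& b, double* u, double& r) {
  double xi[3], xj[3];
  row3(pos, I, xi);
  row3(pos, J, xj);
  disp_xyz(xi, xj, b, u, r);
}

// [[Rcpp::export]]
NumericMatrix cpp_sf_values(NumericMatrix pos, NumericVector box,
                            NumericMatrix specmat) {
  std::vector<Spec> specs = parse_specs(specmat);
  double rcm = max_rc(specs);
  Box b = parse_box(box, rcm);
  int N = pos.nrow(), M = (int) specs.size();
  NumericMatrix out(N, M);
  double u[3], v[3], r1, r2;
  for (int K = 0; K < N; ++K) {
    std::vector<int> nb = neighbors_row(pos, K, b, rcm);
    for (int j = 0; j < M; ++j) {
      const Spec& s = specs[j];
      double acc = 0.0;
      if (s.kind == 0) {
        for (int J : nb) {
          pair_disp(pos, K, J, b, u, r1);
          if (r1 > s.Rc) continue;
          double g, dg;
          radial_term(s, r1, g, dg);
          acc += g;
        }
      } else {
        for (size_t a = 0; a + 1 < nb.size(); ++a) {
          pair_disp(pos, K, nb[a], b, u, r1);
          if (r1 > s.Rc) continue;
          for (size_t c2 = a + 1; c2 < nb.size(); ++c2) {
            pair_disp(pos, K, nb[c2], b, v, r2);
            if (r2 > s.Rc) continue;
            acc += angular_term(s, u, r1, v, r2, false,
                                nullptr, nullptr, nullptr);
          }
        }
      }
      out(K, j) = acc;
    }
  }
  return out;
}

// Design block for force matching: entry [(3I+a), J] = -sum_K dG_J(K)/dR_{I,a}.
// [[Rcpp::export]]
NumericMatrix cpp_sf_design(NumericMatrix pos, NumericVector box,
                            NumericMatrix specmat) {
  std::vector<Spec> specs = parse_specs(specmat);
  double rcm = max_rc(specs);
  Box b = parse_box(box, rcm);
  int N = pos.nrow(), M = (int) specs.size();
  NumericMatrix out(3 * N, M);
  double u[3], v[3], r1, r2, gI[3], gJ[3], gK[3];
  for (int K = 0; K < N; ++K) {
    std::vector<int> nb = neighbors_row(pos, K, b, rcm);
    for (int j = 0; j < M; ++j) {
      const Spec& s = specs[j];
      if (s.kind == 0) {
        for (int J : nb) {
          pair_disp(pos, K, J, b, u, r1);
          if (r1 > s.Rc) continue;
          double g, dg;
          radial_term(s, r1, g, dg);
          for (int d = 0; d < 3; ++d) {
            double comp = dg * u[d] / r1;     // dG_j(K)/dR_{K,d} contribution
            out(3 * K + d, j) -= comp;
            out(3 * J + d, j) += comp;        // dG_j(K)/dR_{J,d} = -comp
          }
        }
      } else {
        for (size_t a = 0; a + 1 < nb.size(); ++a) {
          int Ja = nb[a];
          pair_disp(pos, K, Ja, b, u, r1);
          if (r1 > s.Rc) continue;
          for (size_t c2 = a + 1; c2 < nb.size(); ++c2) {
            int Kb = nb[c2];
            pair_disp(pos, K, Kb, b, v, r2);
            if (r2 > s.Rc) continue;
            for (int d = 0; d < 3; ++d) { gI[d] = gJ[d] = gK[d] = 0; }
            angular_term(s, u, r1, v, r2, true, gI, gJ, gK);
            for (int d = 0; d < 3; ++d) {
              out(3 * K + d, j) -= gI[d];
              out(3 * Ja + d, j) -= gJ[d];
              out(3 * Kb + d, j) -= gK[d];
            }
          }
        }
      }
    }
  }
  return out;
}

// Full gradient tensor dG_J(K)/dR_{I,a} as a dense array (N, 3, M, N),
// intended for validation on small systems.
// [[Rcpp::export]]
NumericVector cpp_sf_grad_tensor(NumericMatrix pos, NumericVector box,
                                 NumericMatrix specmat) {
  std::vector<Spec> specs = parse_specs(specmat);
  double rcm = max_rc(specs);
  Box b = parse_box(box, rcm);
  int N = pos.nrow(), M = (int) specs.size();
  if (N > 64) stop("dense gradient tensor is intended for small systems (N <= 64)");
  NumericVector out((R_xlen_t) N * 3 * M * N);  // [I, d, j, K] column-major
  auto idx = [N, M](int I, int d, int j, int K) {
    return ((K * (R_xlen_t) M + j) * 3 + d) * N + I;
  };
  double u[3], v[3], r1, r2, gI[3], gJ[3], gK[3];
  for (int K = 0; K < N; ++K) {
    std::vector<int> nb = neighbors_row(pos, K, b, rcm);
    for (int j = 0; j < M; ++j) {
      const Spec& s = specs[j];
      if (s.kind == 0) {
        for (int J : nb) {
          pair_disp(pos, K, J, b, u, r1);
          if (r1 > s.Rc) continue;
          double g, dg;
          radial_term(s, r1, g, dg);
          for (int d = 0; d < 3; ++d) {
            double comp = dg * u[d] / r1;
            out[idx(K, d, j, K)] += comp;
            out[idx(J, d, j, K)] -= comp;
          }
        }
      } else {
        for (size_t a = 0; a + 1 < nb.size(); ++a) {
          int Ja = nb[a];
          pair_disp(pos, K, Ja, b, u, r1);
          if (r1 > s.Rc) continue;
          for (size_t c2 = a + 1; c2 < nb.size(); ++c2) {
            int Kb = nb[c2];
            pair_disp(pos, K, Kb, b, v, r2);
            if (r2 > s.Rc) continue;
            for (int d = 0; d < 3; ++d) { gI[d] = gJ[d] = gK[d] = 0; }
            angular_term(s, u, r1, v, r2, true, gI, gJ, gK);
            for (int d = 0; d < 3; ++d) {
              out[idx(K, d, j, K)] += gI[d];
              out[idx(Ja, d, j, K)] += gJ[d];
              out[idx(Kb, d, j, K)] += gK[d];
            }
          }
        }
      }
    }
  }
  return out;
}

// Per-site model energies Phi_K for a configuration (shared MC code path).
// [[Rcpp::export]]
NumericVector cpp_site_energies(NumericMatrix pos, NumericVector box,
                                NumericMatrix specmat, NumericVector w) {
  std::vector<Spec> specs = parse_specs(specmat);
  if ((int) specs.size() != w.size()) stop("weights/specs length mismatch");
  double rcm = max_rc(specs);
  Box b = parse_box(box, rcm);
  int N = pos.nrow();
  std::vector<double> x(3 * N);
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = pos(i, d);
  NumericVector out(N);
  for (int K = 0; K < N; ++K)
    out[K] = site_energy(x.data(), N, K, b, specs, REAL(w), rcm);
  return out;
}
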