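// Shared kernels: minimum-image geometry, cutoff function, radial and angular
// Behler-Parrinello symmetry-function terms. Included by the descriptor
// evaluators and by the Monte Carlo engine so both use the identical
// energy/gradient code path.
#ifndef CGPMF_SF_COMMON_H
#define CGPMF_SF_COMMON_H

#include <Rcpp.h>
#include <cmath>
#include <vector>

namespace cgpmf {

static const double R_DEGEN = 1e-9;

struct Spec {
  int kind;  // 0 radial, 1 angular
  double mu, Rs, mua, xi, lambda, Rc;
};

inline std::vector<Spec> parse_specs(const Rcpp::NumericMatrix& sp) {
  if (sp.ncol() != 7) Rcpp::stop("spec matrix must have 7 columns");
  std::vector<Spec> out(sp.nrow());
  for (int j = 0; j < sp.nrow(); ++j) {
    out[j].kind = (int) sp(j, 0);
    out[j].mu = sp(j, 1); out[j].Rs = sp(j, 2); out[j].mua = sp(j, 3);
    out[j].xi = sp(j, 4); out[j].lambda = sp(j, 5); out[j].Rc = sp(j, 6);
    if (out[j].Rc <= 0) Rcpp::stop("R_c must be positive");
  }
  return out;
}

inline double max_rc(const std::vector<Spec>& sp) {
  double m = 0;
  for (const auto& s : sp) m = std::max(m, s.Rc);
  return m;
}

struct Box {
  bool periodic;
  double L[3];
};

inline Box parse_box(const Rcpp::NumericVector& box, double rcmax) {
  Box b;
  if (box.size() == 0 || Rcpp::NumericVector::is_na(box[0])) {
    b.periodic = false;
    b.L[0] = b.L[1] = b.L[2] = 0;
    return b;
  }
  if (box.size() != 3)
    Rcpp::stop("box must be length 3 or empty/NA for open boundaries");
  b.periodic = true;
  for (int d = 0; d < 3; ++d) {
    b.L[d] = box[d];
    if (!(b.L[d] > 0)) Rcpp::stop("box edge lengths must be positive");
    if (b.L[d] < 2.0 * rcmax)
      Rcpp::stop("minimum-image convention requires box >= 2 R_c on every edge");
  }
  return b;
}

// displacement R_I - R_J under minimum image (raw coordinate arrays)
inline void disp_xyz(const double* xi, const double* xj, const Box& b,
                     double* u, double& r) {
  double s = 0;
  for (int d = 0; d < 3; ++d) {
    double x = xi[d] - xj[d];
    if (b.periodic) x -= b.L[d] * std::nearbyint(x / b.L[d]);
    u[d] = x;
    s += x * x;
  }
  r = std::sqrt(s);
}

inline double fcut(double r, double Rc) {
  if (r > Rc) return 0.0;
  return 0.5 * (std::cos(M_PI * r / Rc) + 1.0);
}

inline double dfcut(double r, double Rc) {
  if (r > Rc) return 0.0;
  return -0.5 * M_PI / Rc * std::sin(M_PI * r / Rc);
}

// Radial pair term and its derivative with respect to r.
inline void radial_term(const Spec& s, double r, double& g, double& dg) {
  double e = std::exp(-s.mu * (r - s.Rs) * (r - s.Rs));
  double fc = fcut(r, s.Rc);
  g = e * fc;
  dg = e * (-2.0 * s.mu * (r - s.Rs) * fc + dfcut(r, s.Rc));
}

// Angular triplet term centered at I with neighbors J (u = R_I - R_J, r1)
// and K (v = R_I - R_K, r2); w = v - u = R_J - R_K. Adds gradients with
// respect to R_I, R_J, R_K into gI/gJ/gK when want_grad.
inline double angular_term(const Spec& s, const double* u, double r1,
                           const double* v, double r2, bool want_grad,
                           double* gI, double* gJ, double* gK) {
  double w[3];
  for (int d = 0; d < 3; ++d) w[d] = v[d] - u[d];
  double r3 = std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
  double fc3 = fcut(r3, s.Rc);
  if (fc3 == 0.0 && !want_grad) return 0.0;

  double c = (u[0] * v[0] + u[1] * v[1] + u[2] * v[2]) / (r1 * r2);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  double base = 1.0 + s.lambda * c;
  if (base < 0.0) base = 0.0;
  double pref = std::pow(2.0, 1.0 - s.xi);
  double P = pref * std::pow(base, s.xi);
  double E = std::exp(-s.mua * (r1 * r1 + r2 * r2 + r3 * r3));
  double f1 = fcut(r1, s.Rc), f2 = fcut(r2, s.Rc);
  double F = f1 * f2 * fc3;
  double t = P * E * F;
  if (!want_grad) return t;

  // one-sided derivative 0 at base == 0 (lambda cos = -1), a zero-measure set
  double dPdc;
  if (s.xi == 1.0) dPdc = pref * s.lambda;
  else dPdc = pref * s.xi * s.lambda * (base > 0 ? std::pow(base, s.xi - 1.0) : 0.0);

  double cI[3], cJ[3], cK[3], eI[3], eJ[3], eK[3], fI[3], fJ[3], fK[3];
  double d1 = dfcut(r1, s.Rc), d2 = dfcut(r2, s.Rc);
  double d3 = (r3 > R_DEGEN) ? dfcut(r3, s.Rc) : 0.0;
  for (int d = 0; d < 3; ++d) {
    cI[d] = (u[d] + v[d]) / (r1 * r2) - c * (u[d] / (r1 * r1) + v[d] / (r2 * r2));
    cJ[d] = -v[d] / (r1 * r2) + c * u[d] / (r1 * r1);
    cK[d] = -u[d] / (r1 * r2) + c * v[d] / (r2 * r2);
    eI[d] = -2.0 * s.mua * (u[d] + v[d]) * E;
    eJ[d] = -2.0 * s.mua * (-u[d] + w[d]) * E;
    eK[d] = -2.0 * s.mua * (-v[d] - w[d]) * E;
    double u1 = u[d] / r1, v1 = v[d] / r2;
    double w1 = (r3 > R_DEGEN) ? w[d] / r3 : 0.0;
    fI[d] = d1 * u1 * f2 * fc3 + d2 * v1 * f1 * fc3;
    fJ[d] = -d1 * u1 * f2 * fc3 + d3 * w1 * f1 * f2;
    fK[d] = -d2 * v1 * f1 * fc3 - d3 * w1 * f1 * f2;
  }
  for (int d = 0; d < 3; ++d) {
    gI[d] += dPdc * cI[d] * E * F + P * eI[d] * F + P * E * fI[d];
    gJ[d] += dPdc * cJ[d] * E * F + P * eJ[d] * F + P * E * fJ[d];
    gK[d] += dPdc * cK[d] * E * F + P * eK[d] * F + P * E * fK[d];
  }
  return t;
}

// Per-site model energy Phi_K = sum_j w_j G_j(K) for positions stored as a
// flat array x (3N, row K at x + 3K).
inline double site_energy(const double* x, int N, int K, const Box& b,
                          const std::vector<Spec>& specs,
                          const double* w, double rcm) {
  std::vector<int> nb;
  std::vector<double> uu;
  std::vector<double> rr;
  double u[3], r;
  for (int J = 0; J < N; ++J) {
    if (J == K) continue;
    disp_xyz(x + 3 * K, x + 3 * J, b, u, r);
    if (r <= rcm) {
      if (r < R_DEGEN) Rcpp::stop("degenerate geometry: coincident particles");
      nb.push_back(J);
      uu.push_back(u[0]); uu.push_back(u[1]); uu.push_back(u[2]);
      rr.push_back(r);
    }
  }
  double phi = 0.0;
  int M = (int) specs.size();
  for (int j = 0; j < M; ++j) {
    const Spec& s = specs[j];
    if (w[j] == 0.0) continue;
    double acc = 0.0;
    if (s.kind == 0) {
      for (size_t a = 0; a < nb.size(); ++a) {
        if (rr[a] > s.Rc) continue;
        double g, dg;
        radial_term(s, rr[a], g, dg);
        acc += g;
      }
    } else {
      for (size_t a = 0; a + 1 < nb.size(); ++a) {
        if (rr[a] > s.Rc) continue;
        for (size_t c2 = a + 1; c2 < nb.size(); ++c2) {
          if (rr[c2] > s.Rc) continue;
          acc += angular_term(s, &uu[3 * a], rr[a], &uu[3 * c2], rr[c2],
                              false, nullptr, nullptr, nullptr);
        }
      }
    }
    phi += w[j] * acc;
  }
  return phi;
}

}  // namespace cgpmf

#endif
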