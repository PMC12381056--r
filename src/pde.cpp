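// Explicit finite-difference kernels for the two PDE stages:
//  - heat-equation inpainting with a data-fidelity term outside the mask,
//  - Chan-Vese level-set evolution (run in fixed-size chunks; the R driver
//    handles signed-distance reinitialization and the stopping rule).
// Both use homogeneous Neumann boundaries via clamped (mirror) indexing.
// Matrices are column-major (R layout): index i = y + H * x.

#include <Rcpp.h>
using namespace Rcpp;

static inline int clampi(int i, int n) {
  if (i < 0) return 0;
  if (i >= n) return n - 1;
  return i;
}

// du/dt = lambda * Laplacian(u) + chi * (f - u), u(0) = f.
// chi = 1 on known pixels, 0 on the inpainting domain.
// [[Rcpp::export]]
List inpaint_cpp(NumericMatrix f_, NumericMatrix chi_, double lambda,
                 double dt, double eps_stop, int max_steps) {
  int H = f_.nrow(), W = f_.ncol();
  NumericMatrix u_(clone(f_)), un_(H, W);
  double *u = REAL(u_), *un = REAL(un_);
  const double *f = REAL(f_), *chi = REAL(chi_);
  double max_change = R_PosInf;
  int step = 0;
  bool converged = false;
  for (step = 1; step <= max_steps; ++step) {
    max_change = 0.0;
    for (int x = 0; x < W; ++x) {
      const double *cm = u + (size_t)H * clampi(x - 1, W);
      const double *cc = u + (size_t)H * x;
      const double *cp = u + (size_t)H * clampi(x + 1, W);
      const double *fc = f + (size_t)H * x;
      const double *xc = chi + (size_t)H * x;
      double *oc = un + (size_t)H * x;
      for (int y = 0; y < H; ++y) {
        int ym = (y == 0) ? 0 : y - 1;
        int yp = (y == H - 1) ? H - 1 : y + 1;
        double lap = cc[ym] + cc[yp] + cm[y] + cp[y] - 4.0 * cc[y];
        double v = cc[y] + dt * (lambda * lap + xc[y] * (fc[y] - cc[y]));
        oc[y] = v;
        double ch = std::fabs(v - cc[y]);
        if (ch > max_change) max_change = ch;
      }
    }
    std::swap(u, un);
    if (max_change < eps_stop) { converged = true; break; }
  }
  if (step > max_steps) step = max_steps;
  NumericMatrix out_ = (u == REAL(u_)) ? u_ : un_;
  return List::create(_["u"] = out_, _["steps"] = step,
                      _["converged"] = converged, _["max_change"] = max_change);
}

// Chan-Vese gradient-descent chunk on unit-scaled intensities:
//   dphi/dt = delta_eps(phi) [ mu * div(grad phi / |grad phi|)
//                              - l1 (I - a1)^2 + l2 (I - a2)^2 ],
// alternating with closed-form region-mean updates a1, a2 (means weighted by
// the regularized Heaviside H_eps). Returns the final means, the discretized
// energy trace and per-iteration interface-change counts for the stopping
// rule.
// [[Rcpp::export]]
List chanvese_chunk_cpp(NumericMatrix phi0_, NumericMatrix I_, double mu,
                        double l1, double l2, double eps, double dt,
                        int n_iter) {
  int H = I_.nrow(), W = I_.ncol();
  size_t N = (size_t)H * W;
  NumericMatrix phi_(clone(phi0_)), phin_(H, W);
  double *phi = REAL(phi_), *phin = REAL(phin_);
  const double *I = REAL(I_);
  std::vector<double> Hbuf(N);
  NumericVector energy(n_iter);
  IntegerVector changes(n_iter);
  double a1 = 0.0, a2 = 0.0;
  const double stab = 1e-8;
  const double inv_pi = 1.0 / M_PI;
  for (int it = 0; it < n_iter; ++it) {
    // region means weighted by the regularized Heaviside
    double s1 = 0.0, s2 = 0.0, n1 = 0.0, n2 = 0.0;
    for (size_t i = 0; i < N; ++i) {
      double h = 0.5 * (1.0 + 2.0 * inv_pi * std::atan(phi[i] / eps));
      Hbuf[i] = h;
      s1 += I[i] * h;       n1 += h;
      s2 += I[i] * (1 - h); n2 += 1 - h;
    }
    a1 = (n1 > 0) ? s1 / n1 : 0.0;
    a2 = (n2 > 0) ? s2 / n2 : 0.0;

    double en = 0.0;
    int nchange = 0;
    for (int x = 0; x < W; ++x) {
      size_t col = (size_t)H * x;
      const double *cm = phi + (size_t)H * clampi(x - 1, W);
      const double *cc = phi + col;
      const double *cp = phi + (size_t)H * clampi(x + 1, W);
      for (int y = 0; y < H; ++y) {
        int ym = (y == 0) ? 0 : y - 1;
        int yp = (y == H - 1) ? H - 1 : y + 1;
        double px = 0.5 * (cp[y] - cm[y]);
        double py = 0.5 * (cc[yp] - cc[ym]);
        double pxx = cp[y] - 2.0 * cc[y] + cm[y];
        double pyy = cc[yp] - 2.0 * cc[y] + cc[ym];
        double pxy = 0.25 * (cp[yp] - cm[yp] - cp[ym] + cm[ym]);
        double g2 = px * px + py * py + stab;
        double sg = std::sqrt(g2);
        double kappa = (pxx * py * py - 2.0 * px * py * pxy + pyy * px * px) /
                       (g2 * sg);
        size_t i = col + y;
        double r = cc[y] / eps;
        double delta = inv_pi / (eps * (1.0 + r * r));
        double d1 = I[i] - a1, d2 = I[i] - a2;
        double v = cc[y] + dt * delta *
                   (mu * kappa - l1 * d1 * d1 + l2 * d2 * d2);
        phin[i] = v;
        if ((v > 0) != (cc[y] > 0)) ++nchange;
        en += mu * delta * sg + l1 * d1 * d1 * Hbuf[i] +
              l2 * d2 * d2 * (1 - Hbuf[i]);
      }
    }
    energy[it] = en;
    changes[it] = nchange;
    std::swap(phi, phin);
  }
  NumericMatrix out_ = (phi == REAL(phi_)) ? phi_ : phin_;
  return List::create(_["phi"] = out_, _["alpha1"] = a1, _["alpha2"] = a2,
                      _["energy"] = energy, _["changes"] = changes);
}
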