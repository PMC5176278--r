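#include "kinetics.h"
#include "tridiag.h"
using namespace Rcpp;

// Radially symmetric free-boundary proliferation model on a moving mesh.
//
// Field columns: E M A T P Ap Ec m1 m2 m1i m2i C N (13).
// The total cell density C + N is (approximately) the constant theta; the
// radial cell velocity u follows from adding the C and N equations, the
// tumor radius R(t) = last mesh node moves with u(R). Mesh nodes are
// advected by u, which removes the u * dX/dr advection term from the
// per-node equations; the remaining divergence term X * (u_r + 2u/r) and
// the diffusion operator are treated implicitly, nonlinear sources by
// damped Picard iteration until the per-step update is below tolerance.

enum { iE, iM, iA, iT, iP, iAp, iEc, im1, im2, im1i, im2i, iC, iN };

// net volumetric source of cells: growth minus death of both populations
static void net_cell_source(const std::vector<std::vector<double> >& X,
                            const ModelParams& p, std::vector<double>& G) {
  int n = (int)G.size();
  for (int i = 0; i < n; ++i) {
    G[i] = growth(X[iM][i], X[iA][i], X[iC][i], X[iN][i], p)
         + growth_normal(X[iN][i], X[iC][i], p)
         - death_cancer(X[iC][i], X[iAp][i], p)
         - death_normal(X[iN][i], X[iAp][i], p);
  }
}

// u(r) = 1/(theta r^2) * int_0^r xi^2 G(xi) dxi with G piecewise linear;
// the xi^2 moments are integrated exactly so that a spatially constant
// source yields u = G r / (3 theta) to machine precision (a plain
// trapezoid is badly biased at the first nodes near r = 0). u(0) = 0.
static void velocity(const std::vector<double>& r,
                     const std::vector<double>& G,
                     double theta, std::vector<double>& u) {
  int n = (int)r.size();
  double acc = 0.0;
  u[0] = 0.0;
  for (int i = 1; i < n; ++i) {
    double r0 = r[i - 1], r1 = r[i], h = r1 - r0;
    double m3 = (r1 * r1 * r1 - r0 * r0 * r0) / 3.0;
    double m4 = (r1 * r1 * r1 * r1 - r0 * r0 * r0 * r0) / 4.0;
    // int_{r0}^{r1} xi^2 [G0 + (G1-G0)(xi-r0)/h] dxi
    acc += G[i - 1] * m3 + (G[i] - G[i - 1]) / h * (m4 - r0 * m3);
    u[i] = acc / (theta * r[i] * r[i]);
  }
}

// div(u e_r) = u_r + 2u/r on a nonuniform mesh; series limit 3*u'(0) at 0
static void divergence(const std::vector<double>& r,
                       const std::vector<double>& u,
                       std::vector<double>& divu) {
  int n = (int)r.size();
  divu[0] = 3.0 * u[1] / r[1];
  for (int i = 1; i < n - 1; ++i) {
    double hp = r[i + 1] - r[i], hm = r[i] - r[i - 1];
    double ur = (hm * hm * u[i + 1] - hp * hp * u[i - 1]
                 + (hp * hp - hm * hm) * u[i]) / (hp * hm * (hp + hm));
    divu[i] = ur + 2.0 * u[i] / r[i];
  }
  double hm = r[n - 1] - r[n - 2];
  divu[n - 1] = (u[n - 1] - u[n - 2]) / hm + 2.0 * u[n - 1] / r[n - 1];
}

// monotone cubic (Fritsch-Carlson) interpolation used when remeshing
static void pchip(const std::vector<double>& x, const std::vector<double>& y,
                  const std::vector<double>& xo, std::vector<double>& yo) {
  int n = (int)x.size();
  std::vector<double> h(n - 1), del(n - 1), m(n);
  for (int i = 0; i < n - 1; ++i) {
    h[i] = x[i + 1] - x[i];
    del[i] = (y[i + 1] - y[i]) / h[i];
  }
  m[0] = del[0]; m[n - 1] = del[n - 2];
  for (int i = 1; i < n - 1; ++i) {
    if (del[i - 1] * del[i] <= 0.0) m[i] = 0.0;
    else {
      double w1 = 2.0 * h[i] + h[i - 1], w2 = h[i] + 2.0 * h[i - 1];
      m[i] = (w1 + w2) / (w1 / del[i - 1] + w2 / del[i]);
    }
  }
  int k = 0;
  for (size_t j = 0; j < xo.size(); ++j) {
    double xx = xo[j];
    while (k < n - 2 && x[k + 1] < xx) ++k;
    double t = (xx - x[k]) / h[k];
    double t2 = t * t, t3 = t2 * t;
    yo[j] = y[k] * (2 * t3 - 3 * t2 + 1) + h[k] * m[k] * (t3 - 2 * t2 + t)
          + y[k + 1] * (-2 * t3 + 3 * t2) + h[k] * m[k + 1] * (t3 - t2);
  }
}

// [[Rcpp::export(name = ".prolif_velocity")]]
NumericVector prolif_velocity(NumericVector r, NumericMatrix fields,
                              List params) {
  ModelParams p(params);
  int n = r.size();
  std::vector<std::vector<double> > X(13, std::vector<double>(n));
  for (int j = 0; j < 13; ++j)
    for (int i = 0; i < n; ++i) X[j][i] = fields(i, j);
  std::vector<double> G(n), u(n);
  net_cell_source(X, p, G);
  velocity(std::vector<double>(r.begin(), r.end()), G, p.theta, u);
  return NumericVector(u.begin(), u.end());
}

// [[Rcpp::export(name = ".prolif_advance")]]
List prolif_advance(NumericVector r_in, NumericMatrix fields, List params,
                    double tau, int nsteps, bool freeze_mesh,
                    double picard_tol, int picard_cap, double remesh_frac) {
  ModelParams p(params);
  const int n = r_in.size();
  if (fields.ncol() != 13) stop("expected 13 field columns");

  std::vector<double> r(r_in.begin(), r_in.end());
  std::vector<std::vector<double> > Xold(13, std::vector<double>(n)),
      X(13, std::vector<double>(n)), Xnew(13, std::vector<double>(n));
  for (int j = 0; j < 13; ++j)
    for (int i = 0; i < n; ++i) Xold[j][i] = fields(i, j);

  const int diff_idx[7] = { iEc, im1, im2, im1i, im2i, iC, iN };
  const double diff_D[7] = { p.D_Ec, p.D_m1, p.D_m2, p.D_C, p.D_C,
                             p.D_C, p.D_N };

  std::vector<double> G(n), u(n), divu(n), rold(n), rnew(n),
      sub(n - 1), diag(n), sup(n - 1), rhs(n), src(n), sink(n);
  int max_iters = 0, n_remesh = 0;

  for (int step = 0; step < nsteps; ++step) {
    rold = r;
    for (int j = 0; j < 13; ++j) X[j] = Xold[j];
    rnew = r;

    int it;
    for (it = 1; it <= picard_cap; ++it) {
      // velocity and mesh update from the current iterate
      net_cell_source(X, p, G);
      velocity(rnew, G, p.theta, u);
      if (freeze_mesh) std::fill(u.begin(), u.end(), 0.0);
      for (int i = 0; i < n; ++i) rnew[i] = rold[i] + u[i] * tau;
      for (int i = 1; i < n; ++i)
        if (rnew[i] <= rnew[i - 1])
          stop("mesh nodes crossed during implicit solve; reduce tau");
      divergence(rnew, u, divu);
      if (freeze_mesh) std::fill(divu.begin(), divu.end(), 0.0);

      // proteins: pointwise semi-implicit with lagged regulators
      for (int i = 0; i < n; ++i) {
        double cfac = X[iC][i] / p.C_0;
        double M = X[iM][i], T = X[iT][i], Pp = X[iP][i];
        double m1t = X[im1][i] + X[im1i][i];
        double m2t = X[im2][i] + X[im2i][i];
        Xnew[iE][i] = (Xold[iE][i]
                       + tau * cfac * p.lam_E / (1.0 + M / p.K_ME))
                      / (1.0 + tau * cfac * p.d_E);
        Xnew[iM][i] = (Xold[iM][i]
                       + tau * cfac * p.lam_M * X[iE][i] / (1.0 + T / p.K_TM))
                      / (1.0 + tau * cfac * p.d_M);
        Xnew[iA][i] = (Xold[iA][i]
                       + tau * cfac * p.lam_A * X[iE][i]
                         / (1.0 + Pp / p.K_PA) / (1.0 + T / p.K_TA)
                         * (1.0 + p.lam_MA * M / (p.K_MA + M)))
                      / (1.0 + tau * cfac * p.d_A);
        Xnew[iT][i] = (Xold[iT][i]
                       + tau * cfac * p.lam_T / (1.0 + 0.5 * m1t / p.K_mT))
                      / (1.0 + tau * cfac * p.d_T);
        Xnew[iP][i] = (Xold[iP][i]
                       + tau * cfac * p.lam_P / (1.0 + m1t / p.K_mP))
                      / (1.0 + tau * cfac * p.d_P);
        Xnew[iAp][i] = (Xold[iAp][i]
                        + tau * cfac * p.lam_Ap / (1.0 + m2t / p.K_m2))
                       / (1.0 + tau * cfac * p.d_Ap);
      }

      // diffusing fields: implicit diffusion, divergence and linear sinks;
      // nonlinear sources lagged (converged by the Picard loop)
      for (int f = 0; f < 7; ++f) {
        const int j = diff_idx[f];
        const double D = diff_D[f];
        for (int i = 0; i < n; ++i) {
          double C = X[iC][i], Ec = X[iEc][i], Ap = X[iAp][i];
          switch (j) {
          case iEc:
            sink[i] = p.d_Ec * C / (p.K_C + C);
            src[i] = p.lam_Ec * C; break;
          case im1:
            sink[i] = p.d_m1;
            src[i] = p.lam_m1 * Ec * C / (p.K_C + C); break;
          case im2:
            sink[i] = p.d_m2;
            src[i] = p.lam_m2 * Ec * C / (p.K_C + C); break;
          case im1i:
            sink[i] = p.d_m1; src[i] = p.lam_m1i * C; break;
          case im2i:
            sink[i] = p.d_m2; src[i] = p.lam_m2i * C; break;
          case iC:
            sink[i] = p.d_D * Ap / (p.K_Ap + Ap) + p.d_C;
            src[i] = growth(X[iM][i], X[iA][i], C, X[iN][i], p); break;
          default:
            sink[i] = p.d_DN * Ap / (p.K_Ap + Ap) + p.d_N;
            src[i] = growth_normal(X[iN][i], C, p);
          }
        }
        // symmetry at r = 0: Laplacian ~ 6 (f1 - f0) / h^2
        {
          double hp = rnew[1] - rnew[0];
          diag[0] = 1.0 / tau + divu[0] + sink[0] + 6.0 * D / (hp * hp);
          sup[0] = -6.0 * D / (hp * hp);
          rhs[0] = Xold[j][0] / tau + src[0];
        }
        for (int i = 1; i < n - 1; ++i) {
          double hp = rnew[i + 1] - rnew[i], hm = rnew[i] - rnew[i - 1];
          double den = hp * hm * (hp + hm), ri = rnew[i];
          double cp = (2.0 * hm + (2.0 / ri) * hm * hm) / den;
          double cm = (2.0 * hp - (2.0 / ri) * hp * hp) / den;
          double c0 = (-2.0 * (hp + hm) + (2.0 / ri) * (hp * hp - hm * hm))
                      / den;
          sub[i - 1] = -D * cm;
          diag[i] = 1.0 / tau + divu[i] + sink[i] - D * c0;
          sup[i] = -D * cp;
          rhs[i] = Xold[j][i] / tau + src[i];
        }
        // no-flux at the free boundary r = R
        {
          double hm = rnew[n - 1] - rnew[n - 2];
          sub[n - 2] = -2.0 * D / (hm * hm);
          diag[n - 1] = 1.0 / tau + divu[n - 1] + sink[n - 1]
                        + 2.0 * D / (hm * hm);
          rhs[n - 1] = Xold[j][n - 1] / tau + src[n - 1];
        }
        thomas(sub, diag, sup, rhs);
        for (int i = 0; i < n; ++i) Xnew[j][i] = rhs[i];
      }

      // scaled sup-norm of the Picard update
      double maxrel = 0.0;
      for (int j = 0; j < 13; ++j) {
        double scale = 0.0, dmax = 0.0;
        for (int i = 0; i < n; ++i) {
          double v = Xnew[j][i];
          if (!std::isfinite(v))
            stop("proliferation step produced a non-finite value; "
                 "reduce tau");
          if (std::fabs(v) > scale) scale = std::fabs(v);
          double dd = std::fabs(v - X[j][i]);
          if (dd > dmax) dmax = dd;
        }
        if (scale > 0.0 && dmax / scale > maxrel) maxrel = dmax / scale;
        X[j] = Xnew[j];
      }
      if (maxrel < picard_tol) break;
    }
    if (it > picard_cap)
      stop("implicit solve did not converge within %d Picard iterations; "
           "reduce tau", picard_cap);
    if (it > max_iters) max_iters = it;

    // accept the step
    r = rnew;
    for (int j = 0; j < 13; ++j) {
      double scale = 0.0;
      for (int i = 0; i < n; ++i)
        if (std::fabs(X[j][i]) > scale) scale = std::fabs(X[j][i]);
      for (int i = 0; i < n; ++i) {
        if (X[j][i] < 0.0) {
          if (X[j][i] < -1e-6 * scale)
            stop("proliferation step produced negative concentrations "
                 "beyond tolerance; reduce tau");
          X[j][i] = 0.0;
        }
        Xold[j][i] = X[j][i];
      }
    }

    // remesh onto a uniform grid if cells collapsed
    double R = r[n - 1], hmin = R;
    for (int i = 1; i < n; ++i)
      if (r[i] - r[i - 1] < hmin) hmin = r[i] - r[i - 1];
    if (hmin < remesh_frac * R) {
      std::vector<double> runi(n), yo(n);
      for (int i = 0; i < n; ++i) runi[i] = R * (double)i / (double)(n - 1);
      for (int j = 0; j < 13; ++j) {
        pchip(r, Xold[j], runi, yo);
        Xold[j] = yo;
      }
      r = runi;
      ++n_remesh;
    }
  }

  NumericMatrix out(n, 13);
  for (int j = 0; j < 13; ++j)
    for (int i = 0; i < n; ++i) out(i, j) = Xold[j][i];
  out.attr("dimnames") = fields.attr("dimnames");
  return List::create(_["r"] = NumericVector(r.begin(), r.end()),
                      _["fields"] = out,
                      _["max_picard_iters"] = max_iters,
                      _["n_remesh"] = n_remesh);
}
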