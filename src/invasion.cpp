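#include "kinetics.h"
#include "tridiag.h"
using namespace Rcpp;

// 1-D tumor-front invasion on a uniform grid over [0, 2] cm.
//
// Field columns: E M A T P Ap Ec m1 m2 m1i m2i C (12).
// Proteins (cols 0-5) evolve pointwise; Ec/m1/m2/m1i/m2i/C diffuse.
// Dirichlet values are held at x = 0 for the diffusing fields (the bulk
// tumor occupying x < 0), no-flux at x = 2. Time stepping is semi-implicit:
// linear diffusion implicit (Thomas solve), reactions and the nonlinear
// directed-migration flux chi * d/dx (C dC/dx) explicit.

// [[Rcpp::export(name = ".invasion_advance")]]
List invasion_advance(NumericMatrix fields, List params,
                      double dx, double dt, int nsteps,
                      NumericVector bc_in) {
  ModelParams p(params);
  const int n = fields.nrow();          // grid nodes
  if (fields.ncol() != 12) stop("expected 12 field columns");
  if (bc_in.size() != 6) stop("expected 6 Dirichlet values");

  // working copies
  std::vector<std::vector<double> > X(12, std::vector<double>(n));
  for (int j = 0; j < 12; ++j)
    for (int i = 0; i < n; ++i) X[j][i] = fields(i, j);

  enum { iE, iM, iA, iT, iP, iAp, iEc, im1, im2, im1i, im2i, iC };
  const int diff_idx[6] = { iEc, im1, im2, im1i, im2i, iC };
  const double diff_D[6] = { p.D_Ec, p.D_m1, p.D_m2, p.D_C, p.D_C, p.D_C };
  const double bc[6] = { bc_in[0], bc_in[1], bc_in[2], bc_in[3], bc_in[4],
                         bc_in[5] };

  std::vector<double> react(n), flux(n), sub(n - 1), diag(n), sup(n - 1),
      rhs(n);
  long n_clipped = 0;

  for (int step = 0; step < nsteps; ++step) {
    // pointwise protein kinetics, explicit Euler
    for (int i = 0; i < n; ++i) {
      ProteinRates r = protein_rates(X[iE][i], X[iM][i], X[iA][i], X[iT][i],
                                     X[iP][i], X[iAp][i], X[im1][i],
                                     X[im2][i], X[im1i][i], X[im2i][i],
                                     X[iC][i], p);
      X[iE][i] += dt * r.E;  X[iM][i] += dt * r.M;  X[iA][i] += dt * r.A;
      X[iT][i] += dt * r.T;  X[iP][i] += dt * r.P;  X[iAp][i] += dt * r.Ap;
    }

    // conservative directed-migration flux for C at half-nodes
    // F_{i+1/2} = chi * C_{i+1/2} * (C_{i+1}-C_i)/dx; no-flux at x = 2
    for (int i = 0; i < n - 1; ++i)
      flux[i] = p.chi * 0.5 * (X[iC][i] + X[iC][i + 1])
                * (X[iC][i + 1] - X[iC][i]) / dx;

    for (int f = 0; f < 6; ++f) {
      const int j = diff_idx[f];
      const double D = diff_D[f];
      const double a = dt * D / (dx * dx);

      for (int i = 0; i < n; ++i) {
        double rj;
        switch (j) {
        case iEc:  rj = exosome_rate(X[iEc][i], X[iC][i], p); break;
        case im1:  rj = mir_exo_rate(X[im1][i], X[iEc][i], X[iC][i],
                                     p.lam_m1, p.d_m1, p); break;
        case im2:  rj = mir_exo_rate(X[im2][i], X[iEc][i], X[iC][i],
                                     p.lam_m2, p.d_m2, p); break;
        case im1i: rj = mir_cell_rate(X[im1i][i], X[iC][i], p.lam_m1i,
                                      p.d_m1); break;
        case im2i: rj = mir_cell_rate(X[im2i][i], X[iC][i], p.lam_m2i,
                                      p.d_m2); break;
        default:   rj = growth(X[iM][i], X[iA][i], X[iC][i], 0.0, p)
                        - death_cancer(X[iC][i], X[iAp][i], p);
        }
        react[i] = rj;
      }
      if (j == iC) {
        for (int i = 1; i < n - 1; ++i)
          react[i] += (flux[i] - flux[i - 1]) / dx;
        react[n - 1] += (0.0 - flux[n - 2]) / dx;
      }

      // (I - dt D L) x = x_old + dt * react; Dirichlet row at node 0
      diag[0] = 1.0; sup[0] = 0.0; rhs[0] = bc[f];
      for (int i = 1; i < n - 1; ++i) {
        sub[i - 1] = -a;
        diag[i] = 1.0 + 2.0 * a;
        sup[i] = -a;
        rhs[i] = X[j][i] + dt * react[i];
      }
      sub[n - 2] = -2.0 * a;
      diag[n - 1] = 1.0 + 2.0 * a;
      rhs[n - 1] = X[j][n - 1] + dt * react[n - 1];
      thomas(sub, diag, sup, rhs);
      for (int i = 0; i < n; ++i) X[j][i] = rhs[i];
    }

    // round-off guard: clip tiny negatives, fail on real ones
    for (int j = 0; j < 12; ++j)
      for (int i = 0; i < n; ++i) {
        double v = X[j][i];
        if (!std::isfinite(v))
          stop("invasion step produced a non-finite value; reduce dt");
        if (v < 0.0) {
          if (v < -1e-8)
            stop("invasion step produced negative concentrations beyond "
                 "tolerance; reduce dt");
          X[j][i] = 0.0;
          ++n_clipped;
        }
      }
  }

  NumericMatrix out(n, 12);
  for (int j = 0; j < 12; ++j)
    for (int i = 0; i < n; ++i) out(i, j) = X[j][i];
  out.attr("dimnames") = fields.attr("dimnames");
  return List::create(_["fields"] = out, _["n_clipped"] = (double)n_clipped);
}
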