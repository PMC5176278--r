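#include "kinetics.h"
using namespace Rcpp;

// Vectorised R entry points to the shared reaction evaluators. Input
// validation (non-negativity, label checks) lives in the R wrappers.

// [[Rcpp::export(name = ".kin_protein_rhs")]]
List kin_protein_rhs(NumericVector E, NumericVector M, NumericVector A,
                     NumericVector T, NumericVector P, NumericVector Ap,
                     NumericVector m1, NumericVector m2,
                     NumericVector m1i, NumericVector m2i,
                     NumericVector C, List params) {
  ModelParams p(params);
  int n = E.size();
  NumericVector rE(n), rM(n), rA(n), rT(n), rP(n), rAp(n);
  for (int i = 0; i < n; ++i) {
    ProteinRates r = protein_rates(E[i], M[i], A[i], T[i], P[i], Ap[i],
                                   m1[i], m2[i], m1i[i], m2i[i], C[i], p);
    rE[i] = r.E; rM[i] = r.M; rA[i] = r.A;
    rT[i] = r.T; rP[i] = r.P; rAp[i] = r.Ap;
  }
  return List::create(_["E"] = rE, _["M"] = rM, _["A"] = rA,
                      _["T"] = rT, _["P"] = rP, _["Ap"] = rAp);
}

// [[Rcpp::export(name = ".kin_exosome")]]
NumericVector kin_exosome(NumericVector Ec, NumericVector C, List params) {
  ModelParams p(params);
  int n = Ec.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = exosome_rate(Ec[i], C[i], p);
  return out;
}

// [[Rcpp::export(name = ".kin_mir")]]
NumericVector kin_mir(NumericVector m, NumericVector driver, NumericVector C,
                      List params, std::string species) {
  ModelParams p(params);
  int n = m.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    if (species == "m1")
      out[i] = mir_exo_rate(m[i], driver[i], C[i], p.lam_m1, p.d_m1, p);
    else if (species == "m2")
      out[i] = mir_exo_rate(m[i], driver[i], C[i], p.lam_m2, p.d_m2, p);
    else if (species == "m1i")
      out[i] = mir_cell_rate(m[i], C[i], p.lam_m1i, p.d_m1);
    else if (species == "m2i")
      out[i] = mir_cell_rate(m[i], C[i], p.lam_m2i, p.d_m2);
    else
      stop("unknown miR species '%s'", species.c_str());
  }
  return out;
}

// [[Rcpp::export(name = ".kin_growth")]]
NumericVector kin_growth(NumericVector M, NumericVector A, NumericVector C,
                         NumericVector N, List params, std::string cell) {
  ModelParams p(params);
  int n = C.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    if (cell == "cancer") out[i] = growth(M[i], A[i], C[i], N[i], p);
    else if (cell == "normal") out[i] = growth_normal(N[i], C[i], p);
    else stop("unknown cell type '%s'", cell.c_str());
  }
  return out;
}

// [[Rcpp::export(name = ".kin_death")]]
NumericVector kin_death(NumericVector X, NumericVector Ap, List params,
                        std::string cell) {
  ModelParams p(params);
  int n = X.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    if (cell == "cancer") out[i] = death_cancer(X[i], Ap[i], p);
    else if (cell == "normal") out[i] = death_normal(X[i], Ap[i], p);
    else stop("unknown cell type '%s'", cell.c_str());
  }
  return out;
}
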