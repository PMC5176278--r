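#ifndef MIRTUMOR_KINETICS_H
#define MIRTUMOR_KINETICS_H

#include "model_params.h"

// Local (non-spatial) reaction terms shared by the invasion and
// proliferation solvers and by the exported R-level evaluators.
// All concentrations in g/cm^3, rates in g cm^-3 day^-1.

struct ProteinRates { double E, M, A, T, P, Ap; };

// Intracellular signalling kinetics. Every bracket is scaled by C/C_0:
// protein turnover only happens inside cancer cells.
inline ProteinRates protein_rates(double E, double M, double A, double T,
                                  double P, double Ap,
                                  double m1, double m2,
                                  double m1i, double m2i,
                                  double C, const ModelParams& p) {
  const double cfac = C / p.C_0;
  ProteinRates r;
  // EGF-EGFR: production inhibited by ERK (represented by MAPK)
  r.E = (p.lam_E / (1.0 + M / p.K_ME) - p.d_E * E) * cfac;
  // MAPK: activated by EGF-EGFR, resisted by TKI
  r.M = (p.lam_M * E / (1.0 + T / p.K_TM) - p.d_M * M) * cfac;
  // AKT: activated by EGF-EGFR directly and through Ras (proportional to
  // MAPK), inhibited by PTEN and TKI; PI3K folded in at quasi-steady state
  r.A = (p.lam_A * E / (1.0 + P / p.K_PA) / (1.0 + T / p.K_TA)
             * (1.0 + p.lam_MA * M / (p.K_MA + M))
         - p.d_A * A) * cfac;
  // TKI: blocked by miR-21, which is only half of the pooled m1 species
  r.T = (p.lam_T / (1.0 + 0.5 * (m1 + m1i) / p.K_mT) - p.d_T * T) * cfac;
  // PTEN: blocked by both miR-21 and miR-205 (the full m1 pool)
  r.P = (p.lam_P / (1.0 + (m1 + m1i) / p.K_mP) - p.d_P * P) * cfac;
  // apoptosome: Apaf-1 expression down-regulated by miR-155
  r.Ap = (p.lam_Ap / (1.0 + (m2 + m2i) / p.K_m2) - p.d_Ap * Ap) * cfac;
  return r;
}

// Exosome shedding by cancer cells minus degradation on merging with them.
inline double exosome_rate(double Ec, double C, const ModelParams& p) {
  return p.lam_Ec * C - p.d_Ec * Ec * C / (p.K_C + C);
}

// Exosomal miR: released when exosomes merge with cancer cells.
inline double mir_exo_rate(double m, double Ec, double C, double lam_m,
                           double d_m, const ModelParams& p) {
  return lam_m * Ec * C / (p.K_C + C) - d_m * m;
}

// Cellular miR: produced by cancer cells directly.
inline double mir_cell_rate(double m, double C, double lam_mi, double d_m) {
  return lam_mi * C - d_m * m;
}

// Logistic growth with MAPK- and AKT-dependent rate; N = 0 in invasion.
inline double growth(double M, double A, double C, double N,
                     const ModelParams& p) {
  return (p.lam_C1 * M / (p.K_M + M) + p.lam_C2 * A / (p.K_A + A))
         * C * (1.0 - (C + p.eps * N) / p.C_M);
}

// Apoptosome-mediated (DNA-damage) plus natural death of cancer cells.
inline double death_cancer(double C, double Ap, const ModelParams& p) {
  return p.d_D * C * Ap / (p.K_Ap + Ap) + p.d_C * C;
}

// Normal-cell logistic growth (competition with cancer cells).
inline double growth_normal(double N, double C, const ModelParams& p) {
  return p.lam_N * N * (1.0 - (N + p.eps * C) / p.C_M);
}

inline double death_normal(double N, double Ap, const ModelParams& p) {
  return p.d_DN * N * Ap / (p.K_Ap + Ap) + p.d_N * N;
}

#endif
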