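#ifndef MIRTUMOR_MODEL_PARAMS_H
#define MIRTUMOR_MODEL_PARAMS_H

#include <Rcpp.h>

// Flat view of a parameter_set list (see R/params.R for units).
// Concentrations are g/cm^3, rates day^-1 (production rates of proteins
// carry an extra g/cm^3), diffusivities cm^2/day, chi cm^5 g^-1 day^-1.
struct ModelParams {
  // diffusivities and directed migration
  double D_Ec, D_m1, D_m2, D_C, D_N, chi;
  // production / activation rates
  double lam_E, lam_M, lam_A, lam_MA, lam_T, lam_P, lam_Ap;
  double lam_Ec, lam_m1, lam_m2, lam_m1i, lam_m2i;
  double lam_C1, lam_C2, lam_N, eps;
  // degradation / death rates
  double d_E, d_M, d_A, d_T, d_P, d_Ap, d_Ec, d_m1, d_m2;
  double d_C, d_D, d_N, d_DN;
  // half-saturations
  double K_ME, K_TM, K_TA, K_PA, K_mT, K_mP, K_m2, K_MA;
  double K_C, K_M, K_A, K_Ap;
  // steady-state / structural constants
  double E_0, M_0, P_30, A_0, T_0, P_0, Ap_0, E_C0, m_10, m_20;
  double C_0, N_0, C_M, gamma, theta;

  static double get(const Rcpp::List& l, const char* nm) {
    if (!l.containsElementNamed(nm))
      Rcpp::stop("parameter set is missing entry '%s'", nm);
    return Rcpp::as<double>(l[nm]);
  }

  explicit ModelParams(const Rcpp::List& p) {
    D_Ec = get(p, "D_Ec"); D_m1 = get(p, "D_m1"); D_m2 = get(p, "D_m2");
    D_C = get(p, "D_C"); D_N = get(p, "D_N"); chi = get(p, "chi");
    lam_E = get(p, "lam_E"); lam_M = get(p, "lam_M"); lam_A = get(p, "lam_A");
    lam_MA = get(p, "lam_MA"); lam_T = get(p, "lam_T"); lam_P = get(p, "lam_P");
    lam_Ap = get(p, "lam_Ap"); lam_Ec = get(p, "lam_Ec");
    lam_m1 = get(p, "lam_m1"); lam_m2 = get(p, "lam_m2");
    lam_m1i = get(p, "lam_m1i"); lam_m2i = get(p, "lam_m2i");
    lam_C1 = get(p, "lam_C1"); lam_C2 = get(p, "lam_C2");
    lam_N = get(p, "lam_N"); eps = get(p, "eps");
    d_E = get(p, "d_E"); d_M = get(p, "d_M"); d_A = get(p, "d_A");
    d_T = get(p, "d_T"); d_P = get(p, "d_P"); d_Ap = get(p, "d_Ap");
    d_Ec = get(p, "d_Ec"); d_m1 = get(p, "d_m1"); d_m2 = get(p, "d_m2");
    d_C = get(p, "d_C"); d_D = get(p, "d_D"); d_N = get(p, "d_N");
    d_DN = get(p, "d_DN");
    K_ME = get(p, "K_ME"); K_TM = get(p, "K_TM"); K_TA = get(p, "K_TA");
    K_PA = get(p, "K_PA"); K_mT = get(p, "K_mT"); K_mP = get(p, "K_mP");
    K_m2 = get(p, "K_m2"); K_MA = get(p, "K_MA"); K_C = get(p, "K_C");
    K_M = get(p, "K_M"); K_A = get(p, "K_A"); K_Ap = get(p, "K_Ap");
    Rcpp::List ss = p["steady"];
    E_0 = get(ss, "E_0"); M_0 = get(ss, "M_0"); P_30 = get(ss, "P_30");
    A_0 = get(ss, "A_0"); T_0 = get(ss, "T_0"); P_0 = get(ss, "P_0");
    Ap_0 = get(ss, "Ap_0"); E_C0 = get(ss, "E_C0");
    m_10 = get(ss, "m_10"); m_20 = get(ss, "m_20");
    C_0 = get(ss, "C_0"); N_0 = get(ss, "N_0"); C_M = get(ss, "C_M");
    gamma = get(ss, "gamma"); theta = get(ss, "theta");
  }
};

#endif
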