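# shared fixtures: default parameter sets are deterministic, build once
p_inv <- default_parameter_set("invasion")
p_pro <- default_parameter_set("proliferation")

# plain-R re-statement of the protein kinetics, used as an independent
# oracle for the compiled evaluators
protein_rhs_oracle <- function(s, p) {
  cf <- s$C / p$steady$C_0
  list(
    E = (p$lam_E / (1 + s$M / p$K_ME) - p$d_E * s$E) * cf,
    M = (p$lam_M * s$E / (1 + s$T / p$K_TM) - p$d_M * s$M) * cf,
    A = (p$lam_A * s$E / (1 + s$P / p$K_PA) / (1 + s$T / p$K_TA) *
           (1 + p$lam_MA * s$M / (p$K_MA + s$M)) - p$d_A * s$A) * cf,
    T = (p$lam_T / (1 + 0.5 * (s$m1 + s$m1i) / p$K_mT) -
           p$d_T * s$T) * cf,
    P = (p$lam_P / (1 + (s$m1 + s$m1i) / p$K_mP) - p$d_P * s$P) * cf,
    Ap = (p$lam_Ap / (1 + (s$m2 + s$m2i) / p$K_m2) -
            p$d_Ap * s$Ap) * cf
  )
}

# random nonnegative point state near the steady state, for property loops
random_state <- function(p, scale = 1) {
  ss <- p$steady
  jit <- function(v) v * stats::runif(1, 0, 2) * scale
  point_state(E = jit(ss$E_0), M = jit(ss$M_0), A = jit(ss$A_0),
              T = jit(ss$T_0), P = jit(ss$P_0), Ap = jit(ss$Ap_0),
              Ec = jit(ss$E_C0), m1 = jit(ss$m_10), m2 = jit(ss$m_20),
              m1i = jit(ss$gamma * ss$m_10),
              m2i = jit(ss$gamma * ss$m_20),
              C = jit(ss$C_0), N = jit(ss$N_0))
}
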