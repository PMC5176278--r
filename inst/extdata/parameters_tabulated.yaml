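# Canonical printed parameter record (invasion phase).
# Units: diffusivities cm^2/day; chi cm^5 g^-1 day^-1; production rates of
# E, T, P, Ap day^-1 g/cm^3, all other rates day^-1; half-saturations and
# steady-state concentrations g/cm^3. chi is the upper end of the modelled
# range [3e-4, 3e-2].
D_Ec: 1.23e-4
D_m1: 0.13028
D_m2: 0.13028
D_C: 8.64e-7
D_N: 8.64e-7
chi: 3.0e-2
lam_E: 1.1741e-3
lam_M: 1.6499e-2
lam_A: 2.9422e-3
lam_MA: 0.5
lam_T: 8.4013e-4
lam_P: 2.3352e-4
lam_Ap: 4.4095e-3
lam_Ec: 9.81e-9
lam_m1: 8.626e-4
lam_m2: 4.313e-4
lam_C1: 0.6133
lam_C2: 0.3067
lam_N: 0.092
eps: 0.1
d_E: 0.8318
d_M: 0.6931
d_A: 0.6931
d_T: 0.3466
d_P: 22.1807
d_Ap: 2.7726
d_Ec: 21.8
d_m1: 0.5545
d_m2: 0.5545
d_C: 0.023
d_D: 0.414
d_N: 0.023
# from the estimation text, absent from the printed table
d_DN: 0.4554
steady:
  E_0: 7.0573e-4
  M_0: 8.4e-6
  P_30: 1.56e-6
  A_0: 9.362e-7
  T_0: 8.5050e-5
  P_0: 1.88e-7
  Ap_0: 2.84e-5
  E_C0: 3.6e-10
  m_10: 2.8e-13
  m_20: 1.4e-13
  C_0: 0.4
  N_0: 0.14
  C_M: 0.8
  gamma: 10
  theta: 0.6
K_ME: 3.936e-5
K_TM: 8.5050e-5
K_TA: 8.5050e-5
K_PA: 1.88e-7
K_mT: 5.6e-14
K_mP: 5.6e-14
K_m2: 2.8e-14
K_MA: 8.4e-6
K_C: 0.4
K_M: 8.4e-6
K_A: 9.362e-7
K_Ap: 2.84e-5
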