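# R-level surface of the shared reaction evaluators. The same compiled
# kernels (src/kinetics.h) are used verbatim by both PDE solvers, so these
# functions are also the solver kinetics.

.field_names <- c("E", "M", "A", "T", "P", "Ap",
                  "Ec", "m1", "m2", "m1i", "m2i", "C")

.check_nonneg <- function(...) {
  vals <- list(...)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (any(!is.finite(v)) || any(v < 0)) {
      stop("negative or non-finite concentration in '", nm, "'")
    }
  }
  invisible(TRUE)
}

#' Point state of the model variables
#'
#' A named list of concentrations (g/cm^3) at one location, or vectors of
#' equal length for many locations. `N` is only used in the proliferation
#' phase.
#'
#' @param E,M,A,T,P,Ap protein concentrations (EGF-EGFR, MAPK, AKT, TKI,
#'   PTEN, apoptosome).
#' @param Ec cancer-shed exosome concentration.
#' @param m1,m2 exosomal miR-21/205 and miR-155.
#' @param m1i,m2i cellular miR-21/205 and miR-155.
#' @param C,N cancer and normal cell densities.
#' @return list of class `point_state`.
#' @export
point_state <- function(E = 0, M = 0, A = 0, T = 0, P = 0, Ap = 0,
                        Ec = 0, m1 = 0, m2 = 0, m1i = 0, m2i = 0,
                        C = 0, N = 0) {
  s <- list(E = E, M = M, A = A, T = T, P = P, Ap = Ap, Ec = Ec,
            m1 = m1, m2 = m2, m1i = m1i, m2i = m2i, C = C, N = N)
  do.call(.check_nonneg, s)
  structure(s, class = "point_state")
}

#' Steady-state point state
#'
#' The point state at which all reaction terms vanish for the default
#' invasion-phase parameter set: every variable at its steady-state value,
#' with the cellular miR pools at gamma times the exosomal ones.
#'
#' @param p a `parameter_set`.
#' @return a [point_state()].
#' @export
steady_point_state <- function(p) {
  ss <- p$steady
  point_state(E = ss$E_0, M = ss$M_0, A = ss$A_0, T = ss$T_0, P = ss$P_0,
              Ap = ss$Ap_0, Ec = ss$E_C0, m1 = ss$m_10, m2 = ss$m_20,
              m1i = ss$gamma * ss$m_10, m2i = ss$gamma * ss$m_20,
              C = ss$C_0, N = ss$N_0)
}

#' Protein reaction rates
#'
#' Right-hand sides of the six intracellular protein equations
#' (EGF-EGFR, MAPK, AKT, TKI, PTEN, apoptosome), each scaled by C/C_0:
#' protein turnover only takes place inside cancer cells. MAPK inhibition
#' of EGF-EGFR and miR inhibition of TKI/PTEN/Apaf-1 enter as
#' `1/(1 + X/K)` factors; miR-21 is half of the pooled m1 species in the
#' TKI equation.
#'
#' @param state a [point_state()] (vector fields allowed).
#' @param p a `parameter_set`.
#' @return named list of rates (g cm^-3 day^-1) for E, M, A, T, P, Ap.
#' @export
protein_rhs <- function(state, p) {
  .check_nonneg(E = state$E, M = state$M, A = state$A, T = state$T,
                P = state$P, Ap = state$Ap, m1 = state$m1, m2 = state$m2,
                m1i = state$m1i, m2i = state$m2i, C = state$C)
  .kin_protein_rhs(state$E, state$M, state$A, state$T, state$P, state$Ap,
                   state$m1, state$m2, state$m1i, state$m2i, state$C,
                   unclass(p))
}

#' Exosome reaction rate
#'
#' Shedding by cancer cells minus degradation on merging with them:
#' `lam_Ec C - d_Ec Ec C / (K_C + C)`.
#'
#' @param Ec exosome concentration (g/cm^3).
#' @param C cancer cell density (g/cm^3).
#' @param p a `parameter_set`.
#' @return reaction rate in g cm^-3 day^-1.
#' @export
exosome_reaction <- function(Ec, C, p) {
  .check_nonneg(Ec = Ec, C = C)
  .kin_exosome(Ec, C, unclass(p))
}

#' miR reaction rate
#'
#' Exosomal species (`"m1"`, `"m2"`): release from exosomes merging with
#' cancer cells minus degradation. Cellular species (`"m1i"`, `"m2i"`):
#' production by cancer cells minus degradation.
#'
#' @param m miR concentration (g/cm^3).
#' @param driver exosome concentration for the exosomal species; ignored
#'   for the cellular species.
#' @param C cancer cell density (g/cm^3).
#' @param p a `parameter_set`.
#' @param species one of `"m1"`, `"m2"`, `"m1i"`, `"m2i"`.
#' @return reaction rate in g cm^-3 day^-1.
#' @export
mir_reaction <- function(m, driver = 0, C, p,
                         species = c("m1", "m2", "m1i", "m2i")) {
  species <- match.arg(species)
  .check_nonneg(m = m, driver = driver, C = C)
  n <- max(length(m), length(driver), length(C))
  .kin_mir(rep_len(m, n), rep_len(driver, n), rep_len(C, n), unclass(p),
           species)
}

#' Cancer or normal cell growth rate
#'
#' Cancer cells grow logistically at a rate set by MAPK and AKT:
#' `(lam_C1 M/(K_M+M) + lam_C2 A/(K_A+A)) C (1 - (C + eps N)/C_M)`.
#' Normal cells (proliferation phase) grow at
#' `lam_N N (1 - (N + eps C)/C_M)`. In the invasion phase N is 0.
#'
#' @param M,A MAPK and AKT concentrations (g/cm^3).
#' @param C,N cancer and normal cell densities (g/cm^3).
#' @param p a `parameter_set`.
#' @param phase `"invasion"` (forces N = 0) or `"proliferation"`.
#' @param cell which population's growth to return.
#' @return growth rate in g cm^-3 day^-1.
#' @export
growth_rate <- function(M, A, C, N = 0, p,
                        phase = c("invasion", "proliferation"),
                        cell = c("cancer", "normal")) {
  phase <- match.arg(phase)
  cell <- match.arg(cell)
  .check_nonneg(M = M, A = A, C = C, N = N)
  if (phase == "invasion") N <- 0
  n <- max(length(M), length(A), length(C), length(N))
  .kin_growth(rep_len(M, n), rep_len(A, n), rep_len(C, n), rep_len(N, n),
              unclass(p), cell)
}

#' Cell death rate
#'
#' Apoptosome-mediated death plus natural apoptosis:
#' `d_D C Ap/(K_Ap+Ap) + d_C C` for cancer cells, and the analogous
#' `d_DN`, `d_N` terms for normal cells.
#'
#' @param X density of the dying population (g/cm^3).
#' @param Ap apoptosome concentration (g/cm^3).
#' @param p a `parameter_set`.
#' @param cell `"cancer"` or `"normal"`.
#' @return death rate in g cm^-3 day^-1.
#' @export
death_rate <- function(X, Ap, p, cell = c("cancer", "normal")) {
  cell <- match.arg(cell)
  .check_nonneg(X = X, Ap = Ap)
  n <- max(length(X), length(Ap))
  .kin_death(rep_len(X, n), rep_len(Ap, n), unclass(p), cell)
}

#' All local reaction rates at a point state
#'
#' Convenience wrapper returning the full right-hand side (reaction part
#' only, no transport) for every model variable.
#'
#' @inheritParams protein_rhs
#' @param phase `"invasion"` (N absent) or `"proliferation"`.
#' @return named list of rates, one per variable.
#' @export
point_rhs <- function(state, p, phase = c("invasion", "proliferation")) {
  phase <- match.arg(phase)
  pr <- protein_rhs(state, p)
  N <- if (phase == "invasion") 0 else state$N
  out <- c(pr, list(
    Ec = exosome_reaction(state$Ec, state$C, p),
    m1 = mir_reaction(state$m1, state$Ec, state$C, p, "m1"),
    m2 = mir_reaction(state$m2, state$Ec, state$C, p, "m2"),
    m1i = mir_reaction(state$m1i, C = state$C, p = p, species = "m1i"),
    m2i = mir_reaction(state$m2i, C = state$C, p = p, species = "m2i"),
    C = growth_rate(state$M, state$A, state$C, N, p, phase, "cancer") -
      death_rate(state$C, state$Ap, p, "cancer")
  ))
  if (phase == "proliferation") {
    out$N <- growth_rate(state$M, state$A, state$C, N, p, phase,
                         "normal") -
      death_rate(N, state$Ap, p, "normal")
  }
  out
}
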