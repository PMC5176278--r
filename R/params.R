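# Parameter derivation from literature constants: unit conversions,
# steady-state tables, and closed-form inversion of the kinetic equations.

#' Avogadro's number (mol^-1)
#' @keywords internal
.N_AVOGADRO <- 6.022e23

#' Degradation rate from a half-life
#'
#' First-order decay `dX/dt = -d_X X` gives `d_X = ln 2 / t_half`.
#'
#' @param t_half half-life in days (> 0).
#' @return degradation rate in day^-1.
#' @examples
#' degradation_rate_from_half_life(1)        # MAPK, 24 h half-life
#' degradation_rate_from_half_life(0.03125)  # PTEN, 45 min half-life
#' @export
degradation_rate_from_half_life <- function(t_half) {
  if (!is.numeric(t_half) || any(!is.finite(t_half)) || any(t_half <= 0)) {
    stop("half-life must be a positive number of days")
  }
  log(2) / t_half
}

#' Molar to mass concentration
#'
#' A 1 nM solution of a species of molecular weight m kDa has a mass
#' concentration of m * 1e-9 g/cm^3 (1 Da = 1 g/mol, 1 nM = 1e-12 mol/cm^3).
#'
#' @param molar_nM molar concentration in nanomolar (> 0).
#' @param mw_kDa molecular weight in kilodalton (> 0).
#' @return mass concentration in g/cm^3.
#' @examples
#' molar_to_mass_concentration(400, 21)   # Ras -> MAPK steady state
#' molar_to_mass_concentration(15.1, 62)  # AKT steady state
#' @export
molar_to_mass_concentration <- function(molar_nM, mw_kDa) {
  if (any(!is.finite(molar_nM)) || any(molar_nM <= 0) ||
      any(!is.finite(mw_kDa)) || any(mw_kDa <= 0)) {
    stop("molar concentration and molecular weight must be positive")
  }
  molar_nM * mw_kDa * 1e-9
}

#' Copy number to mass concentration
#'
#' Converts molecules per cell to a tissue mass concentration:
#' `copies / N_A * mw_kDa * 1e3 / cell_volume` g/cm^3.
#'
#' @param copies molecules per cell (> 0).
#' @param mw_kDa molecular weight in kilodalton (> 0).
#' @param cell_volume cell volume in cm^3 (default 1e-9).
#' @return mass concentration in g/cm^3.
#' @examples
#' copies_to_mass_concentration(2.5e6, 170)  # EGFR
#' @export
copies_to_mass_concentration <- function(copies, mw_kDa,
                                         cell_volume = 1e-9) {
  if (any(!is.finite(copies)) || any(copies <= 0) ||
      any(!is.finite(mw_kDa)) || any(mw_kDa <= 0) ||
      any(!is.finite(cell_volume)) || any(cell_volume <= 0)) {
    stop("copies, molecular weight and cell volume must be positive")
  }
  copies / .N_AVOGADRO * mw_kDa * 1e3 / cell_volume
}

#' MicroRNA diffusivity by molecular-weight scaling
#'
#' Diffusivities scale with the inverse cube root of molecular weight;
#' the reference species is VEGF (D = 8.64e-2 cm^2/day, 24 kDa).
#'
#' @param mw_kDa molecular weight of the diffusing species in kDa.
#' @param D_ref,mw_ref reference diffusivity (cm^2/day) and weight (kDa).
#' @return diffusion coefficient in cm^2/day.
#' @examples
#' mir_diffusivity(7)  # miR-21 / miR-155
#' @export
mir_diffusivity <- function(mw_kDa, D_ref = 8.64e-2, mw_ref = 24) {
  if (any(mw_kDa <= 0) || D_ref <= 0 || mw_ref <= 0) {
    stop("molecular weights and diffusivity must be positive")
  }
  (mw_ref / mw_kDa)^(1 / 3) * D_ref
}

#' Steady-state concentration table
#'
#' Builds the table of steady-state concentrations (g/cm^3) from the
#' underlying literature constants: receptor copy numbers, molar
#' concentrations and molecular weights. `gamma` is the cellular:exosomal
#' miR ratio and `theta` the constant total cell density of the
#' proliferation phase.
#'
#' @param phase `"invasion"` (C_0 = 0.4) or `"proliferation"`
#'   (C_0 = 0.46, N_0 = 0.14 so that C_0 + N_0 = theta = 0.6).
#' @return named list of steady-state constants.
#' @export
steady_state_table <- function(phase = c("invasion", "proliferation")) {
  phase <- match.arg(phase)
  E_0 <- copies_to_mass_concentration(2.5e6, 170, 1e-9)
  P_30 <- molar_to_mass_concentration(8, 195)
  P_0 <- molar_to_mass_concentration(4, 47)
  ss <- list(
    E_0 = E_0,
    M_0 = molar_to_mass_concentration(400, 21),   # Ras proxy for MAPK
    P_30 = P_30,
    A_0 = molar_to_mass_concentration(15.1, 62),
    # TKI and PTEN inhibitions assumed proportional: T_0/E_0 = P_0/P_30
    T_0 = P_0 * E_0 / P_30,
    P_0 = P_0,
    Ap_0 = molar_to_mass_concentration(200, 142),
    E_C0 = 3.6e-10,
    m_10 = 2.8e-13,   # pooled miR-21 + miR-205, exosomal
    m_20 = 1.4e-13,   # miR-155, exosomal
    C_0 = if (phase == "invasion") 0.4 else 0.46,
    N_0 = 0.14,
    C_M = 0.8,
    gamma = 10,
    theta = 0.6
  )
  ss
}

#' Derive production rates by steady-state inversion
#'
#' Inverts the zero right-hand-side conditions of the kinetic equations at
#' the steady state, with every half-saturation at its steady-state
#' convention (K_X = X_0 for proteins and cells, K_mX = m_X0/5 for the
#' miRs). The cellular miR production rates close the cellular pools at
#' m1i = gamma * m_10 (resp. m2i).
#'
#' @param ss steady-state table, see [steady_state_table()].
#' @param degradations named list with entries `d_E`, `d_M`, `d_A`, `d_T`,
#'   `d_P`, `d_Ap`, `d_Ec`, `d_m1`, `d_m2` (day^-1).
#' @param lam_C combined steady-state proliferation rate of cancer cells
#'   (day^-1), split 2:1 between the MAPK and AKT branches.
#' @param lam_MA dimensionless Ras-branch weight in AKT activation.
#' @return named list of production/death rates (`lam_E`, `lam_M`, `lam_A`,
#'   `lam_T`, `lam_P`, `lam_Ap`, `lam_Ec`, `lam_m1`, `lam_m2`, `lam_m1i`,
#'   `lam_m2i`, `lam_C1`, `lam_C2`, `d_D`, `d_C`).
#' @export
derive_production_rates <- function(ss, degradations, lam_C = 0.46,
                                    lam_MA = 1 / 2) {
  d <- degradations
  need <- c("d_E", "d_M", "d_A", "d_T", "d_P", "d_Ap", "d_Ec", "d_m1",
            "d_m2")
  missing <- setdiff(need, names(d))
  if (length(missing) > 0) {
    stop("degradations is missing: ", paste(missing, collapse = ", "))
  }
  denom <- c(E_0 = ss$E_0, E_C0 = ss$E_C0, C_0 = ss$C_0)
  if (any(!is.finite(denom)) || any(denom <= 0)) {
    stop("steady-state denominators must be positive: ",
         paste(names(denom)[!(is.finite(denom) & denom > 0)],
               collapse = ", "))
  }
  if (lam_C <= 0) stop("lam_C must be positive")
  list(
    # K_ME = M_0 halves production at steady state
    lam_E = 2 * d$d_E * ss$E_0,
    # K_TM = T_0 halves MAPK activation
    lam_M = 2 * d$d_M * ss$M_0 / ss$E_0,
    # 1/(1+P_0/K_PA) * 1/(1+T_0/K_TA) * (1 + lam_MA/2) = 5/16
    lam_A = (16 / 5) * d$d_A * ss$A_0 / ss$E_0,
    # 1 + (1/2)(1+gamma) m_10 / (m_10/5) = 28.5
    lam_T = 28.5 * d$d_T * ss$T_0,
    # 1 + (1+gamma) m_10 / (m_10/5) = 56
    lam_P = 56 * d$d_P * ss$P_0,
    lam_Ap = 56 * d$d_Ap * ss$Ap_0,
    lam_Ec = d$d_Ec * ss$E_C0 / (2 * ss$C_0),
    lam_m1 = 2 * d$d_m1 * ss$m_10 / ss$E_C0,
    lam_m2 = 2 * d$d_m2 * ss$m_20 / ss$E_C0,
    lam_m1i = d$d_m1 * ss$gamma * ss$m_10 / ss$C_0,
    lam_m2i = d$d_m2 * ss$gamma * ss$m_20 / ss$C_0,
    lam_C1 = (4 / 3) * lam_C,
    lam_C2 = (2 / 3) * lam_C,
    d_D = 0.9 * lam_C,
    d_C = 0.05 * lam_C
  )
}

#' Default parameter set for one model phase
#'
#' Assembles the full validated parameter set: diffusivities, production
#' rates derived by [derive_production_rates()], degradation rates from
#' literature half-lives, half-saturations at their steady-state
#' conventions, and the steady-state table of [steady_state_table()].
#'
#' In the proliferation phase `lam_C1` and `lam_C2` are increased by a
#' factor 1.4 (proliferating cells grow faster than migrating cells) and
#' the steady densities become C_0 = 0.46, N_0 = 0.14 with
#' C_0 + N_0 = theta = 0.6 g/cm^3.
#'
#' The growth rate of normal cells is reported ambiguously in the source
#' literature: the tabulated value is 0.092 day^-1 while the steady-state
#' derivation 0.8 * lam_C gives 0.368 day^-1. Only the derived value makes
#' the stated proliferation steady state (C_0 = 0.46, N_0 = 0.14) an
#' equilibrium composition, so the proliferation phase defaults to
#' `lambda_N = "derived"`; both variants are available.
#'
#' @param phase `"invasion"` or `"proliferation"`.
#' @param lambda_N `"table"` (0.092 day^-1) or `"derived"` (0.8 * lam_C =
#'   0.368 day^-1). Defaults to `"table"` for invasion (where normal cells
#'   are absent) and `"derived"` for proliferation.
#' @param chi directed migration coefficient in cm^5 g^-1 day^-1; default
#'   3e-2 for invasion (unused in proliferation).
#' @param overrides optional named list of parameter values replacing the
#'   defaults (validation of derived identities is skipped for them).
#' @return object of class `parameter_set`: a named list of rates plus a
#'   `steady` sub-list, with attributes `phase` and `modified`.
#' @examples
#' p <- default_parameter_set("invasion")
#' p$d_Ec           # 21.8 / day
#' validate_parameters(p)
#' @export
default_parameter_set <- function(phase = c("invasion", "proliferation"),
                                  lambda_N = NULL, chi = 3e-2,
                                  overrides = NULL) {
  phase <- match.arg(phase)
  if (is.null(lambda_N)) {
    lambda_N <- if (phase == "proliferation") "derived" else "table"
  }
  lambda_N <- match.arg(lambda_N, c("table", "derived"))

  ss <- steady_state_table("invasion")   # derivation anchor
  degr <- list(
    d_E = degradation_rate_from_half_life(20 / 24),
    d_M = degradation_rate_from_half_life(1),
    d_A = degradation_rate_from_half_life(1),
    d_T = degradation_rate_from_half_life(2),
    d_P = degradation_rate_from_half_life(0.03125),   # 45 min
    d_Ap = degradation_rate_from_half_life(0.25),     # 6 h
    d_Ec = 21.8,                                      # fitted
    d_m1 = degradation_rate_from_half_life(1.25),     # 30 h
    d_m2 = degradation_rate_from_half_life(1.25)
  )
  lam_C <- 0.46
  rates <- derive_production_rates(ss, degr, lam_C = lam_C, lam_MA = 1 / 2)

  p <- c(
    list(
      D_Ec = 1.23e-4, D_m1 = mir_diffusivity(7), D_m2 = mir_diffusivity(7),
      D_C = 8.64e-7, D_N = 8.64e-7,
      chi = chi,
      lam_MA = 1 / 2,
      lam_C = lam_C,
      lam_N = if (lambda_N == "table") 0.092 else 0.8 * lam_C,
      eps = 0.1
    ),
    rates,
    degr,
    list(
      d_N = 0.023,
      d_DN = 1.1 * rates$d_D,
      K_ME = ss$M_0, K_TM = ss$T_0, K_TA = ss$T_0, K_PA = ss$P_0,
      K_mT = ss$m_10 / 5, K_mP = ss$m_10 / 5, K_m2 = ss$m_20 / 5,
      K_MA = ss$M_0, K_C = ss$C_0, K_M = ss$M_0, K_A = ss$A_0,
      K_Ap = ss$Ap_0
    )
  )

  if (phase == "proliferation") {
    p$lam_C1 <- 1.4 * p$lam_C1
    p$lam_C2 <- 1.4 * p$lam_C2
    p$steady <- steady_state_table("proliferation")
  } else {
    p$steady <- ss
  }

  modified <- character(0)
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), names(p))
    if (length(bad) > 0) {
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    }
    p[names(overrides)] <- overrides
    modified <- names(overrides)
  }

  structure(p, class = "parameter_set", phase = phase,
            lambda_N_variant = lambda_N, modified = modified)
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set>  phase:", attr(x, "phase"),
      " lambda_N:", attr(x, "lambda_N_variant"), "\n")
  flat <- x[setdiff(names(x), "steady")]
  cat(" ", length(flat), "rate/diffusivity/half-saturation entries,",
      length(x$steady), "steady-state constants\n")
  if (length(attr(x, "modified")) > 0) {
    cat("  modified:", paste(attr(x, "modified"), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Validate a parameter set
#'
#' Checks type invariants (positivity, chi range, C_0 <= C_M, the
#' proliferation-phase identity C_0 + N_0 = theta) and the derived-rate
#' identities of [derive_production_rates()] to relative tolerance 1e-3
#' (which absorbs 4-significant-figure rounding of printed constants).
#' Identities involving parameters listed in the `modified` attribute
#' (scenario-scaled or overridden) are skipped.
#'
#' @param p a `parameter_set`.
#' @param tol relative tolerance for the identity checks.
#' @return character vector of violations; empty if the set is valid.
#' @export
validate_parameters <- function(p, tol = 1e-3) {
  out <- character(0)
  flat <- unlist(p[setdiff(names(p), "steady")])
  nonpos <- names(flat)[!is.finite(flat) | flat <= 0]
  if (length(nonpos) > 0) {
    out <- c(out, paste0("nonpositive parameter: ", nonpos))
  }
  ss <- p$steady
  ssv <- unlist(ss)
  nonpos <- names(ssv)[!is.finite(ssv) | ssv <= 0]
  if (length(nonpos) > 0) {
    out <- c(out, paste0("nonpositive steady state: ", nonpos))
  }
  if (length(out) > 0) return(out)

  modified <- attr(p, "modified")
  if (is.null(modified)) modified <- character(0)
  phase <- attr(p, "phase")

  if (!("chi" %in% modified) &&
      (p$chi < 3e-4 - 1e-12 || p$chi > 3e-2 + 1e-12)) {
    out <- c(out, "chi outside [3e-4, 3e-2]")
  }
  if (ss$C_0 > ss$C_M) out <- c(out, "C_0 exceeds carrying capacity C_M")
  if (identical(phase, "proliferation") &&
      abs(ss$C_0 + ss$N_0 - ss$theta) > tol * ss$theta) {
    out <- c(out, "C_0 + N_0 != theta in proliferation phase")
  }

  # derived-rate identities, anchored at the invasion-phase steady state
  anchor <- steady_state_table("invasion")
  lam_C <- p$lam_C
  cfac <- if (identical(phase, "proliferation")) 1.4 else 1
  ident <- list(
    lam_E = 2 * p$d_E * anchor$E_0,
    lam_M = 2 * p$d_M * anchor$M_0 / anchor$E_0,
    lam_A = (16 / 5) * p$d_A * anchor$A_0 / anchor$E_0,
    lam_T = 28.5 * p$d_T * anchor$T_0,
    lam_P = 56 * p$d_P * anchor$P_0,
    lam_Ap = 56 * p$d_Ap * anchor$Ap_0,
    lam_Ec = p$d_Ec * anchor$E_C0 / (2 * anchor$C_0),
    lam_m1 = 2 * p$d_m1 * anchor$m_10 / anchor$E_C0,
    lam_m2 = 2 * p$d_m2 * anchor$m_20 / anchor$E_C0,
    lam_m1i = p$d_m1 * anchor$gamma * anchor$m_10 / anchor$C_0,
    lam_m2i = p$d_m2 * anchor$gamma * anchor$m_20 / anchor$C_0,
    lam_C1 = cfac * (4 / 3) * lam_C,
    lam_C2 = cfac * (2 / 3) * lam_C,
    d_D = 0.9 * lam_C,
    d_C = 0.05 * lam_C,
    d_DN = 1.1 * 0.9 * lam_C,
    K_mT = anchor$m_10 / 5,
    K_mP = anchor$m_10 / 5,
    K_m2 = anchor$m_20 / 5
  )
  skip <- unique(c(modified,
                   if (any(c("d_C", "d_D", "lam_C1", "lam_C2", "lam_C")
                           %in% modified))
                     c("d_C", "d_D", "d_DN", "lam_C1", "lam_C2")))
  for (nm in setdiff(names(ident), skip)) {
    if (abs(p[[nm]] - ident[[nm]]) > tol * abs(ident[[nm]])) {
      out <- c(out, paste0("derived-rate identity violated for ", nm))
    }
  }
  out
}

#' Write / read a parameter set as YAML
#'
#' The file is a flat mapping of symbol to value with a nested `steady`
#' mapping and a `phase` field; units follow the package conventions
#' (day^-1, g/cm^3, cm^2/day).
#'
#' @param p a `parameter_set`.
#' @param path file path.
#' @return `read_parameter_set` returns the restored `parameter_set`.
#' @export
write_parameter_set <- function(p, path) {
  obj <- p[setdiff(names(p), "steady")]
  obj$steady <- p$steady
  obj$phase <- attr(p, "phase")
  obj$modified <- as.list(attr(p, "modified"))
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_parameter_set
#' @export
read_parameter_set <- function(path) {
  obj <- yaml::read_yaml(path)
  phase <- obj$phase
  modified <- as.character(unlist(obj$modified))
  obj$phase <- NULL
  obj$modified <- NULL
  structure(obj, class = "parameter_set", phase = phase,
            modified = modified)
}
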