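# Mutation, anti-miR and chemotherapy scenarios as multiplicative
# parameter modifications, plus comparative efficacy metrics.

.scenario_catalogue <- list(
  control        = list(),
  # single oncogene activations (invasion figures)
  mut_EGFR       = list(lam_E = 1.3),
  mut_MAPK       = list(lam_M = 1.6),
  mut_AKT        = list(lam_A = 1.8),
  # dual mutations
  mut_EGFR_MAPK  = list(lam_E = 1.15, lam_M = 1.3),
  mut_EGFR_AKT   = list(lam_E = 1.15, lam_A = 1.4),
  mut_MAPK_AKT   = list(lam_M = 1.3, lam_A = 1.4),
  # anti-miR interventions: production suppressed in both the exosomal
  # and the cellular compartment
  anti_m1        = list(lam_m1 = 0.5, lam_m1i = 0.5),
  anti_m1_m2     = list(lam_m1 = 0.5, lam_m1i = 0.5,
                        lam_m2 = 0.5, lam_m2i = 0.5),
  # chemotherapy / strong-mutation variants (proliferation figures);
  # PTX and gefitinib factors are net multipliers of the already-scaled
  # proliferation rates so that composition stays multiplicative
  EGFRx3         = list(lam_E = 3),
  PTX            = list(lam_C1 = 1.3 / 1.4, lam_C2 = 1.3 / 1.4),
  gefitinib      = list(lam_E = 1.5 / 3),
  anti_m2_mild   = list(lam_m2 = 1 / 1.2, lam_m2i = 1 / 1.2),
  cisplatin      = list(d_C = 1.1, d_D = 1.1)
)

#' Scenario modifiers
#'
#' A named set of multiplicative factors applied to parameters, used to
#' encode mutations (production rates increased), anti-miR drugs
#' (production rates reduced) and chemotherapies.
#'
#' @param factors named list/vector of positive multiplicative factors;
#'   names must be parameter symbols.
#' @param label text label.
#' @return object of class `scenario_modifiers`.
#' @export
scenario_modifiers <- function(factors = list(), label = "custom") {
  factors <- as.list(factors)
  if (length(factors) > 0) {
    vals <- unlist(factors)
    if (is.null(names(factors)) || any(names(factors) == "")) {
      stop("all factors must be named")
    }
    if (any(!is.finite(vals)) || any(vals <= 0)) {
      stop("factors must be positive")
    }
  }
  structure(list(factors = factors, label = label),
            class = "scenario_modifiers")
}

#' Built-in scenario catalogue
#'
#' Returns the modifiers for a named scenario: single mutations
#' (`mut_EGFR`, `mut_MAPK`, `mut_AKT`), dual mutations
#' (`mut_EGFR_MAPK`, `mut_EGFR_AKT`, `mut_MAPK_AKT`), anti-miR treatments
#' (`anti_m1`, `anti_m1_m2`, `anti_m2_mild`), and the chemotherapy
#' variants `EGFRx3`, `PTX`, `gefitinib`, `cisplatin`. `control` is the
#' empty modifier.
#'
#' @param name scenario name; `list_scenarios()` returns all names.
#' @return a [scenario_modifiers()] object.
#' @examples
#' builtin_scenario("mut_MAPK")
#' @export
builtin_scenario <- function(name) {
  if (!name %in% names(.scenario_catalogue)) {
    stop("unknown scenario '", name, "'; see list_scenarios()")
  }
  scenario_modifiers(.scenario_catalogue[[name]], label = name)
}

#' @rdname builtin_scenario
#' @export
list_scenarios <- function() names(.scenario_catalogue)

#' @export
print.scenario_modifiers <- function(x, ...) {
  cat("<scenario_modifiers> ", x$label, "\n")
  if (length(x$factors) == 0) cat("  (identity)\n")
  for (nm in names(x$factors)) {
    cat(sprintf("  %s x %g\n", nm, x$factors[[nm]]))
  }
  invisible(x)
}

#' Compose scenarios
#'
#' Composition is multiplicative on the factors (hence commutative):
#' applying `anti_m1` twice quarters `lam_m1`.
#'
#' @param ... `scenario_modifiers` objects.
#' @return the composed `scenario_modifiers`.
#' @export
compose_scenarios <- function(...) {
  mods <- list(...)
  factors <- list()
  labels <- character(0)
  for (m in mods) {
    stopifnot(inherits(m, "scenario_modifiers"))
    for (nm in names(m$factors)) {
      factors[[nm]] <- (if (is.null(factors[[nm]])) 1 else
                          factors[[nm]]) * m$factors[[nm]]
    }
    labels <- c(labels, m$label)
  }
  scenario_modifiers(factors, label = paste(labels, collapse = " + "))
}

#' Apply scenario modifiers to a parameter set
#'
#' Multiplies the named parameters by their factors. Modified symbols are
#' recorded in the `modified` attribute so that
#' [validate_parameters()] skips their derived-rate identities.
#'
#' @param p a `parameter_set`.
#' @param mods a [scenario_modifiers()] object.
#' @return the modified `parameter_set`.
#' @examples
#' p <- default_parameter_set("invasion")
#' p2 <- apply_scenario(p, builtin_scenario("mut_EGFR"))
#' p2$lam_E / p$lam_E  # 1.3
#' @export
apply_scenario <- function(p, mods) {
  stopifnot(inherits(mods, "scenario_modifiers"))
  bad <- setdiff(names(mods$factors),
                 setdiff(names(p), "steady"))
  if (length(bad) > 0) {
    stop("unknown parameter symbol(s): ", paste(bad, collapse = ", "))
  }
  for (nm in names(mods$factors)) {
    p[[nm]] <- p[[nm]] * mods$factors[[nm]]
  }
  attr(p, "modified") <- unique(c(attr(p, "modified"),
                                  names(mods$factors)))
  p
}

# day-`day` (front-or-radius, mass) pair from a simulation result
.result_metrics <- function(res, day) {
  m <- res$metrics
  i <- which(abs(m$time - day) < 1e-9)
  if (length(i) != 1) {
    stop("requested day ", day, " was not recorded")
  }
  if (inherits(res, "invasion_result")) {
    c(extent = m$front_cm[i], mass = m$mass_C[i])
  } else if (inherits(res, "proliferation_result")) {
    c(extent = m$radius_cm[i],
      mass = m$volume_cm3[i] * res$averages[i, "C"])
  } else {
    stop("res must be an invasion_result or proliferation_result")
  }
}

#' Treatment efficacy
#'
#' The fractional reduction of the tumor extent and tumor mass at a
#' comparison day: `phi_R = (R_control - R_treated) / R_control` on the
#' front position (invasion) or radius (proliferation), and `phi_M`
#' likewise on the linear cancer mass (invasion) or total cancer mass
#' (proliferation).
#'
#' @param control,treated simulation results of the same type containing
#'   the requested day.
#' @param day comparison day (default 60).
#' @return list of class `efficacy_report` with `phi_R`, `phi_M` and the
#'   underlying metrics.
#' @export
efficacy <- function(control, treated, day = 60) {
  mc <- .result_metrics(control, day)
  mt <- .result_metrics(treated, day)
  structure(list(
    phi_R = unname((mc["extent"] - mt["extent"]) / mc["extent"]),
    phi_M = unname((mc["mass"] - mt["mass"]) / mc["mass"]),
    day = day, control = mc, treated = mt
  ), class = "efficacy_report")
}

#' @export
print.efficacy_report <- function(x, ...) {
  cat(sprintf(
    "<efficacy_report> day %g: phi_R = %.3f, phi_M = %.3f\n",
    x$day, x$phi_R, x$phi_M))
  invisible(x)
}

#' Sweep the directed migration coefficient
#'
#' Runs the invasion model at each `chi` value untreated and under a
#' treatment (default: both miR production rates halved) and tabulates
#' the day-`day` front positions, linear cancer masses and efficacies.
#'
#' @param p a `parameter_set` (invasion phase); its own `chi` is replaced
#'   by the sweep values.
#' @param chi_values directed migration coefficients (cm^5 g^-1 day^-1);
#'   default 8 log-spaced values over [3e-4, 3e-2]. Values outside that
#'   range trigger a warning.
#' @param treatment a [scenario_modifiers()] object for the treated arm.
#' @param t_end,day simulation horizon and comparison day.
#' @param ... further arguments passed to [run_invasion()].
#' @return data frame with columns `chi`, `R_chi`, `M_chi`, `R_chi_m`,
#'   `M_chi_m`, `phi_R`, `phi_M`.
#' @export
chi_sweep <- function(p, chi_values = NULL,
                      treatment = builtin_scenario("anti_m1_m2"),
                      t_end = 60, day = t_end, ...) {
  if (is.null(chi_values)) {
    chi_values <- exp(seq(log(3e-4), log(3e-2), length.out = 8))
  }
  if (any(chi_values < 3e-4 - 1e-12 | chi_values > 3e-2 + 1e-12)) {
    warning("chi values outside the modelled range [3e-4, 3e-2]")
  }
  rows <- lapply(chi_values, function(chi) {
    pc <- p
    pc$chi <- chi
    attr(pc, "modified") <- unique(c(attr(pc, "modified"), "chi"))
    ctl <- run_invasion(pc, t_end = t_end,
                        record_times = unique(c(0, day, t_end)), ...)
    trt <- run_invasion(apply_scenario(pc, treatment), t_end = t_end,
                        record_times = unique(c(0, day, t_end)), ...)
    eff <- efficacy(ctl, trt, day = day)
    data.frame(chi = chi,
               R_chi = eff$control["extent"], M_chi = eff$control["mass"],
               R_chi_m = eff$treated["extent"],
               M_chi_m = eff$treated["mass"],
               phi_R = eff$phi_R, phi_M = eff$phi_M)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
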