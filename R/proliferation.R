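# Radially symmetric free-boundary proliferation model: a small spherical
# tumor of radius R(t) in which cancer and normal cells share space at
# constant total density theta; the radial cell velocity u that enforces
# the constraint advects the moving mesh and the free boundary.

.prolif_field_names <- c(.field_names, "N")

#' Initialize the proliferation state
#'
#' R(0) = 0.01 cm with all fields uniform in r: growth-promoting proteins
#' below and growth-inhibiting proteins above their steady states,
#' exosome and exosomal miR concentrations at 1/100 of their steady
#' states, and C(r,0) + N(r,0) = 0.35 + 0.25 = theta. The cellular miR
#' pools start at gamma times the exosomal values, mirroring the
#' steady-state ratio.
#'
#' @param p a `parameter_set` (proliferation phase).
#' @param n_nodes number of radial mesh nodes (default 101, i.e. 100
#'   cells).
#' @param R0 initial tumor radius in cm.
#' @return object of class `proliferation_state` with elements `time`,
#'   `r` (node radii) and the node-by-variable matrix `fields`.
#' @export
initialize_proliferation <- function(p, n_nodes = 101, R0 = 0.01) {
  if (!identical(attr(p, "phase"), "proliferation")) {
    stop("p must be a proliferation-phase parameter set")
  }
  if (n_nodes < 5) stop("need at least 5 mesh nodes")
  init <- c(E = 6.7044e-4, M = 7.14e-6, A = 7.396e-7, T = 1.0206e-4,
            P = 2.2748e-7, Ap = 3.4648e-5, Ec = 3.6e-12, m1 = 2.8e-15,
            m2 = 1.4e-15, m1i = p$steady$gamma * 2.8e-15,
            m2i = p$steady$gamma * 1.4e-15, C = 0.35, N = 0.25)
  fields <- matrix(rep(init, each = n_nodes), nrow = n_nodes,
                   dimnames = list(NULL, .prolif_field_names))
  structure(list(time = 0, r = seq(0, R0, length.out = n_nodes),
                 fields = fields),
            class = "proliferation_state")
}

#' Radial cell velocity field
#'
#' The constant-total-density constraint C + N = theta turns the summed
#' cell equations into an equation for the radial velocity:
#' `u(r) = 1/(theta r^2) * int_0^r xi^2 [growth - death of C and N] dxi`,
#' evaluated by trapezoidal quadrature on the mesh, with u(0) = 0 by the
#' series limit.
#'
#' @param state a `proliferation_state`.
#' @param p a `parameter_set`.
#' @return velocity u per node in cm/day.
#' @export
velocity_field <- function(state, p) {
  .prolif_velocity(state$r, state$fields, unclass(p))
}

#' Advance the proliferation model
#'
#' Takes `nsteps` fully implicit time steps of size `tau` on the moving
#' mesh: mesh nodes are advected by the implicit velocity
#' (`r_i^{k+1} = r_i^k + u_i^{k+1} tau`), diffusion and the velocity
#' divergence are discretized with nonuniform three-point formulas, and
#' the nonlinear system is solved by damped Picard iteration to a scaled
#' residual below `picard_tol`. Symmetry holds at r = 0 and no-flux at the
#' free boundary r = R(t). If mesh cells collapse below
#' `remesh_frac * R`, all fields are re-interpolated (monotone cubic) onto
#' a fresh uniform mesh.
#'
#' @param state a `proliferation_state`.
#' @param p a `parameter_set` (proliferation phase).
#' @param tau time step in days.
#' @param nsteps number of steps.
#' @param freeze_mesh if `TRUE`, forces u = 0 and a static mesh (used for
#'   cross-checking against a method-of-lines reference).
#' @param picard_tol scaled sup-norm tolerance of the implicit solve.
#' @param picard_cap maximum Picard iterations per step.
#' @param remesh_frac smallest tolerated cell size as a fraction of R.
#' @return the advanced `proliferation_state`.
#' @export
advance_proliferation <- function(state, p, tau = 1e-3, nsteps = 1,
                                  freeze_mesh = FALSE, picard_tol = 1e-10,
                                  picard_cap = 50, remesh_frac = 1e-4) {
  if (tau <= 0) stop("tau must be positive")
  res <- .prolif_advance(state$r, state$fields, unclass(p), tau,
                         as.integer(nsteps), freeze_mesh, picard_tol,
                         as.integer(picard_cap), remesh_frac)
  state$r <- res$r
  state$fields <- res$fields
  state$time <- state$time + tau * nsteps
  state$max_picard_iters <- res$max_picard_iters
  state$n_remesh <- res$n_remesh
  state
}

# volume-weighted radial mean (3/R^3) int_0^R r^2 f dr by trapezoid
.radial_average <- function(r, f) {
  R <- r[length(r)]
  g <- r^2 * f
  3 / R^3 * sum(diff(r) * (g[-length(g)] + g[-1]) / 2)
}

# total mass int_0^R 4 pi r^2 f dr
.radial_mass <- function(r, f) {
  g <- 4 * pi * r^2 * f
  sum(diff(r) * (g[-length(g)] + g[-1]) / 2)
}

#' Run the proliferation model and record summary metrics
#'
#' Repeatedly advances the free-boundary model, recording the tumor
#' radius, volume, volume-weighted average of every variable, and the
#' total miR masses `int_0^R 4 pi r^2 (m + m_i) dr`.
#'
#' @inheritParams advance_proliferation
#' @param t_end final time in days.
#' @param n_nodes number of radial mesh nodes.
#' @param record_times recording times in days (multiples of `tau`).
#' @param include_cellular_mir include the cellular pools in the total
#'   miR masses (default `TRUE`).
#' @return object of class `proliferation_result`: data frame `metrics`
#'   with columns `time`, `radius_cm`, `volume_cm3`, `mass_m1_g`,
#'   `mass_m2_g`, and a matrix `averages` (time by variable) of
#'   volume-weighted means.
#' @examples
#' \donttest{
#' p <- default_parameter_set("proliferation")
#' res <- run_proliferation(p, t_end = 2, record_times = c(0, 1, 2))
#' res$metrics
#' }
#' @export
run_proliferation <- function(p, t_end = 60, tau = 1e-3, n_nodes = 101,
                              record_times = seq(0, t_end, by = 1),
                              include_cellular_mir = TRUE,
                              freeze_mesh = FALSE, picard_tol = 1e-10,
                              picard_cap = 50, remesh_frac = 1e-4) {
  state <- initialize_proliferation(p, n_nodes)
  record_times <- sort(unique(c(0, record_times[record_times <= t_end],
                                t_end)))
  steps <- round(record_times / tau)
  if (max(abs(steps * tau - record_times)) > 1e-9) {
    stop("record_times must be multiples of tau")
  }

  nt <- length(record_times)
  averages <- matrix(NA_real_, nrow = nt, ncol = 13,
                     dimnames = list(NULL, .prolif_field_names))
  met <- matrix(NA_real_, nrow = nt, ncol = 4)
  measure <- function(k, state) {
    r <- state$r
    R <- r[length(r)]
    f <- state$fields
    averages[k, ] <<- apply(f, 2, function(col) .radial_average(r, col))
    m1 <- f[, "m1"] + if (include_cellular_mir) f[, "m1i"] else 0
    m2 <- f[, "m2"] + if (include_cellular_mir) f[, "m2i"] else 0
    met[k, ] <<- c(R, 4 / 3 * pi * R^3,
                   .radial_mass(r, m1), .radial_mass(r, m2))
  }
  measure(1, state)
  for (k in seq_along(record_times)[-1]) {
    nsteps <- steps[k] - steps[k - 1]
    if (nsteps > 0) {
      state <- advance_proliferation(state, p, tau, nsteps, freeze_mesh,
                                     picard_tol, picard_cap, remesh_frac)
    }
    measure(k, state)
  }
  metrics <- data.frame(time = record_times, radius_cm = met[, 1],
                        volume_cm3 = met[, 2], mass_m1_g = met[, 3],
                        mass_m2_g = met[, 4])
  structure(list(metrics = metrics, averages = averages,
                 final_state = state, params = p),
            class = "proliferation_result")
}

#' @export
print.proliferation_result <- function(x, ...) {
  m <- x$metrics
  last <- m[nrow(m), ]
  cat("<proliferation_result> ", nrow(m), "records to day", last$time,
      "\n")
  cat(sprintf("  day-%g radius: %.4f cm, avg C: %.4f g/cm^3\n", last$time,
              last$radius_cm, x$averages[nrow(m), "C"]))
  invisible(x)
}
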