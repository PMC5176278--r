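# 1-D tumor-front invasion model on x in [0, 2] cm: the bulk tumor sits in
# x < 0 and its planar front advances into the domain, pushed by the
# nonlinear directed-migration flux chi * d/dx (C dC/dx).

#' Uniform invasion grid on [0, 2] cm
#'
#' @param dx node spacing in cm (must divide the domain length evenly).
#' @param length_cm domain length in cm.
#' @return list with `nodes` (positions) and `dx`, class `invasion_grid`.
#' @export
invasion_grid <- function(dx = 0.01, length_cm = 2) {
  if (dx <= 0 || length_cm <= 0) stop("dx and length must be positive")
  n_cells <- length_cm / dx
  if (abs(n_cells - round(n_cells)) > 1e-8) {
    stop("dx must divide the domain length evenly")
  }
  structure(list(nodes = seq(0, length_cm, by = dx), dx = dx),
            class = "invasion_grid")
}

#' Dirichlet boundary values at x = 0
#'
#' The x = 0 boundary represents the bulk tumor occupying x < 0, so the
#' imposed values are its steady state under the *current* parameters:
#' the cancer density C_0, and the exosome and miR levels solving the
#' zero-reaction conditions at C = C_0. With the default parameter set
#' these equal the tabulated steady states (E_C0, m_10, ...); under an
#' anti-miR scenario the miR boundary values scale down with the treated
#' production rates, i.e. the bulk tumor is treated too.
#'
#' @param p a `parameter_set`.
#' @return named vector of Dirichlet values for Ec, m1, m2, m1i, m2i, C.
#' @export
invasion_boundary_values <- function(p) {
  C0 <- p$steady$C_0
  Ec <- p$lam_Ec * (p$K_C + C0) / p$d_Ec
  merge_frac <- C0 / (p$K_C + C0)
  c(Ec = Ec,
    m1 = p$lam_m1 * Ec * merge_frac / p$d_m1,
    m2 = p$lam_m2 * Ec * merge_frac / p$d_m2,
    m1i = p$lam_m1i * C0 / p$d_m1,
    m2i = p$lam_m2i * C0 / p$d_m2,
    C = C0)
}

#' Initialize the invasion state
#'
#' Zero initial conditions on (0, 2]: the cancer is initially confined to
#' x < 0. At x = 0 the bulk tumor imposes the Dirichlet values of
#' [invasion_boundary_values()] (for the default parameters: exosomes and
#' exosomal miRs at their steady states, cellular miR pools at gamma
#' times those, cancer density at C_0). Protein concentrations start at 0
#' everywhere and evolve pointwise.
#'
#' @param p a `parameter_set` (invasion phase).
#' @param grid an [invasion_grid()].
#' @return object of class `invasion_state` with elements `time`, `grid`
#'   and the node-by-variable matrix `fields`.
#' @export
initialize_invasion <- function(p, grid = invasion_grid()) {
  n <- length(grid$nodes)
  fields <- matrix(0, nrow = n, ncol = 12,
                   dimnames = list(NULL, .field_names))
  fields[1, c("Ec", "m1", "m2", "m1i", "m2i", "C")] <-
    invasion_boundary_values(p)
  structure(list(time = 0, grid = grid, fields = fields),
            class = "invasion_state")
}

#' Advance the invasion model
#'
#' Takes `nsteps` semi-implicit time steps: implicit linear diffusion for
#' the transported fields (exosomes, miRs, cancer cells), explicit
#' reactions and explicit conservative directed-migration flux, pointwise
#' protein kinetics. Dirichlet values are re-imposed at x = 0 and no-flux
#' holds at x = 2. Negative round-off values are clipped to zero; values
#' below -1e-8 g/cm^3 signal a failed step and advise a smaller `dt`.
#'
#' @param state an `invasion_state`.
#' @param p a `parameter_set`.
#' @param dt time step in days (stability of the explicit flux requires
#'   roughly `dt < dx^2 / (2 chi C_M)`).
#' @param nsteps number of steps to take.
#' @return the advanced `invasion_state`.
#' @export
advance_invasion <- function(state, p, dt = 1e-3, nsteps = 1) {
  if (dt <= 0) stop("dt must be positive")
  res <- .invasion_advance(state$fields, unclass(p), state$grid$dx, dt,
                           as.integer(nsteps), invasion_boundary_values(p))
  state$fields <- res$fields
  state$time <- state$time + dt * nsteps
  state
}

#' Run the invasion model and record summary metrics
#'
#' Repeatedly advances the model, recording at `record_times` the front
#' position (largest x where C exceeds `threshold_fraction * C_0`), the
#' total linear mass of cancer cells and the total linear miR masses.
#'
#' @param p a `parameter_set` (invasion phase).
#' @param t_end final time in days.
#' @param dt time step in days.
#' @param dx grid spacing in cm.
#' @param record_times times (days) at which metrics are recorded; must be
#'   multiples of `dt`.
#' @param threshold_fraction front-detection threshold as a fraction of
#'   C_0.
#' @param include_cellular_mir if `TRUE` (default) the recorded miR masses
#'   integrate the exosomal plus cellular pools (m1 + m1i); otherwise the
#'   exosomal pool only.
#' @param snapshot_times optional times at which full spatial profiles are
#'   kept.
#' @return object of class `invasion_result`: a data frame `metrics` with
#'   columns `time`, `front_cm`, `mass_C`, `mass_m1`, `mass_m2` (masses in
#'   g/cm^2), plus any requested `snapshots`.
#' @examples
#' \donttest{
#' p <- default_parameter_set("invasion")
#' res <- run_invasion(p, t_end = 5, record_times = c(0, 5))
#' res$metrics
#' }
#' @export
run_invasion <- function(p, t_end = 60, dt = 1e-3, dx = 0.01,
                         record_times = seq(0, t_end, by = 1),
                         threshold_fraction = 0.1,
                         include_cellular_mir = TRUE,
                         snapshot_times = numeric(0)) {
  if (t_end < 0) stop("t_end must be nonnegative")
  grid <- invasion_grid(dx)
  state <- initialize_invasion(p, grid)
  record_times <- sort(unique(c(0, record_times[record_times <= t_end],
                                t_end)))
  steps <- round(record_times / dt)
  if (max(abs(steps * dt - record_times)) > 1e-9) {
    stop("record_times must be multiples of dt")
  }
  C0 <- p$steady$C_0

  measure <- function(state) {
    f <- state$fields
    m1 <- f[, "m1"] + if (include_cellular_mir) f[, "m1i"] else 0
    m2 <- f[, "m2"] + if (include_cellular_mir) f[, "m2i"] else 0
    c(front_cm = front_position(f[, "C"], grid, threshold_fraction, C0),
      mass_C = linear_mass(f[, "C"], grid),
      mass_m1 = linear_mass(m1, grid),
      mass_m2 = linear_mass(m2, grid))
  }

  snaps <- list()
  met <- matrix(NA_real_, nrow = length(record_times), ncol = 4)
  met[1, ] <- measure(state)
  for (k in seq_along(record_times)[-1]) {
    nsteps <- steps[k] - steps[k - 1]
    if (nsteps > 0) state <- advance_invasion(state, p, dt, nsteps)
    met[k, ] <- measure(state)
    if (any(abs(record_times[k] - snapshot_times) < 1e-9)) {
      snaps[[sprintf("t%g", record_times[k])]] <-
        cbind(x = grid$nodes, state$fields)
    }
  }
  metrics <- data.frame(time = record_times,
                        front_cm = met[, 1], mass_C = met[, 2],
                        mass_m1 = met[, 3], mass_m2 = met[, 4])
  structure(list(metrics = metrics, snapshots = snaps, grid = grid,
                 final_state = state, params = p),
            class = "invasion_result")
}

#' @export
print.invasion_result <- function(x, ...) {
  m <- x$metrics
  last <- m[nrow(m), ]
  cat("<invasion_result> ", nrow(m), "records to day", last$time, "\n")
  cat(sprintf("  day-%g front: %.4f cm, linear cancer mass: %.4g g/cm^2\n",
              last$time, last$front_cm, last$mass_C))
  invisible(x)
}

#' Tumor front position
#'
#' The largest x at which the cancer density reaches
#' `threshold_fraction * C0`, with linear interpolation between grid
#' nodes; 0 if the density is everywhere below the threshold.
#'
#' @param C_profile cancer density per grid node (g/cm^3).
#' @param grid an [invasion_grid()].
#' @param threshold_fraction threshold as a fraction of `C0` (in (0, 1)).
#' @param C0 reference density (the steady-state cancer density).
#' @return front position in cm.
#' @export
front_position <- function(C_profile, grid, threshold_fraction = 0.1,
                           C0 = 0.4) {
  if (threshold_fraction <= 0 || threshold_fraction >= 1) {
    stop("threshold_fraction must be in (0, 1)")
  }
  thr <- threshold_fraction * C0
  x <- grid$nodes
  above <- which(C_profile >= thr)
  if (length(above) == 0) return(0)
  i <- max(above)
  if (i == length(x)) return(x[i])
  # interpolate the downward crossing between nodes i and i+1
  x[i] + (x[i + 1] - x[i]) * (C_profile[i] - thr) /
    (C_profile[i] - C_profile[i + 1])
}

#' Total linear mass of a 1-D profile
#'
#' Trapezoidal integral of a density profile over the invasion domain,
#' i.e. mass per unit cross-sectional area (g/cm^2).
#'
#' @param profile density per grid node (g/cm^3).
#' @param grid an [invasion_grid()].
#' @return integral in g/cm^2.
#' @export
linear_mass <- function(profile, grid) {
  x <- grid$nodes
  sum(diff(x) * (profile[-length(profile)] + profile[-1]) / 2)
}
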