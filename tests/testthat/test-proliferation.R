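# free-boundary proliferation solver: initial conditions, the velocity
# functional, incompressibility, and a frozen-mesh method-of-lines oracle

test_that("initial conditions fill the tumor uniformly with C + N =
          theta", {
  st <- initialize_proliferation(p_pro)
  expect_equal(length(st$r), 101)
  expect_equal(st$r[1], 0)
  expect_equal(st$r[101], 0.01)
  expect_true(all(st$fields[, "C"] == 0.35))
  expect_true(all(st$fields[, "N"] == 0.25))
  expect_equal(unique(st$fields[, "C"] + st$fields[, "N"]), 0.6)
  expect_equal(unique(st$fields[, "T"]), 1.0206e-4)
  expect_equal(unique(st$fields[, "Ap"]), 3.4648e-5)
  expect_error(initialize_proliferation(p_inv), "proliferation")
})

test_that("velocity vanishes when growth balances death and follows the
          closed form for a uniform source", {
  st <- initialize_proliferation(p_pro)
  # kill all growth and death: u must be identically zero
  p0 <- p_pro
  for (nm in c("lam_C1", "lam_C2", "lam_N", "d_C", "d_D", "d_N",
               "d_DN")) {
    p0[[nm]] <- 1e-30
  }
  attr(p0, "modified") <- setdiff(names(p0), "steady")
  expect_equal(max(abs(velocity_field(st, p0))), 0, tolerance = 1e-25)

  # uniform fields give a spatially constant net source s, and the
  # velocity integral collapses to u(r) = s r / (3 theta)
  u <- velocity_field(st, p_pro)
  f <- st$fields[1, ]
  s <- growth_rate(f[["M"]], f[["A"]], f[["C"]], f[["N"]], p_pro,
                   "proliferation", "cancer") +
    growth_rate(f[["M"]], f[["A"]], f[["C"]], f[["N"]], p_pro,
                "proliferation", "normal") -
    death_rate(f[["C"]], f[["Ap"]], p_pro, "cancer") -
    death_rate(f[["N"]], f[["Ap"]], p_pro, "normal")
  expect_equal(u, s * st$r / (3 * p_pro$steady$theta), tolerance = 1e-10)
  expect_equal(u[1], 0)
})

test_that("short runs preserve C + N near theta, the volume identity and
          mesh ordering", {
  res <- run_proliferation(p_pro, t_end = 1, tau = 1e-3,
                           record_times = c(0, 0.5, 1))
  st <- res$final_state
  expect_lt(max(abs(st$fields[, "C"] + st$fields[, "N"] - 0.6)),
            0.02 * 0.6)
  expect_true(all(diff(st$r) > 0))
  expect_equal(res$metrics$volume_cm3,
               4 / 3 * pi * res$metrics$radius_cm^3)
  expect_true(all(res$metrics$mass_m1_g >= 0))
  expect_true(all(st$fields >= 0))
})

test_that("with growth off and death on, the tumor shrinks", {
  p0 <- p_pro
  p0$lam_C1 <- 1e-30
  p0$lam_C2 <- 1e-30
  p0$lam_N <- 1e-30
  attr(p0, "modified") <- setdiff(names(p0), "steady")
  res <- run_proliferation(p0, t_end = 1, tau = 1e-3,
                           record_times = c(0, 0.5, 1))
  expect_true(all(diff(res$metrics$radius_cm) < 0))
})

test_that("the radius moves at u(R) to first order in tau", {
  st <- initialize_proliferation(p_pro)
  u_R <- velocity_field(st, p_pro)[101]
  for (tau in c(2e-3, 1e-3)) {
    st2 <- advance_proliferation(st, p_pro, tau = tau)
    dR <- st2$r[101] - st$r[101]
    expect_equal(dR / tau, u_R, tolerance = 1e-2)
  }
})

test_that("on a frozen mesh the implicit solver matches a method-of-lines
          reference", {
  skip_if_not_installed("deSolve")
  n <- 31
  st <- initialize_proliferation(p_pro, n_nodes = n)
  # perturb the initial data so diffusion is active
  st$fields[, "C"] <- 0.35 + 0.02 * cos(pi * st$r / 0.01)
  st$fields[, "N"] <- 0.6 - st$fields[, "C"]
  t_end <- 0.25

  got <- advance_proliferation(st, p_pro, tau = 2.5e-5,
                               nsteps = t_end / 2.5e-5,
                               freeze_mesh = TRUE)

  # reference: stiff MOL integration of the same semi-discrete system
  r <- st$r
  nm <- colnames(st$fields)
  lap <- function(f) {
    out <- numeric(n)
    h <- r[2] - r[1]
    out[1] <- 6 * (f[2] - f[1]) / h^2
    i <- 2:(n - 1)
    out[i] <- (f[i + 1] - 2 * f[i] + f[i - 1]) / h^2 +
      (f[i + 1] - f[i - 1]) / h / r[i]
    out[n] <- 2 * (f[n - 1] - f[n]) / h^2
    out
  }
  Dmap <- c(E = 0, M = 0, A = 0, T = 0, P = 0, Ap = 0, Ec = p_pro$D_Ec,
            m1 = p_pro$D_m1, m2 = p_pro$D_m2, m1i = p_pro$D_C,
            m2i = p_pro$D_C, C = p_pro$D_C, N = p_pro$D_N)
  deriv <- function(t, y, parms) {
    f <- matrix(pmax(y, 0), nrow = n, dimnames = list(NULL, nm))
    s <- as.list(as.data.frame(f))
    rates <- point_rhs(s, p_pro, "proliferation")
    dy <- sapply(nm, function(v) rates[[v]] + Dmap[[v]] * lap(f[, v]))
    list(as.vector(dy))
  }
  ref <- deSolve::ode(y = as.vector(st$fields), times = c(0, t_end),
                      func = deriv, parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-16)
  ref_f <- matrix(ref[2, -1], nrow = n, dimnames = list(NULL, nm))
  for (v in c("C", "N", "Ec", "m1", "T", "Ap")) {
    expect_equal(got$fields[, v], ref_f[, v], tolerance = 1e-4,
                 label = paste("field", v))
  }
})
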