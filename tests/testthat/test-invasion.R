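# 1-D invasion solver: initialization, conservation/fixed-point checks,
# front and mass functionals, and short-horizon dynamics

test_that("initialization imposes the bulk-tumor boundary and zero
          interior", {
  st <- initialize_invasion(p_inv)
  expect_equal(unname(st$fields[1, "C"]), 0.4)
  expect_equal(unname(st$fields[1, "Ec"]), p_inv$steady$E_C0,
               tolerance = 1e-12)
  expect_equal(unname(st$fields[1, "m1i"]),
               p_inv$steady$gamma * p_inv$steady$m_10, tolerance = 1e-12)
  expect_true(all(st$fields[-1, ] == 0))
  expect_true(all(st$fields[1, c("E", "M", "A", "T", "P", "Ap")] == 0))
  grid <- st$grid
  expect_equal(linear_mass(st$fields[, "C"], grid), 0.5 * 0.01 * 0.4)
  # only the boundary node is occupied: the front sits within one cell
  expect_lte(front_position(st$fields[, "C"], grid, 0.1, 0.4), grid$dx)
})

test_that("anti-miR scenarios scale the bulk boundary values
          consistently", {
  bc0 <- invasion_boundary_values(p_inv)
  bc1 <- invasion_boundary_values(
    apply_scenario(p_inv, builtin_scenario("anti_m1")))
  expect_equal(bc1[["m1"]], bc0[["m1"]] / 2)
  expect_equal(bc1[["m1i"]], bc0[["m1i"]] / 2)
  expect_equal(bc1[["m2"]], bc0[["m2"]])
  expect_equal(bc1[["C"]], bc0[["C"]])
  # defaults reproduce the tabulated steady state
  expect_equal(unname(bc0),
               c(3.6e-10, 2.8e-13, 1.4e-13, 2.8e-12, 1.4e-12, 0.4),
               tolerance = 1e-4)
})

test_that("a uniform steady-state profile is a fixed point of the
          stepper", {
  st <- initialize_invasion(p_inv)
  ss <- steady_point_state(p_inv)
  for (nm in colnames(st$fields)) st$fields[, nm] <- ss[[nm]]
  st2 <- advance_invasion(st, p_inv, dt = 1e-3, nsteps = 10)
  expect_equal(st2$fields, st$fields, tolerance = 1e-8)
})

test_that("with transport and kinetics off, an isolated pulse is
          preserved", {
  p0 <- p_inv
  p0$chi <- 0
  p0$D_C <- 1e-30
  # zero growth and death so the C reaction vanishes
  p0$lam_C1 <- 1e-30
  p0$lam_C2 <- 1e-30
  p0$d_C <- 1e-30
  p0$d_D <- 1e-30
  attr(p0, "modified") <- setdiff(names(p0), "steady")
  st <- initialize_invasion(p0)
  st$fields[, "C"] <- 0
  st$fields[80:90, "C"] <- 0.2
  st$fields[1, "C"] <- invasion_boundary_values(p0)[["C"]]
  before <- st$fields[, "C"]
  st2 <- advance_invasion(st, p0, dt = 1e-3, nsteps = 100)
  expect_equal(st2$fields[, "C"], before, tolerance = 1e-10)
})

test_that("front position interpolates crossings and responds
          monotonically", {
  grid <- invasion_grid()
  C <- ifelse(grid$nodes <= 0.5, 0.4, 0)
  f <- front_position(C, grid, 0.1, 0.4)
  expect_true(abs(f - 0.5) <= grid$dx)
  expect_equal(front_position(rep(0, 201), grid, 0.1, 0.4), 0)
  # pointwise increase never moves the front backwards
  C2 <- pmin(C + 0.05, 0.4)
  expect_gte(front_position(C2, grid, 0.1, 0.4), f)
  # saturated profile reaches the domain end
  expect_equal(front_position(rep(0.4, 201), grid, 0.1, 0.4), 2)
  expect_error(front_position(C, grid, 1.2, 0.4), "threshold")
})

test_that("linear mass is the trapezoidal integral", {
  grid <- invasion_grid()
  expect_equal(linear_mass(rep(0.3, 201), grid), 0.6)
  expect_equal(linear_mass(rep(0, 201), grid), 0)
  # quadratic profile: trapezoid error is O(dx^2)
  f <- function(x) x^2 * (2 - x)
  coarse <- linear_mass(f(grid$nodes), grid)
  fine_grid <- invasion_grid(dx = 0.0025)
  fine <- linear_mass(f(fine_grid$nodes), fine_grid)
  exact <- 4 / 3
  expect_lt(abs(fine - exact), abs(coarse - exact))
  expect_equal(coarse, exact, tolerance = 1e-4)
})

test_that("short runs advance the front monotonically with nonnegative
          fields", {
  res <- run_invasion(p_inv, t_end = 3, record_times = 0:3)
  expect_true(all(diff(res$metrics$front_cm) >= 0))
  expect_true(all(res$metrics$mass_C >= 0))
  expect_true(all(res$final_state$fields >= 0))
  expect_true(all(diff(res$metrics$mass_m1) > 0))
  # t_end = 0 returns the initialization metrics
  res0 <- run_invasion(p_inv, t_end = 0, record_times = 0)
  expect_lte(res0$metrics$front_cm, 0.01)
  expect_equal(res0$metrics$mass_C, 0.5 * 0.01 * 0.4)
})

test_that("halving the miR-21 production slows the front within days", {
  ctl <- run_invasion(p_inv, t_end = 5, record_times = c(0, 5))
  trt <- run_invasion(apply_scenario(p_inv, builtin_scenario("anti_m1")),
                      t_end = 5, record_times = c(0, 5))
  expect_lt(trt$metrics$front_cm[2], ctl$metrics$front_cm[2])
  expect_lt(trt$metrics$mass_C[2], ctl$metrics$mass_C[2])
})

test_that("refining the grid and step changes short-horizon metrics by
          well under two percent", {
  a <- run_invasion(p_inv, t_end = 2, record_times = c(0, 2))
  b <- run_invasion(p_inv, t_end = 2, dt = 2.5e-4, dx = 0.005,
                    record_times = c(0, 2))
  expect_equal(a$metrics$front_cm[2], b$metrics$front_cm[2],
               tolerance = 0.02)
  expect_equal(a$metrics$mass_C[2], b$metrics$mass_C[2],
               tolerance = 0.02)
})
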