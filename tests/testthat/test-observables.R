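test_that("axial velocity is the stream-function gradient", {
  p <- decoupled_params()
  s <- flat_section(F = 2)
  sol <- hpm_solve(p, s)
  expect_equal(axial_velocity(sol, 0), 1.5)
  expect_equal(axial_velocity(sol, c(-1, 1)), c(0, 0), tolerance = 1e-12)
  # even in eta when psi is odd
  eta <- seq(0.1, 0.9, by = 0.2)
  expect_equal(axial_velocity(sol, eta), axial_velocity(sol, -eta))
  expect_error(axial_velocity(sol, 1.5), class = "sutterby_domain_error")
})

test_that("shear stress follows the Sutterby law", {
  p <- decoupled_params()
  p$beta_F <- 1
  s <- flat_section(F = 2)
  sol <- hpm_solve(p, s)
  # cubic psi: psi'' = -3 at eta = 1, tau = (1 - 9) * (-3) = 24
  expect_equal(shear_stress(sol, 1), 24, tolerance = 1e-10)
  expect_equal(shear_stress(sol, 0), 0, tolerance = 1e-12)

  pn <- decoupled_params()  # Newtonian limit: tau = psi''
  soln <- hpm_solve(pn, s)
  eta <- seq(-1, 1, by = 0.25)
  expect_equal(shear_stress(soln, eta),
               poly_eval(poly_deriv(soln$psi, 2), eta))
})

test_that("pressure gradient matches hand evaluation in the trivial limit", {
  p <- decoupled_params()
  p$beta_F <- 0.8; p$Ra <- 0.5; p$Fr <- 0.5; p$Lambda <- pi / 2
  sol <- hpm_solve(p, flat_section(F = 2))
  # psi''' = -3, psi''(0) = 0, body force (Ra/Fr) sin(pi/2) = 1
  expect_equal(pressure_gradient(sol, 0), -2, tolerance = 1e-12)
  expect_equal(pressure_gradient(sol), -2, tolerance = 1e-12)  # centre default
  # off centre the Sutterby factor engages: psi'' = -1.5 at eta = 0.5,
  # dp/dxi = -3 (1 - 0.8 * 2.25) + 1 = 3.4
  expect_equal(pressure_gradient(sol, 0.5), 3.4, tolerance = 1e-12)
  expect_error(pressure_gradient(sol, 3), class = "sutterby_domain_error")

  # all contributions off
  p0 <- decoupled_params()
  p0$Lambda <- 0
  sol0 <- hpm_solve(p0, flat_section(F = 0))
  expect_equal(pressure_gradient(sol0, 0), 0, tolerance = 1e-12)
})

test_that("pressure gradient agrees with a finite-difference oracle evaluation", {
  # buoyancy-driven linear case: the cascade terminates exactly at first
  # order, so the oracle solves the same solution and the finite-difference
  # evaluation of the expression checks the assembly itself
  p <- flow_params(Pr = 1, M = 0, beta_F = 0, N_T = 0, N_B = 0, E_C = 0,
                   Sc = 0, K_R = 0, G_R = 0.2, G_C = 0.2, Lambda = pi / 3)
  case <- printed_series_case()
  sol <- hpm_solve(p, case$section)
  num <- solve_numeric(p, case$section, init = "hpm")
  n <- length(num$eta); h <- diff(num$eta[1:2])
  mid <- (n + 1) / 2
  d1 <- (num$psi[mid + 1] - num$psi[mid - 1]) / (2 * h)
  d2 <- (num$psi[mid + 1] - 2 * num$psi[mid] + num$psi[mid - 1]) / h^2
  d3 <- (num$psi[mid + 2] - 2 * num$psi[mid + 1] + 2 * num$psi[mid - 1] -
           num$psi[mid - 2]) / (2 * h^3)
  hallD <- hall_denominator(p)
  dp_num <- d3 * (1 - p$beta_F * d2^2) -
    p$M^2 * (1 + p$beta_e * p$beta_i) / hallD * d1 +
    p$G_R * num$theta[mid] + p$G_C * num$phi[mid] +
    (p$Ra / p$Fr) * sin(p$Lambda)
  expect_equal(pressure_gradient(sol, num$eta[mid]), dp_num, tolerance = 1e-3)
})

test_that("pressure rise per wavelength integrates to the closed form", {
  # straight channel, couplings off: constant integrand
  # psi''' = -3F/2 = -2.1, body force = 1, so delta p = -1.1
  p <- decoupled_params()
  p$Ra <- 0.5; p$Fr <- 0.5; p$Lambda <- pi / 2
  g <- channel_geometry(a = 0, b = 0, m = 0, omega = 0, Theta = 1.4)
  expect_equal(pressure_rise(p, g, t = 0.2), -1.1, tolerance = 1e-10)

  p0 <- decoupled_params()
  p0$Lambda <- 0
  g0 <- channel_geometry(a = 0, b = 0, m = 0, omega = 0, Theta = 0)
  expect_equal(pressure_rise(p0, g0, t = 0.2), 0, tolerance = 1e-12)
})

test_that("quadrature is converged at the default node count", {
  p <- baseline_params()
  g <- channel_geometry()
  dp64 <- pressure_rise(p, g, n_quad = 64)
  dp128 <- pressure_rise(p, g, n_quad = 128)
  expect_lt(abs(dp64 - dp128), 1e-8)
})

test_that("heat-transfer coefficient reduces to the ramp closed form", {
  p <- flow_params(Pr = 1, N_T = 0, N_B = 0, E_C = 0, Sc = 0, K_R = 0)
  g <- channel_geometry(a = 0.3, b = 0, m = 0, omega = 0, Theta = 1.4)
  # flat upper wall: Z = 0 for all xi
  expect_equal(heat_transfer_coefficient(p, g, 0.37, 0.2), 0)

  g2 <- channel_geometry(a = 0.3, b = 0.3, m = 0.2, omega = pi / 3, Theta = 1.4)
  s <- cross_section(0.4, 0.2, g2)
  slope <- g2$m + 2 * pi * g2$b * cos(2 * pi * (0.4 - 0.2))
  expect_equal(heat_transfer_coefficient(p, g2, 0.4, 0.2),
               slope / (s$h2 - s$h1), tolerance = 1e-10)
})

test_that("heat-transfer coefficient agrees between homotopy and oracle", {
  # viscous heating of the bare cubic: theta = ramp + dissipation correction
  # solves the full energy equation exactly at Pr = 1, so the oracle provides
  # an independent wall-gradient evaluation
  p <- flow_params(Pr = 1, M = 0, beta_F = 0, N_T = 0, N_B = 0, E_C = 0.1,
                   Sc = 0, K_R = 0, G_R = 0, G_C = 0)
  g <- channel_geometry(omega = pi / 3)
  s <- cross_section(0.4, 0.2, g)
  z_hpm <- heat_transfer_coefficient(p, g, 0.4, 0.2)
  num <- solve_numeric(p, s, init = "hpm")
  n <- length(num$eta); h <- diff(num$eta[1:2])
  dth_wall <- sum(c(11, -18, 9, -2) / (6 * h) * num$theta[n:(n - 3)])
  slope <- g$m + 2 * pi * g$b * cos(2 * pi * (0.4 - 0.2))
  expect_equal(z_hpm, slope * dth_wall, tolerance = 1e-2)
})

test_that("Nusselt conventions coincide in the symmetric ramp limit", {
  p <- flow_params(Pr = 1, N_T = 0, N_B = 0, E_C = 0, Sc = 0, K_R = 0)
  g <- channel_geometry(a = 0, b = 0, m = 0, omega = 0, Theta = 1.4)
  expect_equal(nusselt(p, g, 0.4, 0.2), 0.5, tolerance = 1e-12)
  expect_equal(nusselt(p, g, 0.4, 0.2, wall = "h1"),
               nusselt(p, g, 0.4, 0.2, wall = "h2"))
})

test_that("grids satisfy the wall data column-wise and refine consistently", {
  p <- flow_params(Pr = 1)
  g <- channel_geometry(a = 0, b = 0, m = 0, omega = 0, Theta = 1.4)
  sg <- stream_grid(p, g, t = 0.2, n_xi = 7, n_eta = 21)
  tg <- isotherm_grid(p, g, t = 0.2, n_xi = 7, n_eta = 21)
  for (j in seq_along(sg$xi)) {
    F_j <- flow_rate(sg$xi[j], 0.2, g)
    expect_equal(sg$values[1, j], -F_j / 2, tolerance = 1e-10)
    expect_equal(sg$values[21, j], F_j / 2, tolerance = 1e-10)
    expect_equal(tg$values[1, j], 0, tolerance = 1e-10)
    expect_equal(tg$values[21, j], 1, tolerance = 1e-10)
  }

  # a refined mesh contains the coarse nodes; polynomial evaluation must match
  g2 <- channel_geometry()
  c51 <- isotherm_grid(baseline_params(), g2, n_xi = 5, n_eta = 51)
  c101 <- isotherm_grid(baseline_params(), g2, n_xi = 5, n_eta = 101)
  shared <- c101$values[seq(1, 101, by = 2), ]
  both <- !is.na(c51$values) & !is.na(shared)
  expect_gt(sum(both), 100)
  expect_lt(max(abs(c51$values[both] - shared[both])), 1e-6)

  df <- grid_to_df(c51)
  expect_true(all(c("xi", "eta", "value") %in% names(df)))
  expect_false(anyNA(df$value))
})

test_that("pressure rise trends follow the governing terms", {
  g <- channel_geometry()
  dp_ra <- vapply(c(0.5, 1, 1.5, 2), function(v)
    pressure_rise(flow_params(Ra = v), g, n_quad = 16), numeric(1))
  expect_true(all(diff(dp_ra) > 0))

  dp_fr <- vapply(c(0.5, 1, 1.5, 2), function(v)
    pressure_rise(flow_params(Fr = v), g, n_quad = 16), numeric(1))
  expect_true(all(diff(dp_fr) < 0))

  # the inclination series as published: pi/2, pi/3, pi/4, pi/5
  dp_li <- vapply(c(pi / 2, pi / 3, pi / 4, pi / 5), function(v)
    pressure_rise(flow_params(Lambda = v), g, n_quad = 16), numeric(1))
  expect_true(all(diff(dp_li) < 0))
})

test_that("pressure rise is linear in the body-force term with unit slope", {
  g <- channel_geometry()
  p1 <- flow_params(Ra = 0.5, Fr = 0.5, Lambda = pi / 2)
  p2 <- flow_params(Ra = 0.5, Fr = 0.5, Lambda = pi / 5)
  dp1 <- pressure_rise(p1, g, n_quad = 16)
  dp2 <- pressure_rise(p2, g, n_quad = 16)
  body1 <- (p1$Ra / p1$Fr) * sin(p1$Lambda)
  body2 <- (p2$Ra / p2$Fr) * sin(p2$Lambda)
  expect_equal(dp1 - dp2, body1 - body2, tolerance = 1e-10)
})
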