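test_that("the exact polynomial boundary-value solve reproduces closed forms", {
  # u'' = 0, u(-1) = 0, u(1) = 1 -> linear ramp
  u <- poly_bvp(0, -1, 1, order = 2, value = c(0, 1))
  expect_equal(poly_coeffs(poly_trim(u)), c(0.5, 0.5))

  # u'''' = 24 with homogeneous clamped data -> eta^4 - 2 eta^2 + 1
  u <- poly_bvp(24, -1, 1, order = 4, value = c(0, 0), slope = c(0, 0))
  expect_equal(poly_coeffs(poly_trim(u, 1e-14)), c(1, 0, -2, 0, 1))
  expect_equal(poly_coeffs(poly_deriv(u, 4)), 24)
  expect_equal(poly_eval(u, c(-1, 1)), c(0, 0), tolerance = 1e-14)
  expect_equal(poly_eval(poly_deriv(u), c(-1, 1)), c(0, 0), tolerance = 1e-13)

  # u'' = 2, u(+-1) = 0 -> eta^2 - 1
  u <- poly_bvp(2, -1, 1, order = 2, value = c(0, 0))
  expect_equal(poly_coeffs(poly_trim(u)), c(-1, 0, 1))

  expect_error(poly_bvp(0, 1, 1, order = 2), "h1 >= h2")
})

test_that("zeroth order gives the clamped cubic and linear ramps", {
  s <- flat_section(F = 2)
  z <- hpm_order0(s)
  expect_equal(poly_coeffs(poly_trim(z$psi, 1e-14)), c(0, 1.5, 0, -0.5))
  expect_equal(poly_coeffs(poly_trim(z$theta)), c(0.5, 0.5))
  expect_equal(poly_coeffs(poly_trim(z$phi)), c(0.5, 0.5))

  z0 <- hpm_order0(flat_section(F = 0))
  expect_equal(max(abs(poly_coeffs(z0$psi))), 0)
})

test_that("first-order forcings vanish in the advertised limits", {
  s <- flat_section(F = 2)
  z <- hpm_order0(s)

  p <- flow_params(M = 0, G_R = 0, G_C = 0, beta_F = 0.7)
  rhs <- hpm_rhs_order1(z, p)
  expect_equal(max(abs(poly_coeffs(rhs$psi))), 0)

  p <- flow_params(Pr = 1, N_T = 0, N_B = 0, E_C = 0)
  rhs <- hpm_rhs_order1(z, p)
  expect_equal(max(abs(poly_coeffs(rhs$theta))), 0)
})

test_that("first-order species forcing is the reaction term alone", {
  # with a linear zeroth-order temperature the thermophoresis term drops and
  # only Sc*K_R*phi0 survives: 0.3 * (eta + 1)/2 on the unit channel
  s <- flat_section(F = 2)
  z <- hpm_order0(s)
  p <- flow_params(N_T = 1, N_B = 0.5, Sc = 0.6, K_R = 0.5)
  rhs <- hpm_rhs_order1(z, p)
  expect_equal(poly_coeffs(poly_trim(rhs$phi)), c(0.15, 0.15))
})

test_that("all couplings off reduces the cascade to the zeroth order exactly", {
  p <- decoupled_params()
  s <- flat_section(F = 2)
  sol <- hpm_solve(p, s)
  for (k in 2:3) {
    expect_equal(max(abs(poly_coeffs(sol$psi_orders[[k]]))), 0)
    expect_equal(max(abs(poly_coeffs(sol$theta_orders[[k]]))), 0)
    expect_equal(max(abs(poly_coeffs(sol$phi_orders[[k]]))), 0)
  }
  expect_equal(poly_coeffs(poly_trim(sol$psi, 1e-14)), c(0, 1.5, 0, -0.5))
  expect_lt(max(sol$residuals), 1e-12)
})

test_that("higher orders vanish selectively when their forcings are off", {
  s <- flat_section(F = 2)
  # theta stays a ramp when conduction balances exactly
  p <- flow_params(Pr = 1, N_T = 0, N_B = 0, E_C = 0, Sc = 0.6, K_R = 0.5)
  sol <- hpm_solve(p, s)
  expect_equal(poly_coeffs(poly_trim(sol$theta)), c(0.5, 0.5))
  # phi stays a ramp without thermophoresis and reaction
  p <- flow_params(N_T = 0, K_R = 0)
  sol <- hpm_solve(p, s)
  expect_equal(poly_coeffs(poly_trim(sol$phi)), c(0.5, 0.5))
})

test_that("assembled solutions satisfy all eight boundary values", {
  set.seed(101)
  for (i in 1:100) {
    p <- rand_params()
    g <- rand_geometry()
    s <- tryCatch(cross_section(runif(1, 0, 1), runif(1, 0, 1), g),
                  closed_channel_error = function(e) NULL)
    if (is.null(s)) next
    sol <- hpm_solve(p, s)
    expect_lt(abs(poly_eval(sol$psi, s$h2) - s$F / 2), 1e-10)
    expect_lt(abs(poly_eval(sol$psi, s$h1) + s$F / 2), 1e-10)
    u_w <- poly_eval(poly_deriv(sol$psi), c(s$h1, s$h2))
    expect_lt(max(abs(u_w)), 1e-10)
    expect_lt(abs(poly_eval(sol$theta, s$h1)), 1e-10)
    expect_lt(abs(poly_eval(sol$theta, s$h2) - 1), 1e-10)
    expect_lt(abs(poly_eval(sol$phi, s$h1)), 1e-10)
    expect_lt(abs(poly_eval(sol$phi, s$h2) - 1), 1e-10)
  }
})

test_that("stream function is odd in a symmetric channel without buoyancy", {
  set.seed(55)
  g <- channel_geometry(a = 0.3, b = 0.3, m = 0, omega = 0, Theta = 1.4)
  for (i in 1:10) {
    p <- rand_params()
    p$G_R <- 0; p$G_C <- 0
    s <- cross_section(runif(1), runif(1), g)
    sol <- hpm_solve(p, s)
    eta <- seq(0, s$h2, length.out = 31)
    for (k in 1:3) {
      ps <- sol$psi_orders[[k]]
      expect_lt(max(abs(poly_eval(ps, eta) + poly_eval(ps, -eta))), 1e-10)
    }
    expect_lt(max(abs(poly_eval(sol$psi, eta) + poly_eval(sol$psi, -eta))),
              1e-10)
  }
})

test_that("lower truncation orders are nested inside higher ones", {
  case <- printed_series_case()
  s0 <- hpm_solve(case$params, case$section, hpm_config(order = 0))
  s1 <- hpm_solve(case$params, case$section, hpm_config(order = 1))
  s2 <- hpm_solve(case$params, case$section, hpm_config(order = 2))
  z <- hpm_order0(case$section)
  expect_equal(poly_coeffs(s0$psi), poly_coeffs(poly_trim(z$psi, 0)))
  expect_equal(poly_coeffs(s1$psi_orders[[1]]), poly_coeffs(s2$psi_orders[[1]]))
  expect_equal(poly_coeffs(s1$psi_orders[[2]]), poly_coeffs(s2$psi_orders[[2]]))
  expect_equal(poly_coeffs(s1$theta_orders[[2]]), poly_coeffs(s2$theta_orders[[2]]))
})

test_that("assembled degrees match the printed series degrees", {
  case <- printed_series_case()
  sol <- hpm_solve(case$params, case$section)
  expect_lte(poly_degree(sol$psi, 1e-12), 9L)
  expect_lte(poly_degree(sol$theta, 1e-12), 8L)
})

test_that("split boundary allocation still satisfies the assembled data", {
  case <- printed_series_case()
  sol <- hpm_solve(case$params, case$section,
                   hpm_config(bc_allocation = "split"))
  s <- case$section
  expect_lt(abs(poly_eval(sol$psi, s$h2) - s$F / 2), 1e-10)
  expect_lt(abs(poly_eval(sol$theta, s$h2) - 1), 1e-10)
  # and differs from the default allocation away from the walls
  ref <- hpm_solve(case$params, case$section)
  expect_gt(abs(poly_eval(sol$theta, 0) - poly_eval(ref$theta, 0)), 1e-6)
})

test_that("printed series coefficients are recovered to the achievable accuracy", {
  # the printed polynomials carry internal inconsistencies of order 1e-4
  # (their wall data disagree with exact trigonometry), so agreement is
  # bounded by the source's own rounding; these are the recorded regression
  # levels with m = 0.2, the taper reading that matches
  case <- printed_series_case()
  sol <- hpm_solve(case$params, case$section)
  th <- poly_coeffs(sol$theta)
  ps <- poly_coeffs(sol$psi)
  expect_equal(th[1], 0.9356802228, tolerance = 2e-4)
  expect_equal(th[2], 0.3221766493, tolerance = 1e-3)
  expect_equal(ps[1], -0.0557051150073254246, tolerance = 5e-3)
  expect_equal(ps[2], 1.03368242276481737, tolerance = 2e-4)
  # the m = 0 reading is clearly worse on the temperature constant
  geom0 <- channel_geometry(a = 0.3, b = 0.3, m = 0, omega = pi / 3,
                            Theta = 1.4)
  sol0 <- hpm_solve(case$params, cross_section(0.4, 0.2, geom0))
  expect_gt(abs(poly_coeffs(sol0$theta)[1] - 0.9356802228), 0.01)
})
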