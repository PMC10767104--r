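#' Configuration of the homotopy perturbation solver
#'
#' @param order truncation order of the embedding-parameter series, one of
#'   0, 1, 2 (default 2, matching the printed solutions).
#' @param bc_allocation `"full_at_zeroth"` places the complete boundary data
#'   on the zeroth-order problem and homogeneous data on every higher order,
#'   the standard construction and the only one under which the assembled sum
#'   satisfies the boundary conditions identically. `"split"` spreads each
#'   boundary value equally across the orders; it is retained purely as a
#'   sensitivity probe for regression against the printed series.
#' @param residual_grid_size number of uniform points in `[h1, h2]` on which
#'   the residuals of the assembled solution are measured.
#' @param beta1,beta2 optional overrides for the ion-slip symbol appearing in
#'   the first- and second-order Hall blocks. The source's order equations
#'   typeset these as distinct symbols; the natural reading (and the default,
#'   `NULL`) is that both are the ion-slip parameter `beta_i`. Setting them
#'   independently allows forensic comparison of the alternative readings.
#' @export
hpm_config <- function(order = 2,
                       bc_allocation = c("full_at_zeroth", "split"),
                       residual_grid_size = 201,
                       beta1 = NULL, beta2 = NULL) {
  if (!order %in% 0:2) stop("order must be 0, 1 or 2")
  structure(list(order = order,
                 bc_allocation = match.arg(bc_allocation),
                 residual_grid_size = as.integer(residual_grid_size),
                 beta1 = beta1, beta2 = beta2),
            class = "hpm_config")
}

#' Exact polynomial two-point boundary-value solve
#'
#' Solves `u^(order) = rhs` for a polynomial `rhs`, imposing the boundary
#' data by `order`-fold antidifferentiation plus a small linear solve for the
#' integration constants. For `order = 4` the data are values and first
#' derivatives at both walls (stream-function type); for `order = 2` values
#' only (temperature/concentration type). The result is exact up to the
#' linear solve: no collocation or truncation is involved.
#'
#' @param rhs polynomial right-hand side (`eta_poly` or coefficient vector).
#' @param h1,h2 wall positions, `h1 < h2`.
#' @param order derivative order, 2 or 4.
#' @param value length-2 boundary values `c(u(h1), u(h2))`.
#' @param slope length-2 boundary slopes `c(u'(h1), u'(h2))`, order 4 only.
#' @return the solution as an `eta_poly`.
#' @examples
#' poly_bvp(0, -1, 1, order = 2, value = c(0, 1))       # (eta + 1)/2
#' poly_bvp(24, -1, 1, order = 4, value = c(0, 0))      # eta^4 - 2 eta^2 + 1
#' @export
poly_bvp <- function(rhs, h1, h2, order = 2, value = c(0, 0),
                     slope = c(0, 0)) {
  if (!order %in% c(2, 4)) stop("order must be 2 or 4")
  if (h1 >= h2) stop("degenerate boundary system: h1 >= h2")
  P <- poly_antideriv(as_eta_poly(rhs), order)
  if (order == 4) {
    Pd <- poly_deriv(P)
    A <- rbind(c(1, h1, h1^2, h1^3),
               c(1, h2, h2^2, h2^3),
               c(0, 1, 2 * h1, 3 * h1^2),
               c(0, 1, 2 * h2, 3 * h2^2))
    b <- c(value - poly_eval(P, c(h1, h2)),
           slope - poly_eval(Pd, c(h1, h2)))
  } else {
    A <- rbind(c(1, h1), c(1, h2))
    b <- value - poly_eval(P, c(h1, h2))
  }
  P + eta_poly(solve(A, b))
}

# boundary data per order under the configured allocation
hpm_bc_schedule <- function(section, config) {
  K <- config$order
  f <- if (config$bc_allocation == "split") rep(1 / (K + 1), K + 1)
       else c(1, rep(0, K))
  lapply(seq_len(K + 1), function(k) {
    list(psi_value = f[k] * c(-section$F / 2, section$F / 2),
         psi_slope = c(0, 0),
         ramp_value = f[k] * c(0, 1))
  })
}

#' Zeroth-order homotopy solution
#'
#' The zeroth order solves the bare linear operators: the unique cubic
#' stream function with `psi(h1) = -F/2`, `psi(h2) = F/2` and no-slip walls,
#' and linear ramps for temperature and concentration (0 at the lower wall,
#' 1 at the upper).
#'
#' @param section a [cross_section()].
#' @param config an [hpm_config()]; only the boundary allocation is used.
#' @return list of `eta_poly`: `psi`, `theta`, `phi`.
#' @export
hpm_order0 <- function(section, config = hpm_config()) {
  bc <- hpm_bc_schedule(section, config)[[1]]
  list(psi = poly_bvp(0, section$h1, section$h2, order = 4,
                      value = bc$psi_value, slope = bc$psi_slope),
       theta = poly_bvp(0, section$h1, section$h2, order = 2,
                        value = bc$ramp_value),
       phi = poly_bvp(0, section$h1, section$h2, order = 2,
                      value = bc$ramp_value))
}

# Hall-block coefficients; beta_override substitutes for beta_i when the two
# order equations are read with independent ion-slip symbols
hall_coeffs <- function(params, beta_override = NULL) {
  bi <- if (is.null(beta_override)) params$beta_i else beta_override
  D <- (1 + params$beta_e * bi)^2 + params$beta_e^2
  list(momentum = params$M^2 * (1 + params$beta_e * bi) / D,
       joule = params$M^2 / D)
}

#' First-order forcing polynomials
#'
#' Moves every known zeroth-order term of the first-order procedure across
#' the equals sign. Because the zeroth-order stream function is a cubic, its
#' fourth derivative vanishes and the Sutterby product terms drop out exactly;
#' what remains of the momentum forcing is the Hall-damped curvature minus the
#' buoyancy gradients.
#'
#' @param order0 list with `psi`, `theta`, `phi` from [hpm_order0()].
#' @param params a [flow_params()] set.
#' @param config an [hpm_config()].
#' @return list of forcing `eta_poly`s named `psi`, `theta`, `phi` (the
#'   right-hand sides of `psi1''''`, `theta1''`, `phi1''`).
#' @export
hpm_rhs_order1 <- function(order0, params, config = hpm_config()) {
  hc <- hall_coeffs(params, config$beta1)
  p <- params
  psi0 <- order0$psi; th0 <- order0$theta; ph0 <- order0$phi
  psi0_1 <- poly_deriv(psi0); psi0_2 <- poly_deriv(psi0, 2)
  psi0_4 <- poly_deriv(psi0, 4)
  th0_1 <- poly_deriv(th0); th0_2 <- poly_deriv(th0, 2)
  ph0_1 <- poly_deriv(ph0)
  sut0 <- eta_poly(1) - p$beta_F * (psi0_2 * psi0_2)

  rhs_psi <- psi0_4 - psi0_4 * sut0 + hc$momentum * psi0_2 -
    p$G_R * th0_1 - p$G_C * ph0_1
  rhs_theta <- th0_2 - (1 / p$Pr) * th0_2 -
    p$N_T * (th0_1 * th0_1) -
    p$N_B * (th0_1 * ph0_1) -
    p$E_C * ((psi0_2 * psi0_2) * sut0) -
    p$E_C * hc$joule * (psi0_1 * psi0_1)
  rhs_phi <- -nt_over_nb(p) * th0_2 + p$Sc * p$K_R * ph0
  list(psi = rhs_psi, theta = rhs_theta, phi = rhs_phi)
}

#' Second-order forcing polynomials
#'
#' Right-hand sides of the second-order procedure, implemented exactly as the
#' source prints them (including the single cross term
#' `2 beta_F psi0'''' psi0'' psi1''`, which a strict product expansion would
#' double). `psi1_4` is the first-order forcing, i.e. `psi1''''`.
#'
#' @param order0,order1 solved polynomial triples for orders 0 and 1.
#' @param psi1_4 the forcing polynomial used for `psi1` (its exact fourth
#'   derivative).
#' @inheritParams hpm_rhs_order1
#' @export
hpm_rhs_order2 <- function(order0, order1, psi1_4, params,
                           config = hpm_config()) {
  hc <- hall_coeffs(params, config$beta2)
  p <- params
  psi0_1 <- poly_deriv(order0$psi); psi0_2 <- poly_deriv(order0$psi, 2)
  psi0_4 <- poly_deriv(order0$psi, 4)
  th0_1 <- poly_deriv(order0$theta); ph0_1 <- poly_deriv(order0$phi)
  psi1_1 <- poly_deriv(order1$psi); psi1_2 <- poly_deriv(order1$psi, 2)
  th1_1 <- poly_deriv(order1$theta); th1_2 <- poly_deriv(order1$theta, 2)
  ph1_1 <- poly_deriv(order1$phi)
  sut0 <- eta_poly(1) - p$beta_F * (psi0_2 * psi0_2)

  rhs_psi <- psi1_4 - psi1_4 * sut0 +
    2 * p$beta_F * (psi0_4 * (psi0_2 * psi1_2)) +
    hc$momentum * psi1_2 - p$G_R * th1_1 - p$G_C * ph1_1
  rhs_theta <- th1_2 - (1 / p$Pr) * th1_2 -
    2 * p$N_T * (th0_1 * th1_1) -
    p$N_B * (th0_1 * ph1_1) - p$N_B * (th1_1 * ph0_1) +
    2 * p$E_C * p$beta_F * (((psi0_2 * psi0_2) * psi0_2) * psi1_2) -
    2 * p$E_C * hc$joule * (psi0_1 * psi1_1) -
    2 * p$E_C * ((psi0_2 * psi1_2) * sut0)
  rhs_phi <- -nt_over_nb(p) * th1_2 + p$Sc * p$K_R * order1$phi
  list(psi = rhs_psi, theta = rhs_theta, phi = rhs_phi)
}

solve_order_k <- function(rhs, section, bc) {
  list(theta = poly_bvp(rhs$theta, section$h1, section$h2, order = 2,
                        value = bc$ramp_value),
       phi = poly_bvp(rhs$phi, section$h1, section$h2, order = 2,
                      value = bc$ramp_value),
       psi = poly_bvp(rhs$psi, section$h1, section$h2, order = 4,
                      value = bc$psi_value, slope = bc$psi_slope))
}

# residual polynomials of the assembled solution in the three governing
# equations, evaluated as a max-norm on a uniform grid
hpm_residuals <- function(psi, theta, phi, params, section, grid_size) {
  hc <- hall_coeffs(params)
  p <- params
  psi_1 <- poly_deriv(psi); psi_2 <- poly_deriv(psi, 2)
  psi_4 <- poly_deriv(psi, 4)
  th_1 <- poly_deriv(theta); th_2 <- poly_deriv(theta, 2)
  ph_1 <- poly_deriv(phi); ph_2 <- poly_deriv(phi, 2)
  sut <- eta_poly(1) - p$beta_F * (psi_2 * psi_2)
  r_mom <- psi_4 * sut - hc$momentum * psi_2 + p$G_R * th_1 + p$G_C * ph_1
  r_en <- (1 / p$Pr) * th_2 + p$N_T * (th_1 * th_1) +
    p$N_B * (th_1 * ph_1) + p$E_C * hc$joule * (psi_1 * psi_1) +
    p$E_C * ((psi_2 * psi_2) * sut)
  r_sp <- ph_2 + nt_over_nb(p) * th_2 - p$Sc * p$K_R * phi
  grid <- seq(section$h1, section$h2, length.out = grid_size)
  c(momentum = max(abs(poly_eval(r_mom, grid))),
    energy = max(abs(poly_eval(r_en, grid))),
    species = max(abs(poly_eval(r_sp, grid))))
}

#' Solve the coupled system by the homotopy perturbation cascade
#'
#' Runs the zeroth-, first- and second-order procedures (up to
#' `config$order`), assembles the stream function, temperature and
#' concentration at embedding parameter 1, and attaches max-norm residuals of
#' the three governing equations on a dense grid. All algebra is exact on
#' polynomial coefficients; within each order the temperature and
#' concentration problems are solved before the stream function.
#'
#' @param params a [flow_params()] set.
#' @param section a [cross_section()].
#' @param config an [hpm_config()].
#' @return an object of class `hpm_solution` with per-order polynomials
#'   (`psi_orders`, `theta_orders`, `phi_orders`), the assembled `psi`,
#'   `theta`, `phi`, the inputs, and `residuals`.
#' @examples
#' case <- printed_series_case()
#' sol <- hpm_solve(case$params, case$section)
#' poly_coeffs(sol$theta)[1:2]   # constant and linear temperature coefficients
#' @export
hpm_solve <- function(params, section, config = hpm_config()) {
  stopifnot(inherits(params, "sutterby_params"),
            inherits(section, "cross_section"))
  chk <- validate_params(params)
  if (!chk$valid)
    stop("invalid parameters: ", paste(chk$violations, collapse = "; "))
  bcs <- hpm_bc_schedule(section, config)

  orders <- list(hpm_order0_bc(section, bcs[[1]]))
  rhs1 <- NULL
  if (config$order >= 1) {
    rhs1 <- hpm_rhs_order1(orders[[1]], params, config)
    orders[[2]] <- solve_order_k(rhs1, section, bcs[[2]])
  }
  if (config$order >= 2) {
    rhs2 <- hpm_rhs_order2(orders[[1]], orders[[2]], rhs1$psi, params, config)
    orders[[3]] <- solve_order_k(rhs2, section, bcs[[3]])
  }

  assemble <- function(part) {
    out <- orders[[1]][[part]]
    for (k in seq_along(orders)[-1]) out <- out + orders[[k]][[part]]
    poly_trim(out, tol = 0)
  }
  psi <- assemble("psi"); theta <- assemble("theta"); phi <- assemble("phi")
  structure(list(
    psi = psi, theta = theta, phi = phi,
    psi_orders = lapply(orders, `[[`, "psi"),
    theta_orders = lapply(orders, `[[`, "theta"),
    phi_orders = lapply(orders, `[[`, "phi"),
    params = params, section = section, config = config,
    residuals = hpm_residuals(psi, theta, phi, params, section,
                              config$residual_grid_size)),
    class = "hpm_solution")
}

# order-0 solve against an explicit boundary allocation (split mode support)
hpm_order0_bc <- function(section, bc) {
  list(psi = poly_bvp(0, section$h1, section$h2, order = 4,
                      value = bc$psi_value, slope = bc$psi_slope),
       theta = poly_bvp(0, section$h1, section$h2, order = 2,
                        value = bc$ramp_value),
       phi = poly_bvp(0, section$h1, section$h2, order = 2,
                      value = bc$ramp_value))
}

#' @export
print.hpm_solution <- function(x, ...) {
  cat(sprintf("<hpm_solution> order %d at xi = %g, t = %g\n",
              x$config$order, x$section$xi, x$section$t))
  cat(sprintf("  deg(psi) = %d, deg(theta) = %d, deg(phi) = %d\n",
              poly_degree(x$psi, 1e-14), poly_degree(x$theta, 1e-14),
              poly_degree(x$phi, 1e-14)))
  cat("  residual max-norms:",
      paste(names(x$residuals), format(x$residuals, digits = 3),
            sep = " = ", collapse = ", "), "\n")
  invisible(x)
}
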