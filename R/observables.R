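in_channel <- function(eta, section, what) {
  lo <- section$h1 - 1e-12
  hi <- section$h2 + 1e-12
  if (any(eta < lo | eta > hi)) {
    stop(structure(
      class = c("sutterby_domain_error", "error", "condition"),
      list(message = paste0(what, ": eta outside the channel [",
                            format(section$h1), ", ", format(section$h2), "]"),
           call = sys.call(-2))))
  }
  invisible(TRUE)
}

#' Axial velocity profile
#'
#' `u = d psi / d eta`, evaluated from the assembled stream-function
#' polynomial. Errors outside the channel.
#'
#' @param sol an [hpm_solve()] result.
#' @param eta evaluation points within `[h1, h2]`.
#' @export
axial_velocity <- function(sol, eta) {
  stopifnot(inherits(sol, "hpm_solution"))
  in_channel(eta, sol$section, "axial_velocity")
  poly_eval(poly_deriv(sol$psi), eta)
}

#' Shear stress profile
#'
#' The Sutterby shear stress `tau = (1 - beta_F (psi'')^2) psi''`; at
#' `beta_F = 0` this is the Newtonian `psi''`.
#'
#' @inheritParams axial_velocity
#' @export
shear_stress <- function(sol, eta) {
  stopifnot(inherits(sol, "hpm_solution"))
  in_channel(eta, sol$section, "shear_stress")
  d2 <- poly_eval(poly_deriv(sol$psi, 2), eta)
  (1 - sol$params$beta_F * d2^2) * d2
}

#' Axial pressure gradient
#'
#' `dp/dxi = psi''' (1 - beta_F (psi'')^2) - M^2 (1 + beta_e beta_i)/D psi'
#' + G_R theta + G_C phi + (Ra/Fr) sin(Lambda)`. The expression retains an
#' eta dependence in the lubrication limit; the evaluation point defaults to
#' mid-channel (the symmetric choice), and `where` selects the wall or the
#' cross-sectional average instead.
#'
#' @inheritParams axial_velocity
#' @param eta explicit evaluation point(s); overrides `where` when given.
#' @param where `"centre"` (default), `"average"` (cross-sectional mean) or
#'   `"wall"`.
#' @param wall which wall when `where = "wall"`.
#' @export
pressure_gradient <- function(sol, eta = NULL, where = c("centre", "average", "wall"),
                              wall = c("h2", "h1")) {
  stopifnot(inherits(sol, "hpm_solution"))
  where <- match.arg(where)
  wall <- match.arg(wall)
  p <- sol$params
  hc <- hall_coeffs(p)
  psi_1 <- poly_deriv(sol$psi); psi_2 <- poly_deriv(sol$psi, 2)
  psi_3 <- poly_deriv(sol$psi, 3)
  body <- (p$Ra / p$Fr) * sin(p$Lambda)
  dp_poly <- psi_3 * (eta_poly(1) - p$beta_F * (psi_2 * psi_2)) -
    hc$momentum * psi_1 + p$G_R * sol$theta + p$G_C * sol$phi
  if (!is.null(eta)) {
    in_channel(eta, sol$section, "pressure_gradient")
    return(poly_eval(dp_poly, eta) + body)
  }
  sec <- sol$section
  switch(where,
    centre = poly_eval(dp_poly, (sec$h1 + sec$h2) / 2) + body,
    wall = poly_eval(dp_poly, if (wall == "h2") sec$h2 else sec$h1) + body,
    average = {
      anti <- poly_antideriv(dp_poly)
      diff(poly_eval(anti, c(sec$h1, sec$h2))) / (sec$h2 - sec$h1) + body
    })
}

#' Pressure rise per wavelength
#'
#' Integrates the axial pressure gradient over one wave period
#' `xi in [0, 1]` at fixed time, re-solving the homotopy cascade at every
#' quadrature node's cross-section. Gauss-Legendre quadrature; the integrand
#' is smooth in `xi` so the default 64 nodes are converged well below 1e-8.
#'
#' @param params a [flow_params()] set.
#' @param geom a [channel_geometry()].
#' @param t time.
#' @param n_quad number of Gauss-Legendre nodes.
#' @param config an [hpm_config()].
#' @param where,wall pressure-gradient evaluation convention, see
#'   [pressure_gradient()].
#' @export
pressure_rise <- function(params, geom, t = 0.2, n_quad = 64,
                          config = hpm_config(), where = "centre",
                          wall = "h2") {
  gl <- pracma::gaussLegendre(n_quad, 0, 1)
  vals <- vapply(gl$x, function(xi) {
    sol <- hpm_solve(params, cross_section(xi, t, geom), config)
    pressure_gradient(sol, where = where, wall = wall)
  }, numeric(1))
  sum(gl$w * vals)
}

# axial slope of the selected wall
wall_slope <- function(xi, t, geom, wall) {
  phase <- 2 * pi * (xi - t)
  if (wall == "h2") geom$m + 2 * pi * geom$b * cos(phase)
  else -geom$m - 2 * pi * geom$a * cos(phase + geom$omega)
}

#' Heat-transfer coefficient along the wavy wall
#'
#' `Z = (dh2/dxi) * (d theta/d eta)` at the upper wall (our convention; the
#' wall selector switches to the lower wall, where the slope is
#' `dh1/dxi = -m - 2 pi a cos(2 pi (xi - t) + omega)`). `Z` vanishes
#' identically for a flat untapered wall.
#'
#' @inheritParams pressure_rise
#' @param xi axial station.
#' @param wall `"h2"` (default) or `"h1"`.
#' @export
heat_transfer_coefficient <- function(params, geom, xi, t = 0.2,
                                      wall = c("h2", "h1"),
                                      config = hpm_config()) {
  wall <- match.arg(wall)
  section <- cross_section(xi, t, geom)
  sol <- hpm_solve(params, section, config)
  eta_w <- if (wall == "h2") section$h2 else section$h1
  wall_slope(xi, t, geom, wall) * poly_eval(poly_deriv(sol$theta), eta_w)
}

#' Nusselt number (wall temperature gradient)
#'
#' The source uses the symbol without defining it; the package convention is
#' the signed temperature gradient at the upper wall,
#' `Nu = (d theta/d eta)|_{h2}`. Both the wall and the sign are selectable so
#' the fixture runner can sweep conventions against the tabulated values; in
#' the symmetric linear-ramp limit every convention with positive sign gives
#' the same number.
#'
#' @inheritParams heat_transfer_coefficient
#' @param negate flip the sign of the gradient.
#' @export
nusselt <- function(params, geom, xi, t = 0.2, wall = c("h2", "h1"),
                    negate = FALSE, config = hpm_config()) {
  wall <- match.arg(wall)
  section <- cross_section(xi, t, geom)
  sol <- hpm_solve(params, section, config)
  eta_w <- if (wall == "h2") section$h2 else section$h1
  s <- if (negate) -1 else 1
  s * poly_eval(poly_deriv(sol$theta), eta_w)
}

profile_grid <- function(xi, eta, values, quantity, params, geom, t) {
  structure(list(xi = xi, eta = eta, values = values, quantity = quantity,
                 params = params, geom = geom, t = t),
            class = "profile_grid")
}

grid_field <- function(params, geom, t, xi_range, n_xi, n_eta, config, field) {
  xi <- seq(xi_range[1], xi_range[2], length.out = n_xi)
  w <- wall_positions(xi, t, geom)  # errors early if the channel closes
  eta <- seq(min(w$h1), max(w$h2), length.out = n_eta)
  vals <- matrix(NA_real_, n_eta, n_xi)
  for (j in seq_along(xi)) {
    section <- cross_section(xi[j], t, geom)
    sol <- hpm_solve(params, section, config)
    inside <- eta >= section$h1 & eta <= section$h2
    vals[inside, j] <- poly_eval(sol[[field]], eta[inside])
  }
  profile_grid(xi, eta, vals, field, params, geom, t)
}

#' Stream-function and temperature grids
#'
#' Per-station homotopy solves sampled on an `(xi, eta)` mesh; points outside
#' the channel are masked with `NA`. Level sets of the stream-function grid
#' are the streamlines (closed sets are trapped boluses); the temperature
#' grid gives the isotherms.
#'
#' @inheritParams pressure_rise
#' @param xi_range axial extent, default one wavelength.
#' @param n_xi,n_eta mesh resolution.
#' @return a `profile_grid`: vectors `xi`, `eta` and an `n_eta x n_xi`
#'   matrix `values`.
#' @export
stream_grid <- function(params, geom, t = 0.2, xi_range = c(0, 1),
                        n_xi = 41, n_eta = 51, config = hpm_config()) {
  grid_field(params, geom, t, xi_range, n_xi, n_eta, config, "psi")
}

#' @rdname stream_grid
#' @export
isotherm_grid <- function(params, geom, t = 0.2, xi_range = c(0, 1),
                          n_xi = 41, n_eta = 51, config = hpm_config()) {
  grid_field(params, geom, t, xi_range, n_xi, n_eta, config, "theta")
}

#' @export
print.profile_grid <- function(x, ...) {
  cat(sprintf("<profile_grid> %s on %d x %d (eta x xi) mesh, %d points in channel\n",
              x$quantity, length(x$eta), length(x$xi), sum(!is.na(x$values))))
  invisible(x)
}

#' Long-format export of a profile grid
#'
#' @param grid a `profile_grid`.
#' @return data.frame with columns `xi`, `eta`, `value` (masked points
#'   dropped).
#' @export
grid_to_df <- function(grid) {
  stopifnot(inherits(grid, "profile_grid"))
  df <- expand.grid(eta = grid$eta, xi = grid$xi, KEEP.OUT.ATTRS = FALSE)
  df$value <- as.vector(grid$values)
  df <- df[!is.na(df$value), c("xi", "eta", "value")]
  rownames(df) <- NULL
  df
}
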