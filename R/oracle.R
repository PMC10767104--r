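#' Independent finite-difference solution of the coupled system
#'
#' Collocation cross-check for the homotopy cascade: the fourth-order
#' momentum equation, the energy equation and the species equation are
#' discretised with second-order central differences on a uniform mesh over
#' `[h1, h2]` (cubic-exact one-sided stencils for the wall-slope rows) and
#' the resulting nonlinear algebraic system is solved by a damped Newton
#' iteration with an analytic Jacobian. The residual is formed exactly as the
#' equations are written -- the Sutterby factor `1 - beta_F (psi'')^2`
#' multiplies the fourth derivative and is never divided through, so the
#' method remains regular where the factor changes sign (dividing it out, as
#' a shooting method must, makes the initial-value problem singular there; a
#' warning of class `degenerate_sutterby_factor` is emitted when the factor
#' passes within 1e-8 of zero on the converged mesh).
#'
#' The mesh default of 201 nodes balances truncation against rounding: the
#' five-point fourth-derivative stencil amplifies floating-point noise by
#' `1/h^4`, so very fine meshes raise the attainable residual floor.
#'
#' @param params a [flow_params()] set.
#' @param section a [cross_section()].
#' @param n_nodes number of mesh nodes.
#' @param tol convergence tolerance on the max-norm residual.
#' @param max_iter Newton iteration cap.
#' @param init initial iterate: `"hpm0"` (zeroth-order homotopy closed form,
#'   the default), `"hpm"` (assembled second-order homotopy solution), or a
#'   list with numeric `psi`, `theta`, `phi` on the mesh. On
#'   non-convergence from `"hpm0"` the solver automatically retries from
#'   `"hpm"` before failing.
#' @return an object of class `grid_solution`: mesh `eta`, nodal `psi`, `u`
#'   (axial velocity), `theta`, `phi`, and a `report` with convergence flag,
#'   iteration count, max residual and the minimum Sutterby factor.
#' @seealso [compare_solutions()]
#' @export
solve_numeric <- function(params, section, n_nodes = 201, tol = 1e-6,
                          max_iter = 40, init = "hpm0") {
  stopifnot(inherits(params, "sutterby_params"),
            inherits(section, "cross_section"))
  chk <- validate_params(params)
  if (!chk$valid)
    stop("invalid parameters: ", paste(chk$violations, collapse = "; "))

  state <- fd_initial_state(init, params, section, n_nodes)
  out <- fd_newton(state, params, section, n_nodes, tol, max_iter)
  if (!out$converged && identical(init, "hpm0")) {
    state <- fd_initial_state("hpm", params, section, n_nodes)
    out <- fd_newton(state, params, section, n_nodes, tol, max_iter)
  }
  if (!out$converged) {
    stop(structure(
      class = c("sutterby_nonconvergence", "error", "condition"),
      list(message = sprintf(
             paste0("finite-difference Newton solve did not converge: ",
                    "max residual %.3e after %d iterations on %d nodes ",
                    "(try a different initial iterate or a coarser mesh)"),
             out$max_residual, out$iterations, n_nodes),
           call = sys.call(-1))))
  }
  if (out$min_sutterby < 1e-8) {
    warning(structure(
      class = c("degenerate_sutterby_factor", "warning", "condition"),
      list(message = sprintf(
             "Sutterby factor 1 - beta_F*(psi'')^2 reaches %.3e on the converged mesh",
             out$min_sutterby),
           call = sys.call(-1))))
  }
  out$solution
}

fd_initial_state <- function(init, params, section, n_nodes) {
  eta <- seq(section$h1, section$h2, length.out = n_nodes)
  if (is.list(init)) {
    stopifnot(length(init$psi) == n_nodes, length(init$theta) == n_nodes,
              length(init$phi) == n_nodes)
    return(list(eta = eta, psi = init$psi, theta = init$theta, phi = init$phi))
  }
  if (identical(init, "ramps")) {
    ramp <- (eta - section$h1) / (section$h2 - section$h1)
    return(list(eta = eta, psi = section$F * (ramp - 0.5), theta = ramp,
                phi = ramp))
  }
  cfg <- hpm_config(order = if (identical(init, "hpm0")) 0 else 2)
  sol <- hpm_solve(params, section, cfg)
  list(eta = eta,
       psi = poly_eval(sol$psi, eta),
       theta = poly_eval(sol$theta, eta),
       phi = poly_eval(sol$phi, eta))
}

# difference operators on a uniform mesh; first-derivative boundary rows use
# 4-point one-sided stencils, exact for cubics, so the no-slip rows do not
# pollute the trivial closed-form limit
fd_operators <- function(n, h) {
  D1 <- matrix(0, n, n); D2 <- matrix(0, n, n); D4 <- matrix(0, n, n)
  for (i in 2:(n - 1)) {
    D1[i, c(i - 1, i + 1)] <- c(-1, 1) / (2 * h)
    D2[i, (i - 1):(i + 1)] <- c(1, -2, 1) / h^2
  }
  for (i in 3:(n - 2)) D4[i, (i - 2):(i + 2)] <- c(1, -4, 6, -4, 1) / h^4
  D1[1, 1:4] <- c(-11, 18, -9, 2) / (6 * h)
  D1[n, n:(n - 3)] <- -c(-11, 18, -9, 2) / (6 * h)
  list(D1 = D1, D2 = D2, D4 = D4)
}

# fourth-order first derivative for reported velocities (exact on cubics, so
# the decoupled closed-form limit is reproduced without stencil error); the
# Newton residuals themselves stay second order
fd_gradient4 <- function(f, h) {
  n <- length(f)
  g <- numeric(n)
  i <- 3:(n - 2)
  g[i] <- (f[i - 2] - 8 * f[i - 1] + 8 * f[i + 1] - f[i + 2]) / (12 * h)
  g[1] <- sum(c(-11, 18, -9, 2) * f[1:4]) / (6 * h)
  g[2] <- sum(c(-2, -3, 6, -1) * f[1:4]) / (6 * h)
  g[n - 1] <- -sum(c(-2, -3, 6, -1) * f[n:(n - 3)]) / (6 * h)
  g[n] <- -sum(c(-11, 18, -9, 2) * f[n:(n - 3)]) / (6 * h)
  g
}

fd_newton <- function(state, params, section, n, tol, max_iter) {
  h <- (section$h2 - section$h1) / (n - 1)
  op <- fd_operators(n, h)
  hc <- hall_coeffs(params)
  p <- params
  ratio <- nt_over_nb(p)
  Fq <- section$F

  residual <- function(psi, th, ph) {
    p1 <- op$D1 %*% psi; p2 <- op$D2 %*% psi; p4 <- op$D4 %*% psi
    t1 <- op$D1 %*% th; t2 <- op$D2 %*% th
    f1 <- op$D1 %*% ph; f2 <- op$D2 %*% ph
    S <- 1 - p$beta_F * p2^2
    Rp <- p4 * S - hc$momentum * p2 + p$G_R * t1 + p$G_C * f1
    Rt <- t2 / p$Pr + p$N_T * t1^2 + p$N_B * t1 * f1 +
      p$E_C * hc$joule * p1^2 + p$E_C * p2^2 * S
    Rf <- f2 + ratio * t2 - p$Sc * p$K_R * ph
    Rp[1] <- psi[1] + Fq / 2
    Rp[2] <- sum(op$D1[1, 1:4] * psi[1:4])
    Rp[n] <- psi[n] - Fq / 2
    Rp[n - 1] <- sum(op$D1[n, n:(n - 3)] * psi[n:(n - 3)])
    Rt[1] <- th[1]; Rt[n] <- th[n] - 1
    Rf[1] <- ph[1]; Rf[n] <- ph[n] - 1
    c(Rp, Rt, Rf)
  }

  jacobian <- function(psi, th, ph) {
    p1 <- c(op$D1 %*% psi); p2 <- c(op$D2 %*% psi); p4 <- c(op$D4 %*% psi)
    t1 <- c(op$D1 %*% th); f1 <- c(op$D1 %*% ph)
    S <- 1 - p$beta_F * p2^2
    Jpp <- S * op$D4 + (-2 * p$beta_F * p4 * p2 - hc$momentum) * op$D2
    Jtp <- (2 * p$E_C * hc$joule * p1) * op$D1 +
      (2 * p$E_C * p2 * S - 2 * p$E_C * p$beta_F * p2^3) * op$D2
    Jtt <- op$D2 / p$Pr + (2 * p$N_T * t1 + p$N_B * f1) * op$D1
    Jtf <- (p$N_B * t1) * op$D1
    J <- rbind(cbind(Jpp, p$G_R * op$D1, p$G_C * op$D1),
               cbind(Jtp, Jtt, Jtf),
               cbind(matrix(0, n, n), ratio * op$D2,
                     op$D2 - p$Sc * p$K_R * diag(n)))
    bc_rows <- c(1, 2, n - 1, n, n + 1, 2 * n, 2 * n + 1, 3 * n)
    J[bc_rows, ] <- 0
    J[1, 1] <- 1; J[n, n] <- 1
    J[2, 1:4] <- op$D1[1, 1:4]
    J[n - 1, n:(n - 3)] <- op$D1[n, n:(n - 3)]
    J[n + 1, n + 1] <- 1; J[2 * n, 2 * n] <- 1
    J[2 * n + 1, 2 * n + 1] <- 1; J[3 * n, 3 * n] <- 1
    J
  }

  psi <- state$psi; th <- state$theta; ph <- state$phi
  R <- residual(psi, th, ph)
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    if (max(abs(R)) < tol) { converged <- TRUE; break }
    it <- it + 1
    step <- tryCatch(solve(jacobian(psi, th, ph), -R),
                     error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    r0 <- max(abs(R))
    repeat {
      psi_n <- psi + lambda * step[1:n]
      th_n <- th + lambda * step[(n + 1):(2 * n)]
      ph_n <- ph + lambda * step[(2 * n + 1):(3 * n)]
      R_n <- residual(psi_n, th_n, ph_n)
      if (max(abs(R_n)) < r0 || lambda < 1 / 64) break
      lambda <- lambda / 2
    }
    if (max(abs(R_n)) >= r0) break  # stalled (residual floor reached)
    psi <- psi_n; th <- th_n; ph <- ph_n; R <- R_n
  }
  if (!converged && max(abs(R)) < tol) converged <- TRUE
  S <- 1 - params$beta_F * c(op$D2 %*% psi)^2
  sol <- structure(list(
    eta = state$eta, psi = psi, u = fd_gradient4(psi, h),
    theta = th, phi = ph,
    report = list(converged = converged, iterations = it,
                  max_residual = max(abs(R)),
                  min_sutterby = min(abs(S)))),
    class = "grid_solution")
  list(converged = converged, iterations = it, max_residual = max(abs(R)),
       min_sutterby = min(abs(S)), solution = sol)
}

#' Discrepancy between homotopy and finite-difference solutions
#'
#' Evaluates the assembled homotopy polynomials on the oracle mesh and
#' reports max-norm and L2 discrepancies for velocity, temperature and
#' concentration.
#'
#' @param hpm an [hpm_solve()] result.
#' @param num a [solve_numeric()] result on the same cross-section.
#' @return data.frame with columns `quantity`, `max_abs`, `l2`.
#' @export
compare_solutions <- function(hpm, num) {
  stopifnot(inherits(hpm, "hpm_solution"), inherits(num, "grid_solution"))
  eta <- num$eta
  w <- sqrt(diff(range(eta)) / length(eta))
  pairs <- list(
    u = list(poly_eval(poly_deriv(hpm$psi), eta), num$u),
    theta = list(poly_eval(hpm$theta, eta), num$theta),
    phi = list(poly_eval(hpm$phi, eta), num$phi))
  out <- do.call(rbind, lapply(names(pairs), function(q) {
    d <- pairs[[q]][[1]] - pairs[[q]][[2]]
    data.frame(quantity = q, max_abs = max(abs(d)),
               l2 = w * sqrt(sum(d^2)))
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.grid_solution <- function(x, ...) {
  cat(sprintf("<grid_solution> %d nodes on [%.4f, %.4f]\n",
              length(x$eta), min(x$eta), max(x$eta)))
  cat(sprintf("  converged = %s after %d iterations, max residual %.3e\n",
              x$report$converged, x$report$iterations, x$report$max_residual))
  invisible(x)
}
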