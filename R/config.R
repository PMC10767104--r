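#' Default run configuration
#'
#' Nested list of every tunable the tool exposes, pre-filled with the
#' baseline parameter values of the profile studies. Configuration files
#' (YAML, with JSON accepted) override any subset; unknown keys are rejected
#' with their full path.
#'
#' @export
default_config <- function() {
  list(
    params = unclass(flow_params()),
    geometry = list(a = 0.3, b = 0.3, m = 0.2, omega = pi / 2, Theta = 1.4,
                    xi = 0.4, t = 0.2),
    solver = list(order = 2, bc_allocation = "full_at_zeroth",
                  residual_grid_size = 201),
    oracle = list(n_nodes = 201, tol = 1e-6, max_iter = 40),
    observables = list(pressure_eval = "centre", nusselt_wall = "h2",
                       nusselt_negate = FALSE, quadrature_n = 64),
    ann = list(restarts = 20, max_iter = 200, lambda0 = 1e-3,
               lambda_factor = 10),
    output = list(dir = "."),
    seed = 1,
    log_level = "info"
  )
}

merge_config <- function(base, user, path = "") {
  for (key in names(user)) {
    here <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base))
      stop("unknown configuration key: ", here, call. = FALSE)
    if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      if (!is.list(user[[key]]))
        stop("configuration key ", here, " must be a mapping", call. = FALSE)
      base[[key]] <- merge_config(base[[key]], user[[key]], here)
    } else {
      base[[key]] <- parse_config_value(user[[key]], here)
    }
  }
  base
}

# angles may be written as "pi/3"-style fractions
parse_config_value <- function(x, key) {
  if (is.character(x) && length(x) == 1 &&
      grepl("^\\s*-?\\s*(\\d+\\s*\\*\\s*)?pi\\s*(/\\s*\\d+(\\.\\d+)?)?\\s*$", x)) {
    neg <- grepl("^\\s*-", x)
    body <- gsub("\\s|-", "", x)
    num <- if (grepl("\\*", body)) as.numeric(sub("\\*.*$", "", body)) else 1
    den <- if (grepl("/", body)) as.numeric(sub("^.*/", "", body)) else 1
    return((if (neg) -1 else 1) * num * pi / den)
  }
  x
}

#' Load and validate a run configuration
#'
#' @param path YAML or JSON file, or `NULL` for pure defaults.
#' @param overrides optional nested list applied after the file.
#' @return an object of class `run_config`.
#' @examples
#' cfg <- load_config()           # baseline defaults
#' cfg$params$Pr
#' @export
load_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("configuration file not found: ", path)
    user <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    if (!is.null(user)) cfg <- merge_config(cfg, user)
  }
  if (!is.null(overrides)) cfg <- merge_config(cfg, overrides)
  params <- do.call(flow_params, cfg$params)
  chk <- validate_params(params)
  if (!chk$valid)
    stop("invalid parameter block: ", paste(chk$violations, collapse = "; "))
  cfg$params <- unclass(params)
  structure(cfg, class = "run_config")
}

#' @rdname load_config
#' @param config a `run_config`.
#' @export
dump_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' Materialise the model objects described by a configuration
#'
#' @param config a `run_config`.
#' @return list with `params`, `geom`, `section`, `hpm_config`.
#' @export
config_objects <- function(config) {
  params <- do.call(flow_params, config$params)
  g <- config$geometry
  geom <- channel_geometry(a = g$a, b = g$b, m = g$m, omega = g$omega,
                           Theta = g$Theta)
  list(params = params, geom = geom,
       section = cross_section(g$xi, g$t, geom),
       hpm_config = do.call(hpm_config, config$solver))
}

#' Write run provenance next to outputs
#'
#' Every run directory records the resolved configuration, the seed, the
#' package version and the R version, so identical configurations rerun
#' bit-identically on the deterministic paths.
#'
#' @param dir output directory (created if missing).
#' @param config a `run_config`.
#' @export
write_run_metadata <- function(dir, config) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dump_config(config, file.path(dir, "resolved-config.yaml"))
  meta <- list(package = "sutterby",
               version = as.character(utils::packageVersion("sutterby")),
               r_version = R.version.string,
               seed = config$seed,
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(meta, file.path(dir, "run-metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Export a solved cross-section as a long-format table
#'
#' @param sol an [hpm_solve()] result.
#' @param n number of sample points.
#' @return data.frame with columns `eta`, `psi`, `u`, `theta`, `phi`.
#' @export
solution_profile <- function(sol, n = 201) {
  stopifnot(inherits(sol, "hpm_solution"))
  eta <- seq(sol$section$h1, sol$section$h2, length.out = n)
  data.frame(eta = eta,
             psi = poly_eval(sol$psi, eta),
             u = poly_eval(poly_deriv(sol$psi), eta),
             theta = poly_eval(sol$theta, eta),
             phi = poly_eval(sol$phi, eta))
}

#' JSON export of the per-order polynomial coefficients
#'
#' @param sol an [hpm_solve()] result.
#' @param path output file.
#' @export
solution_to_json <- function(sol, path) {
  stopifnot(inherits(sol, "hpm_solution"))
  payload <- list(
    section = sol$section[c("xi", "t", "h1", "h2", "F")],
    params = unclass(sol$params),
    order = sol$config$order,
    psi_orders = lapply(sol$psi_orders, poly_coeffs),
    theta_orders = lapply(sol$theta_orders, poly_coeffs),
    phi_orders = lapply(sol$phi_orders, poly_coeffs),
    psi = poly_coeffs(sol$psi),
    theta = poly_coeffs(sol$theta),
    phi = poly_coeffs(sol$phi),
    residuals = as.list(sol$residuals))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# printed reference coefficients of the assembled series at the fixed
# parameter case (ascending powers); the phi series is typeset identically to
# psi in the source -- an evident copy error -- and is not used as a fixture
printed_series_coefficients <- function() {
  list(
    psi = c(-0.0557051150073254246, 1.03368242276481737, 0.0392845599708364080,
            -0.163720970462385013, -0.00372810735110439993,
            -0.00590205595371576415, -0.000437344682700783270,
            -0.00159526762663897188, 0.000000700415712498828533,
            -0.000002507211831),
    theta = c(0.935680222799999960, 0.322176649299999951, -0.271312562400000179,
              0.0409078656200000668, -0.00966402786900004418,
              -0.00254884465199998892, 0.00793300027099999930,
              -0.0000699205341099992380, 0.001738482617))
}

#' Run every published-value fixture and report achieved vs printed
#'
#' Recomputes the printed series coefficients under the taper readings
#' (m = 0.2 and m = 0) and both boundary-condition allocations, and sweeps
#' the Nusselt conventions (wall, sign, taper, phase) against the first
#' tabulated row. The report records which variant matches each fixture best
#' and, separately for the Nusselt table, which convention reproduces the
#' table's qualitative column trends -- the two need not coincide.
#'
#' @param quiet suppress printing.
#' @return list with data.frames `series` and `nusselt_sweep`, plus
#'   `best_nusselt` (value-closest convention), `trend_consistent`
#'   (conventions matching the table's N_T and N_B column directions) and
#'   `elapsed` seconds.
#' @export
run_fixture_suite <- function(quiet = FALSE) {
  t0 <- Sys.time()
  ref <- printed_series_coefficients()
  case <- printed_series_case()

  variants <- expand.grid(m = c(0.2, 0),
                          bc = c("full_at_zeroth", "split"),
                          stringsAsFactors = FALSE)
  series <- do.call(rbind, lapply(seq_len(nrow(variants)), function(i) {
    geom <- channel_geometry(a = 0.3, b = 0.3, m = variants$m[i],
                             omega = pi / 3, Theta = 1.4)
    sol <- hpm_solve(case$params, cross_section(0.4, 0.2, geom),
                     hpm_config(bc_allocation = variants$bc[i]))
    th <- poly_coeffs(sol$theta); ps <- poly_coeffs(sol$psi)
    data.frame(m = variants$m[i], bc_allocation = variants$bc[i],
               coefficient = c("theta_const", "theta_eta", "psi_const", "psi_eta"),
               printed = c(ref$theta[1], ref$theta[2], ref$psi[1], ref$psi[2]),
               computed = c(th[1], th[2], ps[1], ps[2]))
  }))
  series$rel_error <- abs(series$computed - series$printed) / abs(series$printed)

  tab <- nusselt_table()
  row1 <- tab[1, ]
  conv <- expand.grid(wall = c("h2", "h1"), negate = c(FALSE, TRUE),
                      m = c(0.2, 0), omega = c(pi / 2, pi / 3),
                      stringsAsFactors = FALSE)
  nusweep <- do.call(rbind, lapply(seq_len(nrow(conv)), function(i) {
    geom <- channel_geometry(m = conv$m[i], omega = conv$omega[i])
    p1 <- flow_params(N_T = row1$N_T, N_B = row1$N_B, M = row1$M,
                      beta_e = row1$beta_e, beta_i = row1$beta_i,
                      beta_F = row1$beta_F)
    nu_fun <- function(pp) nusselt(pp, geom, 0.4, 0.2, wall = conv$wall[i],
                                   negate = conv$negate[i])
    nu1 <- nu_fun(p1)
    # trend checks along the table's N_T and N_B columns
    nu_nt <- vapply(c(1.5, 2, 2.5), function(v)
      nu_fun(flow_params(N_T = v, N_B = 0.5, M = 1, beta_e = 0.1,
                         beta_i = 0.1, beta_F = 1)), numeric(1))
    nu_nb <- vapply(c(1, 1.5, 2), function(v)
      nu_fun(flow_params(N_T = 1, N_B = v, M = 1, beta_e = 0.1,
                         beta_i = 0.1, beta_F = 1)), numeric(1))
    data.frame(conv[i, , drop = FALSE],
               Nu = nu1, printed = row1$Nu,
               abs_error = abs(nu1 - row1$Nu),
               nt_decreasing = all(diff(nu_nt) < 0),
               nb_decreasing = all(diff(nu_nb) < 0))
  }))
  rownames(nusweep) <- NULL

  best_row <- nusweep[which.min(nusweep$abs_error), ]
  trend_rows <- nusweep[nusweep$nt_decreasing & nusweep$nb_decreasing, ]
  elapsed <- as.numeric(Sys.time() - t0, units = "secs")

  if (!quiet) {
    cat("Printed-series fixtures (achieved vs printed):\n")
    print(series[order(series$rel_error), ], digits = 9, row.names = FALSE)
    cat("\nNusselt convention sweep against tabulated row 1 (printed ",
        format(row1$Nu), "):\n", sep = "")
    print(nusweep[order(nusweep$abs_error), ], digits = 6, row.names = FALSE)
    cat(sprintf("\nValue-closest convention: wall=%s negate=%s m=%g omega=%.4f (|err| = %.4f)\n",
                best_row$wall, best_row$negate, best_row$m, best_row$omega,
                best_row$abs_error))
    if (nrow(trend_rows)) {
      cat("Trend-consistent conventions (Nu decreasing in both N_T and N_B):\n")
      print(trend_rows[, c("wall", "negate", "m", "omega")], row.names = FALSE)
    } else {
      cat("No convention reproduces the table's column trends.\n")
    }
    cat(sprintf("Elapsed: %.1f s\n", elapsed))
  }
  invisible(list(series = series, nusselt_sweep = nusweep,
                 best_nusselt = best_row, trend_consistent = trend_rows,
                 elapsed = elapsed))
}
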