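#' Tabulated Nusselt values
#'
#' The published table of wall heat-transfer rates: one row per parameter
#' variation (six inputs `N_T`, `N_B`, `M`, `beta_e`, `beta_i`, `beta_F`),
#' the reported `Nu`, the reported network prediction `ANN` and their
#' difference `Error`. Although described in the source as 17 rows, the
#' table body carries 18 (six parameters at three off-baseline levels each);
#' the parse is verified row-wise by `Nu - ANN = Error`.
#'
#' @return data.frame with 18 rows.
#' @export
nusselt_table <- function() {
  path <- system.file("extdata", "table1_nusselt.csv", package = "sutterby",
                      mustWork = TRUE)
  utils::read.csv(path)
}

#' Min-max feature scaling to [-1, 1]
#'
#' @param x numeric matrix (columns = features) or vector.
#' @return a `minmax_scaler`: per-column minimum and maximum. Constant
#'   columns map to 0.
#' @export
minmax_scaler <- function(x) {
  x <- as.matrix(x)
  structure(list(min = apply(x, 2, min), max = apply(x, 2, max)),
            class = "minmax_scaler")
}

#' @rdname minmax_scaler
#' @param scaler a `minmax_scaler`.
#' @export
scaler_transform <- function(scaler, x) {
  x <- as.matrix(x)
  span <- scaler$max - scaler$min
  span[span == 0] <- 1
  out <- sweep(sweep(x, 2, scaler$min), 2, span / 2, "/") - 1
  out[, span == 0] <- 0
  out
}

#' @rdname minmax_scaler
#' @export
scaler_invert <- function(scaler, x) {
  x <- as.matrix(x)
  span <- scaler$max - scaler$min
  sweep(sweep((x + 1), 2, span / 2, "*"), 2, scaler$min, "+")
}

SURROGATE_FEATURES <- c("N_T", "N_B", "M", "beta_e", "beta_i", "beta_F")

#' Dataset container for the Nusselt surrogate
#'
#' Scales the six features and the target to `[-1, 1]` and assigns each row
#' to the train/validation/test split (0.70/0.15/0.15, uniformly at random
#' under the stored seed, up to one-row rounding).
#'
#' @param features matrix or data.frame with columns `N_T`, `N_B`, `M`,
#'   `beta_e`, `beta_i`, `beta_F`.
#' @param target numeric vector of Nusselt values.
#' @param seed split seed.
#' @param fractions length-3 split fractions summing to 1.
#' @export
surrogate_dataset <- function(features, target, seed = 1,
                              fractions = c(0.70, 0.15, 0.15)) {
  X <- as.matrix(as.data.frame(features)[, SURROGATE_FEATURES])
  y <- as.numeric(target)
  stopifnot(nrow(X) == length(y), abs(sum(fractions) - 1) < 1e-12)
  n <- nrow(X)
  n_train <- round(fractions[1] * n)
  n_val <- round(fractions[2] * n)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  perm <- sample.int(n)
  split <- character(n)
  split[perm[seq_len(n_train)]] <- "train"
  split[perm[n_train + seq_len(min(n_val, n - n_train))]] <- "val"
  split[split == ""] <- "test"
  xs <- minmax_scaler(X)
  ys <- minmax_scaler(matrix(y, ncol = 1))
  structure(list(X = X, y = y,
                 Xs = scaler_transform(xs, X),
                 ys = c(scaler_transform(ys, matrix(y, ncol = 1))),
                 xscaler = xs, yscaler = ys,
                 split = factor(split, levels = c("train", "val", "test")),
                 seed = seed),
            class = "surrogate_dataset")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Build a surrogate dataset by running the solver over a parameter grid
#'
#' One row per point of the full factorial grid; the target is
#' [nusselt()] computed under the configured convention with all remaining
#' parameters held at `params`. Solver errors abort with the offending grid
#' point named.
#'
#' @param levels named list of numeric level vectors for any subset of the
#'   six surrogate features; defaults are 3 levels per parameter spanning the
#'   tabulated study ranges.
#' @param params baseline [flow_params()] supplying the non-varied groups.
#' @param geom a [channel_geometry()].
#' @param xi,t station.
#' @param wall,negate Nusselt convention, see [nusselt()].
#' @param config an [hpm_config()].
#' @param seed split seed handed to [surrogate_dataset()].
#' @export
generate_dataset <- function(levels = NULL, params = baseline_params(),
                             geom = channel_geometry(), xi = 0.4, t = 0.2,
                             wall = "h2", negate = FALSE,
                             config = hpm_config(), seed = 1) {
  defaults <- list(N_T = c(0.5, 1, 1.5), N_B = c(0.5, 1, 1.5),
                   M = c(1, 1.5, 2), beta_e = c(0.1, 1, 2),
                   beta_i = c(0.1, 1, 2), beta_F = c(0, 1, 2))
  if (!is.null(levels)) {
    unknown <- setdiff(names(levels), SURROGATE_FEATURES)
    if (length(unknown)) stop("unknown grid parameter(s): ",
                              paste(unknown, collapse = ", "))
    defaults[names(levels)] <- levels
  }
  grid <- do.call(expand.grid, c(defaults[SURROGATE_FEATURES],
                                 KEEP.OUT.ATTRS = FALSE))
  y <- vapply(seq_len(nrow(grid)), function(i) {
    row <- grid[i, ]
    p_i <- do.call(flow_params, utils::modifyList(unclass(params), as.list(row)))
    tryCatch(nusselt(p_i, geom, xi, t, wall = wall, negate = negate,
                     config = config),
             error = function(e) stop("solver failed at grid point ",
                                      paste(names(row), unlist(row), sep = "=",
                                            collapse = ", "), ": ",
                                      conditionMessage(e), call. = FALSE))
  }, numeric(1))
  surrogate_dataset(grid, y, seed = seed)
}

#' The tabulated rows as a surrogate dataset
#'
#' @inheritParams surrogate_dataset
#' @export
table_dataset <- function(seed = 1, fractions = c(0.70, 0.15, 0.15)) {
  tab <- nusselt_table()
  surrogate_dataset(tab[, SURROGATE_FEATURES], tab$Nu, seed = seed,
                    fractions = fractions)
}

N_HIDDEN <- 5L
N_WEIGHTS <- 6L * N_HIDDEN + N_HIDDEN + N_HIDDEN + 1L  # 41

mlp_unpack <- function(w) {
  list(W1 = matrix(w[1:30], 6, N_HIDDEN),
       b1 = w[31:35], w2 = w[36:40], b2 = w[41])
}

mlp_forward <- function(w, X) {
  p <- mlp_unpack(w)
  H <- tanh(sweep(X %*% p$W1, 2, p$b1, "+"))
  c(H %*% p$w2 + p$b2)
}

# Jacobian of network outputs with respect to all 41 weights
mlp_jacobian <- function(w, X) {
  p <- mlp_unpack(w)
  A <- sweep(X %*% p$W1, 2, p$b1, "+")
  H <- tanh(A)
  dH <- 1 - H^2
  J <- matrix(0, nrow(X), N_WEIGHTS)
  for (j in seq_len(N_HIDDEN)) {
    cols <- (j - 1L) * 6L + 1:6
    J[, cols] <- (p$w2[j] * dH[, j]) * X
    J[, 30L + j] <- p$w2[j] * dH[, j]
  }
  J[, 36:40] <- H
  J[, 41] <- 1
  J
}

lm_fit_once <- function(X, y, w0, max_iter, lambda0, lambda_factor) {
  w <- w0
  lambda <- lambda0
  r <- mlp_forward(w, X) - y
  sse <- sum(r^2)
  sse_trace <- sse
  lambda_trace <- lambda
  iters <- 0L
  for (it in seq_len(max_iter)) {
    J <- mlp_jacobian(w, X)
    g <- crossprod(J, r)
    A <- crossprod(J)
    accepted <- FALSE
    repeat {
      step <- tryCatch(solve(A + lambda * diag(N_WEIGHTS), -g),
                       error = function(e) NULL)
      if (!is.null(step)) {
        w_n <- w + c(step)
        r_n <- mlp_forward(w_n, X) - y
        if (sum(r_n^2) < sse) {
          w <- w_n; r <- r_n; sse <- sum(r_n^2)
          lambda <- lambda / lambda_factor
          accepted <- TRUE
          break
        }
      }
      lambda <- lambda * lambda_factor  # singular or rejected: damp harder
      if (lambda > 1e12) break
    }
    if (!accepted) break
    iters <- it
    sse_trace <- c(sse_trace, sse)
    lambda_trace <- c(lambda_trace, lambda)
    if (sse < 1e-28) break
  }
  list(w = w, sse = sse, sse_trace = sse_trace, lambda_trace = lambda_trace,
       iterations = iters, converged = sse < 1e-28 || iters < max_iter)
}

#' Train the 6-5-1 Nusselt surrogate by Levenberg-Marquardt
#'
#' A single hidden layer of five tanh neurons and a linear output (41
#' weights) is fitted to the scaled training split by damped Gauss-Newton:
#' the damping factor is divided by `lambda_factor` on every accepted step
#' and multiplied on every rejected or singular one, so the accepted-step
#' training error never increases. The best of `restarts` random
#' initialisations (child seeds drawn deterministically from `seed`) is
#' returned, selected by training SSE with validation MSE as tie-breaker.
#'
#' @param data a [surrogate_dataset()].
#' @param seed master seed for the restart initialisations.
#' @param restarts number of random restarts.
#' @param max_iter Levenberg-Marquardt iteration cap per restart.
#' @param lambda0 initial damping factor.
#' @param lambda_factor damping multiplier/divisor.
#' @return list with `model` (class `mlp_surrogate`) and `report` (class
#'   `lm_train_report`): accepted-step SSE trace, damping trajectory,
#'   per-split MSE on the original Nusselt scale, best restart index and
#'   seeds.
#' @export
train_lm <- function(data, seed = 1, restarts = 20, max_iter = 200,
                     lambda0 = 1e-3, lambda_factor = 10) {
  stopifnot(inherits(data, "surrogate_dataset"))
  tr <- data$split == "train"
  if (sum(tr) < 10) stop("need at least 10 training rows, got ", sum(tr))
  X <- data$Xs[tr, , drop = FALSE]
  y <- data$ys[tr]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  child_seeds <- sample.int(.Machine$integer.max - 1L, restarts)
  fits <- vector("list", restarts)
  for (i in seq_len(restarts)) {
    set.seed(child_seeds[i])
    w0 <- stats::runif(N_WEIGHTS, -0.5, 0.5)
    fits[[i]] <- lm_fit_once(X, y, w0, max_iter, lambda0, lambda_factor)
  }
  best <- which.min(vapply(fits, `[[`, numeric(1), "sse"))
  fit <- fits[[best]]
  model <- structure(c(mlp_unpack(fit$w),
                       list(weights = fit$w, xscaler = data$xscaler,
                            yscaler = data$yscaler,
                            feature_names = SURROGATE_FEATURES,
                            train_box = list(min = data$xscaler$min,
                                             max = data$xscaler$max))),
                     class = "mlp_surrogate")
  mse <- split_mse(model, data)
  report <- structure(list(sse_trace = fit$sse_trace,
                           lambda_trace = fit$lambda_trace,
                           iterations = fit$iterations,
                           converged = fit$converged,
                           mse = mse,
                           restart_sse = vapply(fits, `[[`, numeric(1), "sse"),
                           best_restart = best,
                           seed = seed, child_seeds = child_seeds),
                      class = "lm_train_report")
  list(model = model, report = report)
}

#' Predict Nusselt values from the trained surrogate
#'
#' @param object an `mlp_surrogate`.
#' @param newdata matrix or data.frame with the six feature columns.
#' @param ... unused.
#' @return numeric vector on the original Nusselt scale. Inputs outside the
#'   training box trigger an extrapolation warning.
#' @export
predict.mlp_surrogate <- function(object, newdata, ...) {
  X <- as.matrix(as.data.frame(newdata)[, object$feature_names, drop = FALSE])
  lo <- object$train_box$min; hi <- object$train_box$max
  span <- pmax(hi - lo, .Machine$double.eps)
  if (any(t(X) < lo - 0.05 * span) || any(t(X) > hi + 0.05 * span))
    warning("predicting outside the training box (extrapolation)",
            call. = FALSE)
  ys <- mlp_forward(object$weights, scaler_transform(object$xscaler, X))
  c(scaler_invert(object$yscaler, matrix(ys, ncol = 1)))
}

split_mse <- function(model, data) {
  pred <- suppressWarnings(predict(model, data$X))
  err <- data$y - pred
  out <- vapply(levels(data$split), function(s) {
    idx <- data$split == s
    if (!any(idx)) NA_real_ else mean(err[idx]^2)
  }, numeric(1))
  c(out, all = mean(err^2))
}

#' Evaluate the surrogate against a dataset
#'
#' @param model an `mlp_surrogate`.
#' @param data a [surrogate_dataset()].
#' @return list with `mse` (per split and pooled, original scale) and
#'   `table`, a per-row error table mirroring the published layout: the six
#'   inputs, the target `Nu`, the prediction `ANN` and `Error = Nu - ANN`.
#' @export
evaluate_surrogate <- function(model, data) {
  stopifnot(inherits(model, "mlp_surrogate"),
            inherits(data, "surrogate_dataset"))
  pred <- suppressWarnings(predict(model, data$X))
  tab <- as.data.frame(data$X)
  tab$Nu <- data$y
  tab$ANN <- pred
  tab$Error <- tab$Nu - tab$ANN
  tab$split <- data$split
  list(mse = split_mse(model, data), table = tab)
}

#' @export
print.lm_train_report <- function(x, ...) {
  cat("<lm_train_report>\n")
  cat(sprintf("  best restart %d/%d, %d accepted steps, final train SSE %.3e\n",
              x$best_restart, length(x$restart_sse), x$iterations,
              utils::tail(x$sse_trace, 1)))
  cat("  MSE (original scale):",
      paste(names(x$mse), format(x$mse, digits = 4), sep = " = ",
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.mlp_surrogate <- function(x, ...) {
  cat("<mlp_surrogate> 6-5-1 tanh/linear network,",
      length(x$weights), "weights\n")
  invisible(x)
}
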