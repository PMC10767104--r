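#' Polynomials in the cross-channel coordinate
#'
#' The homotopy perturbation cascade works entirely on polynomials in the
#' wall-normal coordinate eta. An `eta_poly` stores the coefficient sequence
#' in ascending powers (`coeffs[k]` multiplies `eta^(k-1)`). Addition,
#' multiplication, differentiation and antidifferentiation act exactly on the
#' coefficients -- there is no truncation anywhere in the cascade -- and
#' evaluation uses Horner's scheme.
#'
#' @param coeffs numeric vector of coefficients, ascending powers of eta.
#' @return an object of class `eta_poly`.
#' @examples
#' p <- eta_poly(c(0, 1.5, 0, -0.5))  # (3*eta - eta^3)/2
#' poly_eval(p, c(-1, 0, 1))
#' poly_degree(poly_deriv(p, 2))
#' @export
eta_poly <- function(coeffs = 0) {
  coeffs <- as.numeric(coeffs)
  if (length(coeffs) == 0L) coeffs <- 0
  if (any(!is.finite(coeffs))) stop("polynomial coefficients must be finite")
  structure(coeffs, class = "eta_poly")
}

#' @rdname eta_poly
#' @param x numeric vector or `eta_poly`.
#' @export
as_eta_poly <- function(x) {
  if (inherits(x, "eta_poly")) x else eta_poly(x)
}

#' @rdname eta_poly
#' @export
is_eta_poly <- function(x) inherits(x, "eta_poly")

#' @rdname eta_poly
#' @export
poly_coeffs <- function(x) as.numeric(unclass(as_eta_poly(x)))

#' Degree of a polynomial
#'
#' Trailing zero coefficients are ignored, so the degree is that of the
#' highest power with a nonzero coefficient (the zero polynomial has degree 0).
#'
#' @param x an `eta_poly` or coefficient vector.
#' @param tol coefficients with absolute value at or below `tol` count as zero.
#' @export
poly_degree <- function(x, tol = 0) {
  cf <- poly_coeffs(x)
  nz <- which(abs(cf) > tol)
  if (length(nz) == 0L) 0L else max(nz) - 1L
}

#' @rdname poly_degree
#' @export
poly_trim <- function(x, tol = 0) {
  cf <- poly_coeffs(x)
  eta_poly(cf[seq_len(poly_degree(cf, tol) + 1L)])
}

#' Evaluate a polynomial (Horner's scheme)
#'
#' @param x an `eta_poly` or coefficient vector.
#' @param eta numeric vector of evaluation points.
#' @export
poly_eval <- function(x, eta) {
  cf <- poly_coeffs(x)
  out <- rep(0, length(eta))
  for (c_k in rev(cf)) out <- out * eta + c_k
  out
}

#' Differentiate or antidifferentiate a polynomial
#'
#' Both operations are exact on the coefficient representation.
#' `poly_antideriv` takes the antiderivative with zero constant of
#' integration; integration constants are handled by the boundary-value
#' solver, not here.
#'
#' @param x an `eta_poly` or coefficient vector.
#' @param n number of times to apply the operation.
#' @export
poly_deriv <- function(x, n = 1) {
  cf <- poly_coeffs(x)
  for (i in seq_len(n)) {
    cf <- if (length(cf) <= 1L) 0 else cf[-1L] * seq_len(length(cf) - 1L)
  }
  eta_poly(cf)
}

#' @rdname poly_deriv
#' @export
poly_antideriv <- function(x, n = 1) {
  cf <- poly_coeffs(x)
  for (i in seq_len(n)) cf <- c(0, cf / seq_along(cf))
  eta_poly(cf)
}

pad_coeffs <- function(cf, n) {
  length(cf) <- n
  cf[is.na(cf)] <- 0
  cf
}

#' @export
Ops.eta_poly <- function(e1, e2) {
  if (missing(e2)) {
    if (.Generic == "-") return(eta_poly(-poly_coeffs(e1)))
    if (.Generic == "+") return(as_eta_poly(e1))
    stop("unary '", .Generic, "' not defined for eta_poly")
  }
  a <- poly_coeffs(e1)
  b <- poly_coeffs(e2)
  scalar1 <- !is_eta_poly(e1) && length(a) == 1L
  scalar2 <- !is_eta_poly(e2) && length(b) == 1L
  switch(.Generic,
    "+" = {
      n <- max(length(a), length(b))
      eta_poly(pad_coeffs(a, n) + pad_coeffs(b, n))
    },
    "-" = {
      n <- max(length(a), length(b))
      eta_poly(pad_coeffs(a, n) - pad_coeffs(b, n))
    },
    "*" = {
      if (scalar1) return(eta_poly(a * b))
      if (scalar2) return(eta_poly(a * b))
      out <- numeric(length(a) + length(b) - 1L)
      for (i in seq_along(a)) {
        idx <- i:(i + length(b) - 1L)
        out[idx] <- out[idx] + a[i] * b
      }
      eta_poly(out)
    },
    stop("'", .Generic, "' not defined for eta_poly")
  )
}

#' @export
print.eta_poly <- function(x, digits = 6, ...) {
  cf <- poly_coeffs(poly_trim(x))
  deg <- length(cf) - 1L
  terms <- vapply(seq_along(cf), function(i) {
    pw <- i - 1L
    if (cf[i] == 0 && deg > 0) return(NA_character_)
    val <- format(cf[i], digits = digits)
    if (pw == 0) val
    else if (pw == 1) paste0(val, "*eta")
    else paste0(val, "*eta^", pw)
  }, character(1))
  terms <- terms[!is.na(terms)]
  cat("<eta_poly degree ", deg, ">\n  ", paste(terms, collapse = " + "), "\n", sep = "")
  invisible(x)
}
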