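#' Polynomial coefficient sets for spherical contact
#'
#' The exact spherical (Sneddon) contact solution relates force and depth only
#' parametrically through the contact radius. Expanding the contact radius as
#' \deqn{r_c/R = c_1 (h/R)^{1/2} + c_2 (h/R) + c_3 (h/R)^2 + \dots +
#'   c_N (h/R)^{N-1}}
#' gives a closed-form force-depth law valid up to a maximum depth-to-radius
#' ratio. Two fitted sets are in routine use: a three-term set valid for
#' \eqn{h_{max}/R \le 1.32} and a six-term set valid for
#' \eqn{h_{max}/R \le 4.9512} (i.e. essentially any practical indentation).
#'
#' @param set Which built-in set: `"N6"` (default, valid to h/R = 4.9512) or
#'   `"N3"` (valid to h/R = 1.32).
#' @return An object of class `coef_set`: a list with elements `name`, `N`
#'   (number of terms), `c` (numeric vector of coefficients c1..cN) and
#'   `domain_max` (upper validity bound on h/R).
#' @seealso [fit_coefficient_set()] to refit a set for a custom domain.
#' @examples
#' afm_coefs("N3")
#' @export
afm_coefs <- function(set = c("N6", "N3")) {
  set <- match.arg(set)
  .builtin_coefs[[set]]
}

.builtin_coefs <- list(
  N3 = structure(list(
    name = "N3",
    N = 3L,
    c = c(1.022, -0.1133, -0.0742),
    domain_max = 1.32
  ), class = "coef_set"),
  N6 = structure(list(
    name = "N6",
    N = 6L,
    c = c(1.0100000, -0.0730300, -0.1357000, 0.0359800, -0.0040240, 0.0001653),
    domain_max = 4.9512
  ), class = "coef_set")
)

#' Construct a coefficient set
#'
#' Low-level constructor with validity checks; most users want [afm_coefs()]
#' or [fit_coefficient_set()].
#'
#' @param coefficients Numeric vector c1..cN, N >= 2, c1 > 0.
#' @param domain_max Upper validity bound on h/R (> 0).
#' @param name Identifier used in messages and calibration reports.
#' @return A `coef_set` object.
#' @export
coef_set <- function(coefficients, domain_max, name = "custom") {
  coefficients <- as.numeric(coefficients)
  if (length(coefficients) < 2L)
    stop("a coefficient set needs at least 2 terms", call. = FALSE)
  if (!all(is.finite(coefficients)))
    stop("coefficients must be finite", call. = FALSE)
  if (coefficients[1L] <= 0)
    stop("c1 must be positive", call. = FALSE)
  if (!is.numeric(domain_max) || length(domain_max) != 1L || domain_max <= 0)
    stop("'domain_max' must be a single positive number", call. = FALSE)
  structure(list(
    name = as.character(name)[1L],
    N = length(coefficients),
    c = coefficients,
    domain_max = as.numeric(domain_max)
  ), class = "coef_set")
}

#' @export
print.coef_set <- function(x, ...) {
  cat("Spherical-contact coefficient set '", x$name, "'\n", sep = "")
  cat("  terms:  N =", x$N, "\n")
  cat("  c:     ", paste(format(x$c, digits = 7), collapse = ", "), "\n")
  cat("  valid for h/R <=", format(x$domain_max), "\n")
  invisible(x)
}

as_coef_set <- function(coefs) {
  if (inherits(coefs, "coef_set")) return(coefs)
  if (is.character(coefs) && length(coefs) == 1L) return(afm_coefs(coefs))
  stop("'coefs' must be a coef_set object, \"N3\" or \"N6\"", call. = FALSE)
}

check_domain <- function(ratio, coefs, what = "h/R", slack = 1e-9) {
  bad <- ratio > coefs$domain_max * (1 + slack)
  if (any(bad, na.rm = TRUE))
    stop(sprintf(
      "%s = %.4g exceeds the validity bound %.5g of coefficient set '%s'%s",
      what, max(ratio[bad]), coefs$domain_max, coefs$name,
      if (identical(coefs$name, "N3")) "; consider the N6 set" else ""),
      call. = FALSE)
  invisible(TRUE)
}

#' Refit contact-radius expansion coefficients
#'
#' Samples the exact parametric depth relation [sneddon_depth()] on a dense
#' grid of contact radii and least-squares fits the basis
#' \eqn{\{(h/R)^{1/2}, (h/R), (h/R)^2, \dots, (h/R)^{N-1}\}} to
#' \eqn{r_c/R}. The built-in sets returned by [afm_coefs()] are the
#' authoritative defaults; refitting serves validation and custom domains.
#'
#' @param domain_max Upper bound on h/R the fit should cover.
#' @param N Number of terms (>= 2).
#' @param n_grid Number of evenly spaced contact-radius samples (default 2000).
#' @return A `coef_set` with attributes `max_residual` (largest absolute
#'   rc/R residual on the fitting grid) and `condition` (condition number of
#'   the design matrix, a diagnostic for ill-conditioned high-order bases).
#' @examples
#' fit_coefficient_set(1.32, 3)
#' @export
fit_coefficient_set <- function(domain_max, N, n_grid = 2000L) {
  if (!is.numeric(domain_max) || domain_max <= 0)
    stop("'domain_max' must be positive", call. = FALSE)
  N <- as.integer(N)
  if (N < 2L) stop("'N' must be at least 2", call. = FALSE)
  # contact-radius bound whose depth reaches domain_max
  t_max <- stats::uniroot(
    function(t) 0.5 * t * log((1 + t) / (1 - t)) - domain_max,
    c(1e-12, 1 - 1e-12), tol = 1e-15)$root
  t <- seq(1e-6, t_max, length.out = n_grid)
  u <- 0.5 * t * log((1 + t) / (1 - t))  # h/R
  X <- vapply(seq_len(N),
              function(k) if (k == 1L) sqrt(u) else u^(k - 1L),
              numeric(length(u)))
  kappa <- kappa(X, exact = FALSE)
  cf <- qr.coef(qr(X), t)
  out <- coef_set(cf, domain_max,
                  name = sprintf("fit-N%d-%.4g", N, domain_max))
  attr(out, "max_residual") <- max(abs(X %*% cf - t))
  attr(out, "condition") <- kappa
  out
}
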