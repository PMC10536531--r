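#' Sample and indenter description
#'
#' Bundles the elastic parameters of a spherical indentation problem and
#' derives the reduced modulus \eqn{E^* = E/(1-\nu^2)} (rigid indenter on an
#' elastic half-space).
#'
#' @param E Young's modulus of the sample, Pa (> 0).
#' @param v Poisson ratio, in \[0, 0.5\]; 0.5 (incompressible) is typical for
#'   hydrated biological samples.
#' @param R Tip radius, m (> 0).
#' @return A `contact_params` list with elements `E`, `v`, `R`, `E_star`.
#' @examples
#' contact_params(E = 100e3, v = 0.5, R = 1e-6)
#' @export
contact_params <- function(E, v = 0.5, R) {
  if (!is.numeric(E) || length(E) != 1L || !is.finite(E) || E <= 0)
    stop("'E' must be a single positive number (Pa)", call. = FALSE)
  if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 0.5)
    stop("'v' must be in [0, 0.5]", call. = FALSE)
  if (!is.numeric(R) || length(R) != 1L || !is.finite(R) || R <= 0)
    stop("'R' must be a single positive number (m)", call. = FALSE)
  structure(list(E = E, v = v, R = R, E_star = E / (1 - v^2)),
            class = "contact_params")
}

#' @export
print.contact_params <- function(x, ...) {
  cat(sprintf("Contact parameters: E = %.4g Pa, v = %.3g, R = %.4g m (E* = %.4g Pa)\n",
              x$E, x$v, x$R, x$E_star))
  invisible(x)
}

#' Exact spherical indentation depth from contact radius
#'
#' The parametric Sneddon solution for a rigid sphere gives the indentation
#' depth as \eqn{h = (r_c/2)\,\ln[(R + r_c)/(R - r_c)]}, where \eqn{r_c} is
#' the contact radius. The relation is continuous and strictly increasing in
#' `rc`, with `h -> 0` as `rc -> 0` and a logarithmic singularity at
#' `rc = R`.
#'
#' @param rc Contact radius, m; `0 <= rc < R`. Vectorized.
#' @param R Tip radius, m.
#' @return Indentation depth h, m.
#' @seealso [sneddon_contact_radius()] for the numerical inverse.
#' @export
sneddon_depth <- function(rc, R) {
  if (any(rc < 0)) stop("'rc' must be non-negative", call. = FALSE)
  if (any(rc >= R))
    stop("'rc' must be smaller than the tip radius R (logarithm singularity at rc = R)",
         call. = FALSE)
  ifelse(rc == 0, 0, (rc / 2) * log((R + rc) / (R - rc)))
}

#' Contact radius from indentation depth (numerical inversion)
#'
#' Inverts the parametric depth relation by a bracketed root search on
#' \eqn{r_c/R \in [0, 1)}; monotone in `h`, so the bracket is safe. The
#' contact radius approaches (never reaches) the tip radius as depth grows.
#'
#' @param h Indentation depth, m (>= 0). Vectorized.
#' @param R Tip radius, m (> 0).
#' @param tol Relative solver tolerance on rc/R.
#' @return Contact radius, m.
#' @export
sneddon_contact_radius <- function(h, R, tol = 1e-12) {
  if (any(h < 0)) stop("'h' must be non-negative", call. = FALSE)
  if (!is.numeric(R) || R <= 0) stop("'R' must be positive", call. = FALSE)
  u <- h / R
  one <- function(ui) {
    if (ui == 0) return(0)
    stats::uniroot(function(t) 0.5 * t * log((1 + t) / (1 - t)) - ui,
                   lower = 1e-16, upper = 1 - 1e-12, tol = tol)$root
  }
  R * vapply(u, one, numeric(1))
}

#' Exact spherical (Sneddon) indentation force
#'
#' Evaluates the exact rigid-sphere force
#' \deqn{F = \frac{E}{2(1-\nu^2)}\left[(r_c^2 + R^2)\,
#'   \ln\frac{R + r_c}{R - r_c} - 2 r_c R\right]}
#' with the contact radius obtained from [sneddon_contact_radius()].
#' F(0) = 0 and F is strictly increasing and linear in the reduced modulus.
#'
#' @param h Indentation depth, m (>= 0). Vectorized.
#' @param params A [contact_params()] object.
#' @return Force, N.
#' @export
sneddon_force <- function(h, params) {
  stopifnot(inherits(params, "contact_params"))
  rc <- sneddon_contact_radius(h, params$R)
  R <- params$R
  ifelse(rc == 0, 0,
         (params$E_star / 2) *
           ((rc^2 + R^2) * log((R + rc) / (R - rc)) - 2 * rc * R))
}

#' Polynomial approximation to the spherical indentation force
#'
#' Closed-form force-depth law obtained by integrating the contact stiffness
#' with the contact radius expanded in powers of h/R:
#' \deqn{F = \frac{2E}{1-\nu^2}\left[\frac{2}{3} c_1 R^{1/2} h^{3/2}
#'   + \frac{1}{2} c_2 h^2 + \frac{1}{3} c_3 R^{-1} h^3 + \dots
#'   + \frac{1}{N} c_N R^{2-N} h^N\right].}
#' Agrees with [sneddon_force()] to better than 1% over the validity domain
#' of the six-term set.
#'
#' @param h Indentation depth, m (>= 0). Vectorized. Must satisfy
#'   `h/R <= coefs$domain_max`.
#' @param params A [contact_params()] object.
#' @param coefs A `coef_set`, or `"N3"`/`"N6"` (default `"N6"`).
#' @return Force, N.
#' @export
polynomial_force <- function(h, params, coefs = afm_coefs("N6")) {
  stopifnot(inherits(params, "contact_params"))
  coefs <- as_coef_set(coefs)
  if (any(h < 0)) stop("'h' must be non-negative", call. = FALSE)
  u <- h / params$R
  check_domain(u, coefs)
  2 * params$E_star * params$R^2 * force_dimless(u, coefs)
}

# F / (2 E* R^2) as a function of u = h/R
force_dimless <- function(u, coefs) {
  cc <- coefs$c
  out <- (2 / 3) * cc[1L] * u^1.5
  for (k in seq_along(cc)[-1L]) out <- out + cc[k] * u^k / k
  out
}

# S / (2 E* R) as a function of u = h/R
stiffness_dimless <- function(u, coefs) {
  cc <- coefs$c
  out <- cc[1L] * sqrt(u)
  for (k in seq_along(cc)[-1L]) out <- out + cc[k] * u^(k - 1L)
  out
}

#' Hertz (small-depth) spherical indentation force
#'
#' The classical parabolic-contact law
#' \eqn{F = \frac{4}{3} E^* R^{1/2} h^{3/2}}, valid for depths much smaller
#' than the tip radius. It is the small-depth limit of the exact model.
#'
#' @inheritParams sneddon_force
#' @return Force, N.
#' @export
hertz_force <- function(h, params) {
  stopifnot(inherits(params, "contact_params"))
  if (any(h < 0)) stop("'h' must be non-negative", call. = FALSE)
  (4 / 3) * params$E_star * sqrt(params$R) * h^1.5
}

#' Contact stiffness of the polynomial model
#'
#' Analytic derivative dF/dh of [polynomial_force()]:
#' \deqn{S(h) = \frac{2E}{1-\nu^2}\left[c_1 R^{1/2} h^{1/2} + c_2 h
#'   + c_3 R^{-1} h^2 + \dots + c_N R^{2-N} h^{N-1}\right].}
#' Evaluated at maximum depth this is the slope of the tangent line the
#' calibration method is built on.
#'
#' @inheritParams polynomial_force
#' @return Stiffness, N/m.
#' @export
contact_stiffness <- function(h, params, coefs = afm_coefs("N6")) {
  stopifnot(inherits(params, "contact_params"))
  coefs <- as_coef_set(coefs)
  if (any(h < 0)) stop("'h' must be non-negative", call. = FALSE)
  u <- h / params$R
  check_domain(u, coefs)
  2 * params$E_star * params$R * stiffness_dimless(u, coefs)
}
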