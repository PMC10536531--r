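#' Indentation-axis intercept ratio of the tangent line
#'
#' For the polynomial contact model, the tangent to the force-indentation
#' curve at maximum depth crosses the indentation axis at
#' \eqn{h_{com} = -b/S}. The ratio \eqn{h_{com}/h_{max}} depends only on the
#' depth-to-radius ratio \eqn{u = h_{max}/R} — not on the Young's modulus —
#' which is what makes the tip radius recoverable from a single curve:
#' \deqn{\frac{h_{com}}{h_{max}} = \frac{\frac{1}{3}c_1 u^{3/2}
#'   + \frac{1}{2}c_2 u^2 + \frac{2}{3}c_3 u^3 + \dots
#'   + \frac{N-1}{N}c_N u^N}{u\,(c_1 u^{1/2} + c_2 u + \dots + c_N u^{N-1})}.}
#' The ratio decreases strictly from 1/3 (Hertz limit, u -> 0) to about 0.10
#' at u = 5.
#'
#' @param ratio Depth-to-radius ratio hmax/R, in (0, domain_max\]. Vectorized.
#' @param coefs A `coef_set`, or `"N3"`/`"N6"` (default `"N6"`).
#' @return hcom/hmax, dimensionless.
#' @export
hcom_over_hmax <- function(ratio, coefs = afm_coefs("N6")) {
  coefs <- as_coef_set(coefs)
  if (any(ratio <= 0)) stop("'ratio' must be positive", call. = FALSE)
  check_domain(ratio, coefs, what = "hmax/R", slack = 0.01)
  -b_dimensionless(ratio, coefs) / (ratio * stiffness_dimless(ratio, coefs))
}

#' Dimensionless force-axis intercept of the tangent line
#'
#' Evaluates \eqn{b/(2 E^* R^2)} as a function of the depth-to-radius ratio:
#' \deqn{\frac{b}{2E^*R^2} = -\left[\frac{1}{3}c_1 u^{3/2}
#'   + \frac{1}{2}c_2 u^2 + \frac{2}{3}c_3 u^3 + \dots
#'   + \frac{N-1}{N}c_N u^N\right].}
#' Negative throughout; tends to -0.5 for large u.
#'
#' @inheritParams hcom_over_hmax
#' @return b/(2 E* R^2), dimensionless (negative).
#' @export
b_dimensionless <- function(ratio, coefs = afm_coefs("N6")) {
  coefs <- as_coef_set(coefs)
  if (any(ratio <= 0)) stop("'ratio' must be positive", call. = FALSE)
  check_domain(ratio, coefs, what = "hmax/R", slack = 0.01)
  cc <- coefs$c
  out <- (1 / 3) * cc[1L] * ratio^1.5
  for (k in seq_along(cc)[-1L])
    out <- out + ((k - 1) / k) * cc[k] * ratio^k
  -out
}

#' Tangent line at maximum indentation depth
#'
#' From a fitted force-depth polynomial \eqn{F = a h^{3/2} + b h^2 + c h^3}
#' (see [fit_force_curve()]), constructs the tangent line \eqn{F = S h + b}
#' at \eqn{h = h_{max}}: the contact stiffness S is the analytic derivative,
#' the force-axis intercept is \eqn{b = F_{max} - S\,h_{max}}, and the
#' indentation-axis intercept is \eqn{h_{com} = -b/S}.
#'
#' @param fit An `afm_polyfit` from [fit_force_curve()], or a numeric vector
#'   of length 3 `c(a, b, c)` in SI units.
#' @param hmax Maximum indentation depth, m.
#' @return A `tangent_line` list: `S` (N/m), `b_intercept` (N), `hmax` (m),
#'   `Fmax` (N), `hcom` (m).
#' @examples
#' tangent_from_polyfit(c(281, -23340, -1.019e10), hmax = 4.32e-7)
#' @export
tangent_from_polyfit <- function(fit, hmax) {
  if (inherits(fit, "afm_polyfit")) abc <- fit$coefficients
  else if (is.numeric(fit) && length(fit) == 3L) abc <- as.numeric(fit)
  else stop("'fit' must be an afm_polyfit or a numeric vector c(a, b, c)",
            call. = FALSE)
  if (!is.numeric(hmax) || length(hmax) != 1L || hmax <= 0)
    stop("'hmax' must be a single positive depth (m)", call. = FALSE)
  a <- unname(abc[1L]); b <- unname(abc[2L]); cc <- unname(abc[3L])
  S <- 1.5 * a * sqrt(hmax) + 2 * b * hmax + 3 * cc * hmax^2
  if (!is.finite(S) || S <= 0)
    stop("non-positive contact stiffness at hmax: not a valid indentation curve",
         call. = FALSE)
  Fmax <- a * hmax^1.5 + b * hmax^2 + cc * hmax^3
  b_int <- Fmax - S * hmax
  structure(list(S = S, b_intercept = b_int, hmax = hmax, Fmax = Fmax,
                 hcom = -b_int / S),
            class = "tangent_line")
}

#' @export
print.tangent_line <- function(x, ...) {
  cat("Tangent line at maximum indentation depth\n")
  cat(sprintf("  S     = %.4g N/m   (contact stiffness)\n", x$S))
  cat(sprintf("  b     = %.4g N     (force-axis intercept)\n", x$b_intercept))
  cat(sprintf("  hcom  = %.4g m     (indentation-axis intercept)\n", x$hcom))
  cat(sprintf("  hmax  = %.4g m, Fmax = %.4g N\n", x$hmax, x$Fmax))
  invisible(x)
}

#' Recover the tip radius from the tangent-line intercepts
#'
#' Solves the modulus-free radius equation: finds the depth-to-radius ratio
#' `u = hmax/R` at which [hcom_over_hmax()] equals the measured
#' `hcom/hmax`, by a bracketed root search on `(0, domain_max]` (the mapping
#' is strictly decreasing), then returns `R = hmax/u`.
#'
#' When `hcom/hmax` is within `degeneracy_threshold` of 1/3 the curve is in
#' the Hertz (small-depth) regime, where the intercept ratio is exactly 1/3
#' for every radius: no radius information is present and the result is
#' flagged degenerate with `R = NA`.
#'
#' @param hcom Indentation-axis intercept of the tangent line, m.
#' @param hmax Maximum indentation depth, m.
#' @param coefs A `coef_set`, or `"N3"`/`"N6"` (default `"N6"`).
#' @param degeneracy_threshold Flag the Hertz regime when
#'   `hcom/hmax > 1/3 - degeneracy_threshold` (default 0.005).
#' @return A list: `R` (m, `NA` if degenerate), `ratio` (hmax/R),
#'   `hcom_ratio` (hcom/hmax), `degenerate` (logical), `residual`
#'   (radius-equation residual at the solution).
#' @export
solve_radius <- function(hcom, hmax, coefs = afm_coefs("N6"),
                         degeneracy_threshold = 0.005) {
  coefs <- as_coef_set(coefs)
  if (!is.numeric(hcom) || length(hcom) != 1L ||
      !is.numeric(hmax) || length(hmax) != 1L || hmax <= 0 || hcom <= 0)
    stop("'hcom' and 'hmax' must be single positive depths (m)", call. = FALSE)
  x <- hcom / hmax
  if (x >= 1) stop("hcom/hmax >= 1: not a physical tangent intercept", call. = FALSE)
  if (x > 1 / 3 - degeneracy_threshold) {
    return(list(R = NA_real_, ratio = NA_real_, hcom_ratio = x,
                degenerate = TRUE, residual = NA_real_))
  }
  lo <- 1e-4
  x_hi <- hcom_over_hmax(coefs$domain_max, coefs)
  if (x < x_hi)
    stop(sprintf(
      "hcom/hmax = %.4f is below the value %.4f at the '%s' set's validity bound (hmax/R = %.4g)%s",
      x, x_hi, coefs$name, coefs$domain_max,
      if (identical(coefs$name, "N3")) "; use the N6 set" else ""),
      call. = FALSE)
  u <- stats::uniroot(function(u) hcom_over_hmax(u, coefs) - x,
                      lower = lo, upper = coefs$domain_max, tol = 1e-12)$root
  list(R = hmax / u, ratio = u, hcom_ratio = x, degenerate = FALSE,
       residual = hcom_over_hmax(u, coefs) - x)
}

#' Young's modulus from the force-axis intercept
#'
#' With the tip radius known (measured or recovered by [solve_radius()]),
#' the force-axis intercept of the tangent line gives the modulus:
#' \eqn{b = 2 E^* R^2 \cdot \tilde b(h_{max}/R)} with \eqn{\tilde b} from
#' [b_dimensionless()], so \eqn{E = b\,(1-\nu^2) / (2 R^2 \tilde b)}.
#'
#' @param tangent A `tangent_line` from [tangent_from_polyfit()].
#' @param R Tip radius, m.
#' @param v Poisson ratio.
#' @param coefs A `coef_set`, or `"N3"`/`"N6"` (default `"N6"`).
#' @return Young's modulus, Pa.
#' @export
solve_modulus <- function(tangent, R, v = 0.5, coefs = afm_coefs("N6")) {
  stopifnot(inherits(tangent, "tangent_line"))
  coefs <- as_coef_set(coefs)
  if (!is.numeric(R) || length(R) != 1L || R <= 0)
    stop("'R' must be a single positive radius (m)", call. = FALSE)
  if (tangent$b_intercept == 0) return(0)
  if (tangent$b_intercept > 0)
    stop("positive force-axis intercept: tangent line is not from a stiffening contact curve",
         call. = FALSE)
  u <- tangent$hmax / R
  bd <- b_dimensionless(u, coefs)
  if (!is.finite(bd) || bd >= 0)
    stop("non-negative dimensionless intercept: outside the model domain", call. = FALSE)
  tangent$b_intercept * (1 - v^2) / (2 * R^2 * bd)
}

#' Quartic inverse map from intercept ratio to depth-to-radius ratio
#'
#' Convenience approximation for desk use: generates
#' `(hcom/hmax, hmax/R)` pairs from [hcom_over_hmax()] on a uniform ratio
#' grid and least-squares fits a fourth-degree polynomial
#' \deqn{h_{max}/R = p_4 x^4 + p_3 x^3 + p_2 x^2 + p_1 x + p_0,\quad
#'   x = h_{com}/h_{max}.}
#' The fit is regenerated rather than tabulated because rounded quartic
#' coefficients suffer catastrophic cancellation (the four terms nearly
#' cancel); for accurate inversion prefer [solve_radius()].
#'
#' @param domain_max Upper end of the hmax/R grid (must be within the
#'   coefficient set's validity bound).
#' @param coefs A `coef_set`, or `"N3"`/`"N6"` (default `"N6"`).
#' @param step Grid step in hmax/R (default 0.01; grid starts at 0.01).
#' @return A list: `p` (named p0..p4), `r_squared`, `max_residual` (largest
#'   absolute hmax/R residual on the grid) and `predict`, a function of
#'   hcom/hmax.
#' @export
fit_inverse_quartic <- function(domain_max = 1.32, coefs = afm_coefs("N6"),
                                step = 0.01) {
  coefs <- as_coef_set(coefs)
  if (domain_max > coefs$domain_max)
    stop("'domain_max' exceeds the coefficient set's validity bound", call. = FALSE)
  u <- seq(step, domain_max, by = step)
  x <- hcom_over_hmax(u, coefs)
  fit <- stats::lm(u ~ x + I(x^2) + I(x^3) + I(x^4))
  p <- stats::setNames(stats::coef(fit), paste0("p", 0:4))
  pred <- function(x) p[1L] + p[2L] * x + p[3L] * x^2 + p[4L] * x^3 + p[5L] * x^4
  list(p = p,
       r_squared = summary(fit)$r.squared,
       max_residual = max(abs(stats::residuals(fit))),
       predict = pred)
}

#' Lookup table of intercept ratio versus depth-to-radius ratio
#'
#' Tabulates [hcom_over_hmax()] on a regular grid, rounded half-even to four
#' decimals, for graphical/desk determination of the tip radius: locate the
#' measured `hcom/hmax` in the second column and read off `hmax/R`.
#'
#' @param ratio_min,ratio_max,step Grid specification in hmax/R.
#' @param coefs A `coef_set`, or `"N3"`/`"N6"` (default `"N6"`).
#' @return A data.frame with columns `hmax_over_R` and `hcom_over_hmax`
#'   (strictly decreasing).
#' @examples
#' head(build_lookup_table(0.01, 1.00, 0.01))
#' @export
build_lookup_table <- function(ratio_min = 0.01, ratio_max = 1.00,
                               step = 0.01, coefs = afm_coefs("N6")) {
  coefs <- as_coef_set(coefs)
  if (!is.numeric(step) || step <= 0 || ratio_max < ratio_min)
    stop("invalid grid: need ratio_min <= ratio_max and step > 0", call. = FALSE)
  if (ratio_min + step > ratio_max + 1e-12 && ratio_min != ratio_max)
    stop("'step' larger than the requested range", call. = FALSE)
  u <- seq(ratio_min, ratio_max, by = step)
  check_domain(u, coefs, what = "hmax/R", slack = 0.01)
  data.frame(hmax_over_R = u,
             hcom_over_hmax = round(hcom_over_hmax(u, coefs), 4))
}

#' Write a lookup table as CSV
#'
#' @param table A data.frame from [build_lookup_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lookup_table <- function(table, path) {
  out <- data.frame(hmax_over_R = format(table$hmax_over_R, trim = TRUE),
                    hcom_over_hmax = sprintf("%.4f", table$hcom_over_hmax))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
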