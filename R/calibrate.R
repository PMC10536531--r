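#' Calibrate tip radius and Young's modulus from one force-indentation curve
#'
#' The package's central fitting function. The approach-segment
#' force-indentation data are fitted to \eqn{F = a h^{3/2} + b h^2 + c h^3}
#' ([fit_force_curve()]); the tangent line at the maximum depth is formed
#' ([tangent_from_polyfit()]); its indentation-axis intercept ratio
#' `hcom/hmax` is inverted for the depth-to-radius ratio and hence the tip
#' radius ([solve_radius()]) — a step that never uses the modulus — and the
#' force-axis intercept then yields the Young's modulus ([solve_modulus()]).
#'
#' With `coefs = "auto"` (default) the radius equation is first solved with
#' the six-term coefficient set, which covers any practical depth; if the
#' recovered ratio lies within the three-term set's domain (h/R <= 1.32) the
#' calibration is re-solved and reported with the simpler three-term set,
#' matching routine practice for conventional depths.
#'
#' Shallow (Hertz-regime) curves carry no radius information: the intercept
#' ratio equals 1/3 for every radius. Such curves are flagged `degenerate`
#' and return `NA` for R and E rather than an arbitrary number.
#'
#' @param curve A [force_curve()], or a two-column data.frame/matrix of
#'   depth (m) and force (N).
#' @param v Sample Poisson ratio (default 0.5, incompressible).
#' @param coefs `"auto"` (default), `"N3"`, `"N6"`, or a `coef_set`.
#' @param degeneracy_threshold Passed to [solve_radius()] (default 0.005 on
#'   `hcom/hmax` distance from 1/3).
#' @return An object of class `afm_calibration`: a list with elements
#'   `R` (m), `E` (Pa), `ratio` (hmax/R), `hcom_ratio`, `degenerate`,
#'   `coef_set` (name), `tangent` (`tangent_line`), `fit` (`afm_polyfit`),
#'   `curve`, `v`, `residual`, `call`. Methods: `print`, `summary`, `coef`,
#'   `predict`, `fitted`, `residuals`, `plot`, `simulate`.
#' @examples
#' cur <- simulate_curve(E = 100e3, R = 1e-6, hmax = 0.5e-6)
#' fit <- afm_calibrate(cur)
#' fit
#' coef(fit)
#' @export
afm_calibrate <- function(curve, v = 0.5, coefs = c("auto", "N3", "N6"),
                          degeneracy_threshold = 0.005) {
  cl <- match.call()
  if (is.data.frame(curve) || is.matrix(curve))
    curve <- force_curve(curve[, 1L], curve[, 2L])
  stopifnot(inherits(curve, "force_curve"))
  if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 0.5)
    stop("'v' must be in [0, 0.5]", call. = FALSE)
  auto <- FALSE
  if (is.character(coefs)) {
    coefs <- match.arg(coefs)
    if (coefs == "auto") { auto <- TRUE; cset <- afm_coefs("N6") }
    else cset <- afm_coefs(coefs)
  } else cset <- as_coef_set(coefs)

  fit <- fit_force_curve(curve)
  tangent <- tangent_from_polyfit(fit, curve$hmax)
  sol <- solve_radius(tangent$hcom, tangent$hmax, cset,
                      degeneracy_threshold = degeneracy_threshold)
  if (auto && !sol$degenerate && sol$ratio <= afm_coefs("N3")$domain_max) {
    cset <- afm_coefs("N3")
    sol <- solve_radius(tangent$hcom, tangent$hmax, cset,
                        degeneracy_threshold = degeneracy_threshold)
  }
  E <- if (sol$degenerate) NA_real_ else solve_modulus(tangent, sol$R, v, cset)
  structure(list(
    R = sol$R, E = E, ratio = sol$ratio, hcom_ratio = sol$hcom_ratio,
    degenerate = sol$degenerate, coef_set = cset$name, coefs = cset,
    tangent = tangent, fit = fit, curve = curve, v = v,
    residual = sol$residual, call = cl
  ), class = "afm_calibration")
}

#' @export
print.afm_calibration <- function(x, ...) {
  cat("Tangent-line AFM calibration\n")
  if (x$degenerate) {
    cat(sprintf(
      "  DEGENERATE: hcom/hmax = %.4f is at the Hertz limit 1/3 - the curve is\n  too shallow to carry tip-radius information (no R, no E reported).\n",
      x$hcom_ratio))
  } else {
    cat(sprintf("  Tip radius      R = %.4g m  (%.4g um)\n", x$R, x$R * 1e6))
    cat(sprintf("  Young's modulus E = %.4g Pa (%.4g kPa, v = %.3g)\n",
                x$E, x$E / 1e3, x$v))
    cat(sprintf("  hmax/R = %.4f, hcom/hmax = %.4f, coefficient set '%s'\n",
                x$ratio, x$hcom_ratio, x$coef_set))
  }
  invisible(x)
}

#' @export
summary.afm_calibration <- function(object, ...) {
  structure(list(cal = object), class = "summary.afm_calibration")
}

#' @export
print.summary.afm_calibration <- function(x, ...) {
  cal <- x$cal
  print(cal)
  cat("\nCurve fit  F = a h^{3/2} + b h^2 + c h^3:\n")
  cat(sprintf("  a = %.6g, b = %.6g, c = %.6g (SI), R-squared = %.4f, n = %d\n",
              cal$fit$coefficients[1L], cal$fit$coefficients[2L],
              cal$fit$coefficients[3L], cal$fit$r_squared, cal$fit$n))
  cat("Tangent line at hmax:\n")
  cat(sprintf("  S = %.6g N/m, b = %.6g N, hcom = %.6g m, hmax = %.6g m\n",
              cal$tangent$S, cal$tangent$b_intercept, cal$tangent$hcom,
              cal$tangent$hmax))
  invisible(x)
}

#' @export
coef.afm_calibration <- function(object, ...) {
  c(R = object$R, E = object$E)
}

#' Predict force from a calibrated contact model
#'
#' Evaluates the physical contact model at the calibrated tip radius and
#' modulus (`type = "model"`), or the empirical polynomial fit
#' (`type = "fit"`), at the requested depths.
#'
#' @param object An `afm_calibration`.
#' @param h Depths, m (default: the calibrated curve's depths).
#' @param type `"model"` (calibrated E, R through [polynomial_force()]) or
#'   `"fit"` (the empirical a, b, c polynomial).
#' @param ... Unused.
#' @return Forces, N.
#' @export
predict.afm_calibration <- function(object, h = object$curve$h,
                                    type = c("model", "fit"), ...) {
  type <- match.arg(type)
  if (type == "fit") {
    cf <- object$fit$coefficients
    return(cf[1L] * h^1.5 + cf[2L] * h^2 + cf[3L] * h^3)
  }
  if (object$degenerate)
    stop("degenerate calibration: no recovered radius to predict from", call. = FALSE)
  polynomial_force(h, contact_params(object$E, object$v, object$R), object$coefs)
}

#' @export
fitted.afm_calibration <- function(object, ...) object$fit$fitted

#' @export
residuals.afm_calibration <- function(object, ...) object$fit$residuals

#' Plot a calibrated force-indentation curve
#'
#' Data, fitted polynomial and the tangent line at maximum depth, with the
#' indentation-axis intercept marked.
#'
#' @param x An `afm_calibration`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.afm_calibration <- function(x, ...) {
  h <- x$curve$h; Fo <- x$curve$F
  graphics::plot(h * 1e9, Fo * 1e9, pch = 16, cex = 0.5, col = "grey40",
                 xlab = "indentation depth h (nm)", ylab = "force F (nN)", ...)
  hg <- seq(0, x$curve$hmax, length.out = 200)
  graphics::lines(hg * 1e9, predict(x, hg, type = "fit") * 1e9,
                  col = "steelblue", lwd = 2)
  tl <- x$tangent
  graphics::abline(a = tl$b_intercept * 1e9,
                   b = tl$S * 1e9 / 1e9 * 1,  # N/m -> nN/nm is 1:1
                   col = "firebrick", lty = 2)
  graphics::points(tl$hcom * 1e9, 0, pch = 4, col = "firebrick", lwd = 2)
  graphics::legend("topleft", bty = "n",
                   legend = c("data", "polynomial fit", "tangent at hmax"),
                   col = c("grey40", "steelblue", "firebrick"),
                   pch = c(16, NA, NA), lty = c(NA, 1, 2))
  invisible(x)
}

#' Simulate curves from a calibrated model
#'
#' Draws synthetic force-indentation curves from the calibrated tip radius
#' and modulus, with additive Gaussian force noise — useful for parametric-
#' bootstrap style checks of the recovery.
#'
#' @param object An `afm_calibration` (non-degenerate).
#' @param nsim Number of curves.
#' @param seed Integer seed (required when `noise_sd_fraction > 0`).
#' @param noise_sd_fraction Force noise sd as a fraction of Fmax
#'   (default matches the fitted residual scale).
#' @param ... Unused.
#' @return A list of [force_curve()] objects.
#' @export
simulate.afm_calibration <- function(object, nsim = 1, seed = NULL,
                                     noise_sd_fraction = NULL, ...) {
  if (object$degenerate)
    stop("degenerate calibration: nothing to simulate from", call. = FALSE)
  if (is.null(noise_sd_fraction))
    noise_sd_fraction <- object$fit$sigma / abs(object$tangent$Fmax)
  model <- if (object$coef_set == "N3") "polynomial-N3" else "polynomial-N6"
  lapply(seq_len(nsim), function(i) {
    simulate_curve(E = object$E, v = object$v, R = object$R,
                   hmax = object$curve$hmax, n_points = object$curve$n,
                   noise_sd_fraction = noise_sd_fraction,
                   seed = if (is.null(seed)) NULL else seed + i,
                   model = model)
  })
}
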