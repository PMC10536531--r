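#' Force-indentation curve
#'
#' Paired indentation depth and force samples from the post-contact approach
#' segment of an AFM nanoindentation. Samples are stored sorted by depth;
#' `hmax`/`Fmax` refer to the deepest sample.
#'
#' @param h Indentation depth samples, m (non-negative).
#' @param F Force samples, N.
#' @return A `force_curve` list: `h`, `F`, `hmax`, `Fmax`, `n`.
#' @export
force_curve <- function(h, F) {
  h <- as.numeric(h); F <- as.numeric(F)
  if (length(h) != length(F))
    stop("'h' and 'F' must have equal length", call. = FALSE)
  if (length(h) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (!all(is.finite(h)) || !all(is.finite(F)))
    stop("'h' and 'F' must be finite", call. = FALSE)
  if (any(h < 0)) stop("'h' must be non-negative (post-contact depths)", call. = FALSE)
  o <- order(h)
  h <- h[o]; F <- F[o]
  structure(list(h = h, F = F, hmax = h[length(h)], Fmax = F[length(F)],
                 n = length(h)),
            class = "force_curve")
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf("Force-indentation curve: %d samples, hmax = %.4g m, Fmax = %.4g N\n",
              x$n, x$hmax, x$Fmax))
  invisible(x)
}

#' @export
as.data.frame.force_curve <- function(x, ...) data.frame(h = x$h, F = x$F)

#' Raw piezo-displacement / deflection curve
#'
#' The instrument-level approach record: piezo displacement `z` and
#' cantilever deflection `d` (both m), with the cantilever spring constant
#' `k` (N/m). Conversion to force-indentation happens after contact-point
#' detection ([find_contact_point()], [to_force_indentation()]).
#'
#' @param z Piezo displacement, m (non-decreasing approach ramp).
#' @param d Cantilever deflection, m.
#' @param k Spring constant, N/m (> 0).
#' @return A `raw_curve` list.
#' @export
raw_curve <- function(z, d, k) {
  z <- as.numeric(z); d <- as.numeric(d)
  if (length(z) != length(d)) stop("'z' and 'd' must have equal length", call. = FALSE)
  if (length(z) < 20L) stop("need at least 20 samples", call. = FALSE)
  if (!is.numeric(k) || length(k) != 1L || k <= 0)
    stop("'k' must be a single positive spring constant (N/m)", call. = FALSE)
  structure(list(z = z, d = d, k = k, n = length(z)), class = "raw_curve")
}

#' @export
print.raw_curve <- function(x, ...) {
  cat(sprintf("Raw AFM curve: %d samples, z range [%.4g, %.4g] m, k = %.4g N/m\n",
              x$n, min(x$z), max(x$z), x$k))
  invisible(x)
}

unit_scale <- function(units = c("si", "nm")) {
  units <- match.arg(units)
  # nm/nN on disk -> m/N internally
  if (units == "nm") c(x = 1e-9, y = 1e-9) else c(x = 1, y = 1)
}

read_two_columns <- function(path, what) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) stop("no data lines in ", path, call. = FALSE)
  sep <- if (grepl(",", lines[idx[1L]])) "," else ""
  first <- strsplit(trimws(lines[idx[1L]]),
                    if (sep == ",") "," else "\\s+")[[1L]]
  header <- suppressWarnings(any(is.na(as.numeric(first))))
  skip_first <- if (header) idx[1L] else integer(0)
  data_idx <- setdiff(idx, skip_first)
  parse_one <- function(i) {
    fields <- strsplit(trimws(lines[i]), if (sep == ",") "," else "\\s+")[[1L]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) < 2L || any(is.na(vals[1:2])))
      stop(sprintf("parse error in %s at line %d: expected two numeric %s columns, got '%s'",
                   path, i, what, lines[i]), call. = FALSE)
    vals[1:2]
  }
  m <- t(vapply(data_idx, parse_one, numeric(2)))
  list(x = m[, 1L], y = m[, 2L])
}

#' Read a force-indentation curve from delimited text
#'
#' Expects two numeric columns (depth, force), comma- or whitespace-
#' separated; lines starting with `#` and an optional header line are
#' ignored. Units are SI (m, N) by default or nm/nN with `units = "nm"`.
#'
#' @param path Input file.
#' @param units `"si"` (m, N) or `"nm"` (nm, nN).
#' @return A [force_curve()].
#' @export
read_force_curve <- function(path, units = c("si", "nm")) {
  sc <- unit_scale(units)
  cols <- read_two_columns(path, "h,F")
  force_curve(cols$x * sc["x"], cols$y * sc["y"])
}

#' Read a raw piezo/deflection curve from delimited text
#'
#' Two numeric columns (piezo displacement z, deflection d); the spring
#' constant is supplied separately.
#'
#' @param path Input file.
#' @param k Spring constant, N/m.
#' @param units `"si"` (m) or `"nm"` (nm).
#' @return A [raw_curve()].
#' @export
read_raw_curve <- function(path, k, units = c("si", "nm")) {
  sc <- unit_scale(units)
  cols <- read_two_columns(path, "z,d")
  raw_curve(cols$x * sc["x"], cols$y * sc["x"], k = k)
}

#' Write a force-indentation curve as delimited text
#'
#' @param curve A [force_curve()].
#' @param path Output file.
#' @param units `"si"` (m, N) or `"nm"` (nm, nN).
#' @return `path`, invisibly.
#' @export
write_force_curve <- function(curve, path, units = c("si", "nm")) {
  stopifnot(inherits(curve, "force_curve"))
  sc <- unit_scale(units)
  df <- data.frame(h = curve$h / sc["x"], F = curve$F / sc["y"])
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# force-indentation curve (%s units): h F",
                     match.arg(units)), con)
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = TRUE),
                     con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

fast_rss <- function(X, y) {
  fit <- stats::.lm.fit(X, y)
  sum(fit$residuals^2)
}

#' Contact-point detection by trial-point residual scan
#'
#' Every admissible sample index is tried as the contact point: a polynomial
#' (default degree 1, a tilted baseline) is fitted to the pre-contact
#' segment and the spherical contact basis \eqn{\{h^{3/2}, h^2, h^3\}} to the
#' post-contact segment (in force units), and the index minimizing the total
#' sum of squared residuals is returned. For curves longer than 5000 samples
#' every second index is scanned.
#'
#' @param raw A [raw_curve()].
#' @param precontact_degree Baseline polynomial degree, 0-3 (default 1).
#' @return A `contact_point` list: `index`, `z0`, `d0` (offsets at contact),
#'   `rss` (total residual at the optimum).
#' @export
find_contact_point <- function(raw, precontact_degree = 1L) {
  stopifnot(inherits(raw, "raw_curve"))
  precontact_degree <- as.integer(precontact_degree)
  if (precontact_degree < 0L || precontact_degree > 3L)
    stop("'precontact_degree' must be between 0 and 3", call. = FALSE)
  z <- raw$z; d <- raw$d; k <- raw$k; n <- raw$n
  lo <- precontact_degree + 2L
  hi <- n - 5L
  if (hi < lo) stop("curve too short for contact-point scan", call. = FALSE)
  stride <- if (n > 5000L) 2L else 1L
  trials <- seq(lo, hi, by = stride)
  zs <- (z - z[1L]) / max(abs(z - z[1L]))  # scaled abscissa for the baseline fit
  Xpre_full <- vapply(0:precontact_degree, function(p) zs^p, numeric(n))
  best <- Inf; best_i <- NA_integer_
  for (i in trials) {
    pre <- seq_len(i)
    rss_pre <- fast_rss(Xpre_full[pre, , drop = FALSE], d[pre]) * k^2
    post <- (i + 1L):n
    h <- (z[post] - z[i]) - (d[post] - d[i])
    Fp <- k * (d[post] - d[i])
    ok <- h > 0
    if (sum(ok) < 5L) next
    h <- h[ok]; Fp <- Fp[ok]
    rss_post <- fast_rss(cbind(h^1.5, h^2, h^3), Fp)
    tot <- rss_pre + rss_post
    if (tot < best) { best <- tot; best_i <- i }
  }
  if (!is.finite(best)) stop("no valid trial contact point found", call. = FALSE)
  structure(list(index = best_i, z0 = z[best_i], d0 = d[best_i], rss = best),
            class = "contact_point")
}

#' Convert a raw curve to force-indentation
#'
#' Standard AFM kinematics: after contact the indentation is the piezo
#' travel minus the cantilever bending, \eqn{h = (z - z_0) - (d - d_0)}, and
#' the force is \eqn{F = k\,(d - d_0)}. Only the post-contact segment is
#' kept. The piezo ramp must be non-decreasing (approach segment only);
#' retract/hysteresis data are rejected.
#'
#' @param raw A [raw_curve()].
#' @param contact A `contact_point` from [find_contact_point()], or an
#'   integer sample index.
#' @return A [force_curve()].
#' @export
to_force_indentation <- function(raw, contact) {
  stopifnot(inherits(raw, "raw_curve"))
  if (inherits(contact, "contact_point")) {
    i <- contact$index; z0 <- contact$z0; d0 <- contact$d0
  } else if (is.numeric(contact) && length(contact) == 1L) {
    i <- as.integer(contact)
    if (i < 1L || i > raw$n) stop("contact index out of range", call. = FALSE)
    z0 <- raw$z[i]; d0 <- raw$d[i]
  } else stop("'contact' must be a contact_point or an index", call. = FALSE)
  post <- i:raw$n
  if (is.unsorted(raw$z[post]))
    stop(paste("piezo displacement is not monotonically increasing after contact:",
               "extract the approach segment before conversion"), call. = FALSE)
  h <- (raw$z[post] - z0) - (raw$d[post] - d0)
  Fp <- raw$k * (raw$d[post] - d0)
  keep <- h >= 0
  if (sum(keep) < 2L) stop("no post-contact samples with positive depth", call. = FALSE)
  force_curve(h[keep], Fp[keep])
}

#' Fit the deep-indentation force law to a curve
#'
#' Unweighted linear least squares of \eqn{F = a h^{3/2} + b h^2 + c h^3}
#' (the model is linear in a, b, c; no intercept — F(0) = 0). For a
#' physically meaningful spherical-contact curve a > 0, b < 0, c < 0; sign
#' violations are flagged, not constrained. When b and c are statistically
#' indistinguishable from zero the curve is Hertz-like (small-depth regime)
#' and `hertz_like` is set.
#'
#' @param curve A [force_curve()] (>= 10 post-contact samples).
#' @return An `afm_polyfit` list: `coefficients` (a, b, c), `r_squared`,
#'   `sigma`, `t_values`, `sign_ok`, `hertz_like`, `fitted`, `residuals`,
#'   `hmax`, `n`.
#' @export
fit_force_curve <- function(curve) {
  stopifnot(inherits(curve, "force_curve"))
  if (curve$n < 10L) stop("need at least 10 post-contact samples", call. = FALSE)
  h <- curve$h; Fo <- curve$F
  fit <- stats::lm(Fo ~ I(h^1.5) + I(h^2) + I(h^3) - 1)
  cf <- stats::coef(fit)
  if (any(is.na(cf)))
    stop("singular design: indentation depths do not span the fitting basis",
         call. = FALSE)
  # noiseless model curves trigger summary.lm's "essentially perfect fit"
  # warning; that is the expected case here, not a problem
  sm <- suppressWarnings(summary(fit))
  tv <- sm$coefficients[, "t value"]
  a <- unname(cf[1L]); b <- unname(cf[2L]); cc <- unname(cf[3L])
  tss <- sum((Fo - mean(Fo))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 1
  # Hertz-likeness: does adding the h^2 and h^3 terms improve on the pure
  # h^{3/2} law? (nested-model F test; individual t values are misleading
  # here because the basis functions are nearly collinear)
  fit_hertz <- stats::lm(Fo ~ I(h^1.5) - 1)
  ftest <- stats::anova(fit_hertz, fit)
  hertz_p <- ftest[["Pr(>F)"]][2L]
  structure(list(
    coefficients = c(a = a, b = b, c = cc),
    r_squared = r2,
    sigma = sm$sigma,
    t_values = stats::setNames(unname(tv), c("a", "b", "c")),
    sign_ok = c(a = a > 0, b = b < 0, c = cc < 0),
    hertz_like = is.na(hertz_p) || hertz_p > 0.01,
    hertz_p = hertz_p,
    fitted = unname(stats::fitted(fit)),
    residuals = unname(stats::residuals(fit)),
    hmax = curve$hmax,
    n = curve$n
  ), class = "afm_polyfit")
}

#' @export
print.afm_polyfit <- function(x, ...) {
  cat("Spherical-contact polynomial fit  F = a h^{3/2} + b h^2 + c h^3\n")
  cat(sprintf("  a = %.6g, b = %.6g, c = %.6g (SI)\n",
              x$coefficients[1L], x$coefficients[2L], x$coefficients[3L]))
  cat(sprintf("  R-squared = %.4f on %d samples\n", x$r_squared, x$n))
  if (!all(x$sign_ok))
    cat("  note: sign expectation (a>0, b<0, c<0) violated for:",
        paste(names(x$sign_ok)[!x$sign_ok], collapse = ", "), "\n")
  if (isTRUE(x$hertz_like))
    cat("  note: b and c indistinguishable from 0 - Hertz-like (small-depth) curve\n")
  invisible(x)
}

#' Hertz-model modulus fit
#'
#' Conventional comparator: least-squares Young's modulus under the Hertz
#' law \eqn{F = \frac{4}{3} E^* R^{1/2} h^{3/2}} with a known tip radius.
#' Accurate for shallow curves; underestimates the modulus by roughly 10%
#' when the depth reaches the tip radius.
#'
#' @param curve A [force_curve()].
#' @param R Tip radius, m.
#' @param v Poisson ratio.
#' @return Young's modulus, Pa.
#' @export
fit_hertz_modulus <- function(curve, R, v = 0.5) {
  stopifnot(inherits(curve, "force_curve"))
  if (!is.numeric(R) || length(R) != 1L || R <= 0)
    stop("'R' must be a single positive radius (m)", call. = FALSE)
  x <- curve$h^1.5
  slope <- sum(curve$F * x) / sum(x^2)
  0.75 * slope / sqrt(R) * (1 - v^2)
}
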