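# Run code under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

model_force_fun <- function(model, params) {
  switch(model,
         "sneddon" = function(h) sneddon_force(h, params),
         "polynomial-N3" = function(h) polynomial_force(h, params, afm_coefs("N3")),
         "polynomial-N6" = function(h) polynomial_force(h, params, afm_coefs("N6")),
         "hertz" = function(h) hertz_force(h, params),
         stop("unknown model '", model, "'", call. = FALSE))
}

model_domain_check <- function(model, hmax, R) {
  dm <- switch(model,
               "polynomial-N3" = afm_coefs("N3")$domain_max,
               "polynomial-N6" = afm_coefs("N6")$domain_max,
               Inf)
  if (hmax / R > dm * (1 + 1e-9))
    stop(sprintf("hmax/R = %.4g exceeds the '%s' model bound %.5g",
                 hmax / R, model, dm), call. = FALSE)
}

#' Generate a synthetic force-indentation curve with known ground truth
#'
#' Evaluates a spherical contact model on an evenly spaced depth grid and
#' adds Gaussian force noise with standard deviation
#' `noise_sd_fraction * Fmax` — the simplest noise model consistent with
#' photodiode-dominated deflection error. The ground truth is attached as
#' the `"truth"` attribute, so every pipeline stage can be tested without
#' instrument data.
#'
#' @param E Young's modulus, Pa.
#' @param v Poisson ratio.
#' @param R Tip radius, m.
#' @param hmax Maximum indentation depth, m (must be within the chosen
#'   model's validity domain).
#' @param n_points Number of depth samples (>= 20; default 200, comparable
#'   to real force-curve sampling).
#' @param noise_sd_fraction Force noise sd as a fraction of the noiseless
#'   maximum force (default 0).
#' @param seed Integer seed; mandatory when `noise_sd_fraction > 0`.
#' @param model Forward model: `"polynomial-N6"` (default; valid to
#'   h/R = 4.9512), `"polynomial-N3"`, `"sneddon"` (exact parametric) or
#'   `"hertz"`.
#' @return A [force_curve()] with attribute `"truth"` (list of the
#'   generating parameters).
#' @examples
#' cur <- simulate_curve(E = 100e3, R = 1e-6, hmax = 0.5e-6,
#'                       noise_sd_fraction = 0.01, seed = 7)
#' @export
simulate_curve <- function(E, v = 0.5, R, hmax, n_points = 200L,
                           noise_sd_fraction = 0, seed = NULL,
                           model = c("polynomial-N6", "polynomial-N3",
                                     "sneddon", "hertz")) {
  model <- match.arg(model)
  n_points <- as.integer(n_points)
  if (n_points < 20L) stop("'n_points' must be at least 20", call. = FALSE)
  if (noise_sd_fraction < 0) stop("'noise_sd_fraction' must be >= 0", call. = FALSE)
  if (noise_sd_fraction > 0 && is.null(seed))
    stop("'seed' is mandatory when noise_sd_fraction > 0", call. = FALSE)
  params <- contact_params(E, v, R)
  model_domain_check(model, hmax, R)
  h <- seq(0, hmax, length.out = n_points)
  Fo <- model_force_fun(model, params)(h)
  if (noise_sd_fraction > 0) {
    sd <- noise_sd_fraction * max(Fo)
    Fo <- Fo + with_seed(seed, stats::rnorm(n_points, 0, sd))
  }
  out <- force_curve(h, Fo)
  attr(out, "truth") <- list(E = E, v = v, R = R, hmax = hmax,
                             n_points = n_points,
                             noise_sd_fraction = noise_sd_fraction,
                             seed = seed, model = model)
  out
}

#' Generate a synthetic raw piezo/deflection curve
#'
#' Wraps [simulate_curve()] in instrument kinematics: after contact the
#' piezo displacement is \eqn{z = z_c + h + d} with deflection
#' \eqn{d = F/k}; before contact a baseline of `baseline_points` samples is
#' prepended, optionally tilted (`baseline_tilt`, force per metre of piezo
#' travel) and carrying the same force noise. The ground-truth contact index
#' is recorded in the `"truth"` attribute.
#'
#' @inheritParams simulate_curve
#' @param k Cantilever spring constant, N/m.
#' @param baseline_points Number of pre-contact samples (default 200).
#' @param baseline_tilt Baseline slope, N per m of piezo travel (default 0).
#' @return A [raw_curve()] with attribute `"truth"` (including
#'   `contact_index`).
#' @export
simulate_raw_curve <- function(E, v = 0.5, R, hmax, k, n_points = 200L,
                               noise_sd_fraction = 0, seed = NULL,
                               baseline_points = 200L, baseline_tilt = 0,
                               model = c("polynomial-N6", "polynomial-N3",
                                         "sneddon", "hertz")) {
  model <- match.arg(model)
  baseline_points <- as.integer(baseline_points)
  if (baseline_points < 0L) stop("'baseline_points' must be >= 0", call. = FALSE)
  if (!is.numeric(k) || length(k) != 1L || k <= 0)
    stop("'k' must be a single positive spring constant (N/m)", call. = FALSE)
  n_points <- as.integer(n_points)
  if (n_points < 20L) stop("'n_points' must be at least 20", call. = FALSE)
  if (noise_sd_fraction > 0 && is.null(seed))
    stop("'seed' is mandatory when noise_sd_fraction > 0", call. = FALSE)
  params <- contact_params(E, v, R)
  model_domain_check(model, hmax, R)

  h <- seq(0, hmax, length.out = n_points)
  Fclean <- model_force_fun(model, params)(h)
  Fsd <- noise_sd_fraction * max(Fclean)
  # pre-contact piezo ramp mirrors the post-contact spacing
  dz <- if (n_points > 1L) hmax / (n_points - 1L) else hmax
  z_pre <- if (baseline_points > 0L)
    seq(-baseline_points * dz, -dz, by = dz) else numeric(0)
  noise <- if (Fsd > 0)
    with_seed(seed, stats::rnorm(baseline_points + n_points, 0, Fsd))
  else rep(0, baseline_points + n_points)
  # baseline deflection: tilt (force per metre of z) plus noise, zero at contact
  d_pre <- (baseline_tilt * z_pre + noise[seq_len(baseline_points)]) / k
  Fnoisy <- Fclean + noise[baseline_points + seq_len(n_points)]
  d_post <- Fnoisy / k
  z_post <- h + d_post
  out <- raw_curve(z = c(z_pre, z_post), d = c(d_pre, d_post), k = k)
  attr(out, "truth") <- list(E = E, v = v, R = R, hmax = hmax, k = k,
                             n_points = n_points,
                             noise_sd_fraction = noise_sd_fraction,
                             seed = seed, model = model,
                             baseline_points = baseline_points,
                             baseline_tilt = baseline_tilt,
                             contact_index = baseline_points + 1L)
  out
}

#' Generate a batch of synthetic curves with a truth table
#'
#' Draws per-curve moduli uniformly from `E_range` under the master seed and
#' generates each curve with a deterministic child seed (`seed + i`),
#' mirroring a multi-curve calibration experiment on a gel: many curves,
#' one tip, varying local stiffness. Defaults follow a soft agarose-gel
#' scenario (E in 102-174 kPa, R = 0.92 um).
#'
#' @param n Number of curves (>= 1).
#' @param E_range Length-2 range for the uniform modulus draw, Pa.
#' @param R Tip radius, m (fixed across the batch).
#' @param hmax Maximum depth, m.
#' @param v Poisson ratio.
#' @param n_points Samples per curve.
#' @param noise_sd_fraction Force noise sd as fraction of Fmax.
#' @param seed Master seed (mandatory; child seeds are `seed + 1..n`).
#' @param model Forward model, as in [simulate_curve()].
#' @return A list with `curves` (list of [force_curve()]) and `truth`
#'   (data.frame: id, seed, E, R, hmax, v).
#' @export
simulate_batch <- function(n, E_range = c(102e3, 174e3), R = 0.92e-6,
                           hmax = 0.432e-6, v = 0.5, n_points = 200L,
                           noise_sd_fraction = 0.02, seed,
                           model = c("polynomial-N6", "polynomial-N3",
                                     "sneddon", "hertz")) {
  model <- match.arg(model)
  n <- as.integer(n)
  if (n < 1L) stop("'n' must be at least 1", call. = FALSE)
  if (missing(seed) || is.null(seed)) stop("'seed' is mandatory", call. = FALSE)
  if (length(E_range) == 1L) E_range <- rep(E_range, 2L)
  E <- with_seed(seed, stats::runif(n, E_range[1L], E_range[2L]))
  curves <- lapply(seq_len(n), function(i) {
    simulate_curve(E = E[i], v = v, R = R, hmax = hmax, n_points = n_points,
                   noise_sd_fraction = noise_sd_fraction,
                   seed = if (noise_sd_fraction > 0) seed + i else NULL,
                   model = model)
  })
  list(curves = curves,
       truth = data.frame(id = seq_len(n), seed = seed + seq_len(n),
                          E = E, R = R, hmax = hmax, v = v))
}
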