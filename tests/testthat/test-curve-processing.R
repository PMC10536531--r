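test_that("contact point is found exactly on a noiseless curve", {
  raw <- simulate_raw_curve(E = 100e3, R = 1e-6, hmax = 0.5e-6, k = 0.1,
                            model = "polynomial-N3")
  cp <- find_contact_point(raw)
  expect_identical(cp$index, attr(raw, "truth")$contact_index)
  expect_lt(cp$rss, 1e-30)
})

test_that("contact point under force noise is unbiased to a few samples", {
  # 1% force noise; near the contact the force is below the noise floor, so
  # a spread of ~10 samples (of 400) is intrinsic to the trial-point scan
  err <- vapply(1:50, function(s) {
    raw <- simulate_raw_curve(E = 100e3, R = 1e-6, hmax = 0.5e-6, k = 0.1,
                              noise_sd_fraction = 0.01, seed = s,
                              model = "polynomial-N3")
    find_contact_point(raw)$index - attr(raw, "truth")$contact_index
  }, numeric(1))
  expect_lte(abs(stats::median(err)), 5)
  expect_lte(max(abs(err)), 20)
})

test_that("contact point tolerates a tilted baseline with a degree-1 prefit", {
  err <- vapply(1:25, function(s) {
    raw <- simulate_raw_curve(E = 100e3, R = 1e-6, hmax = 0.5e-6, k = 0.1,
                              noise_sd_fraction = 0.01, seed = 100 + s,
                              baseline_tilt = 0.005, model = "polynomial-N3")
    find_contact_point(raw, precontact_degree = 1)$index -
      attr(raw, "truth")$contact_index
  }, numeric(1))
  expect_lte(abs(stats::median(err)), 5)
  expect_lte(max(abs(err)), 20)
})

test_that("raw-to-force conversion implements the cantilever kinematics", {
  # zero deflection: no force, indentation equals piezo travel
  z <- seq(0, 1e-6, length.out = 50)
  raw <- raw_curve(z, rep(0, 50), k = 0.1)
  cur <- to_force_indentation(raw, 1L)
  expect_equal(cur$F, rep(0, 50))
  expect_equal(cur$h, z)
  # rigid surface: all travel goes into deflection, h stays ~0
  raw_rigid <- raw_curve(z, z, k = 0.1)
  cur_rigid <- to_force_indentation(raw_rigid, 1L)
  expect_true(all(abs(cur_rigid$h) < 1e-15))
  # synthetic raw curve inverts to the generating force curve
  cur0 <- simulate_curve(E = 100e3, R = 1e-6, hmax = 0.5e-6,
                         model = "polynomial-N3")
  raw2 <- simulate_raw_curve(E = 100e3, R = 1e-6, hmax = 0.5e-6, k = 0.1,
                             model = "polynomial-N3")
  back <- to_force_indentation(raw2, attr(raw2, "truth")$contact_index)
  expect_equal(back$h, cur0$h, tolerance = 1e-12)
  expect_equal(back$F, cur0$F, tolerance = 1e-12)
})

test_that("retract/hysteresis segments are rejected", {
  z <- c(seq(0, 1e-6, length.out = 30), seq(1e-6, 0.5e-6, length.out = 10))
  raw <- raw_curve(z, rep(0, 40), k = 0.1)
  expect_error(to_force_indentation(raw, 1L), "approach segment")
})

test_that("cubic-basis fit is exact on model data and maps to the constants", {
  cur <- simulate_curve(E = 100e3, v = 0.5, R = 1e-6, hmax = 0.5e-6,
                        model = "polynomial-N3")
  fit <- suppressWarnings(fit_force_curve(cur))
  expect_gt(fit$r_squared, 0.999999)
  expect_lt(max(abs(fit$residuals)), 1e-12)
  # closed-form coefficient map from the physical constants
  E <- 100e3; v <- 0.5; R <- 1e-6; cs <- afm_coefs("N3")
  a_map <- 4 * cs$c[1] * E * sqrt(R) / (3 * (1 - v^2))
  b_map <- cs$c[2] * E / (1 - v^2)
  c_map <- 2 * cs$c[3] * E / (3 * (1 - v^2) * R)
  expect_lt(max(rel_err(fit$coefficients, c(a_map, b_map, c_map))), 1e-6)
})

test_that("cubic-basis fit on noisy data keeps the expected signs", {
  cur <- simulate_curve(E = 100e3, v = 0.5, R = 1e-6, hmax = 0.5e-6,
                        noise_sd_fraction = 0.01, seed = 11,
                        model = "polynomial-N3")
  fit <- fit_force_curve(cur)
  expect_true(all(fit$sign_ok))
  expect_gt(fit$r_squared, 0.97)
  expect_false(fit$hertz_like)
})

test_that("Hertz-generated data raise the small-depth flag", {
  cur <- simulate_curve(E = 100e3, v = 0.5, R = 1e-6, hmax = 0.05e-6,
                        noise_sd_fraction = 0.005, seed = 3, model = "hertz")
  fit <- fit_force_curve(cur)
  expect_true(fit$hertz_like)
  expect_error(fit_force_curve(force_curve(1:5 * 1e-9, 1:5 * 1e-9)),
               "at least 10")
})

test_that("end-to-end calibration recovers the generating parameters", {
  # worked-example scale
  cur <- simulate_curve(E = 132.5e3, v = 0.5, R = 0.92e-6, hmax = 0.432e-6,
                        model = "polynomial-N3")
  cal <- suppressWarnings(afm_calibrate(cur))
  expect_lt(rel_err(cal$R, 0.92e-6), 0.005)
  expect_lt(rel_err(cal$E, 132.5e3), 0.01)
  expect_identical(cal$coef_set, "N3")  # auto policy drops to N3 here
  # grid of conditions
  for (E in c(50e3, 100e3, 200e3)) for (R in c(0.5e-6, 1e-6, 2e-6))
    for (r in c(0.3, 0.5, 1.0)) {
      cur <- simulate_curve(E = E, v = 0.5, R = R, hmax = r * R,
                            model = "polynomial-N3")
      cal <- suppressWarnings(afm_calibrate(cur, coefs = "N3"))
      expect_lt(rel_err(cal$R, R), 0.005)
      expect_lt(rel_err(cal$E, E), 0.01)
    }
})

test_that("shallow curves are flagged degenerate rather than solved", {
  cur <- simulate_curve(E = 100e3, v = 0.5, R = 1e-6, hmax = 0.01e-6,
                        model = "polynomial-N3")
  cal <- suppressWarnings(afm_calibrate(cur))
  expect_true(cal$degenerate)
  expect_true(is.na(cal$R) && is.na(cal$E))
})

test_that("contact mislocation by a few samples degrades the radius gracefully", {
  # the inversion amplifies intercept-ratio error ~13x at this depth ratio:
  # a 3-sample offset moves R by several percent, asymmetrically (worse when
  # baseline points are absorbed into the contact segment)
  raw <- simulate_raw_curve(E = 100e3, R = 1e-6, hmax = 0.5e-6, k = 0.1,
                            model = "polynomial-N3")
  ci <- attr(raw, "truth")$contact_index
  shifts <- vapply(c(-3, 0, 3), function(s) {
    cal <- suppressWarnings(
      afm_calibrate(to_force_indentation(raw, ci + s), coefs = "N3"))
    cal$R / 1e-6 - 1
  }, numeric(1))
  expect_lt(abs(shifts[2]), 1e-6)
  expect_lt(max(abs(shifts)), 0.10)
  expect_lt(shifts[1], 0)  # early contact underestimates R
})

test_that("radius recovery is insensitive to modulus variation across a batch", {
  # modulus varies ~ +/- 25% across the batch; any R-vs-E association should
  # be statistically indistinguishable from zero
  batch <- simulate_batch(80, seed = 42, noise_sd_fraction = 0.02)
  cals <- lapply(batch$curves, function(cu) suppressWarnings(afm_calibrate(cu)))
  R_hat <- vapply(cals, `[[`, numeric(1), "R")
  ok <- !vapply(cals, `[[`, logical(1), "degenerate")
  expect_gt(sum(ok), 50)
  ct <- stats::cor.test(R_hat[ok], batch$truth$E[ok])
  expect_gt(ct$p.value, 0.01)
  # at instrument-realistic noise the batch is accurate and tight
  batch2 <- simulate_batch(80, seed = 42, noise_sd_fraction = 0.002)
  R2 <- vapply(batch2$curves,
               function(cu) suppressWarnings(afm_calibrate(cu))$R, numeric(1))
  expect_lt(rel_err(mean(R2), 0.92e-6), 0.01)
  expect_lt(stats::sd(R2) / mean(R2), 0.15)
})

test_that("Hertz modulus fit is exact on Hertz data and biased on deep data", {
  cur_h <- simulate_curve(E = 80e3, v = 0.5, R = 1e-6, hmax = 0.1e-6,
                          model = "hertz")
  expect_lt(rel_err(fit_hertz_modulus(cur_h, 1e-6), 80e3), 1e-10)
  # shallow exact-model data: Hertz is a good approximation
  cur_s <- simulate_curve(E = 100e3, v = 0.5, R = 1e-6, hmax = 0.1e-6,
                          model = "polynomial-N3")
  expect_lt(rel_err(fit_hertz_modulus(cur_s, 1e-6), 100e3), 0.015)
  # matching the exact-model force at h = R underestimates E by ~10%
  p <- contact_params(E = 100e3, v = 0.5, R = 1e-6)
  F_R <- polynomial_force(1e-6, p, "N3")
  E_hertz <- 0.75 * F_R * (1 - 0.5^2) / (sqrt(1e-6) * 1e-6^1.5)
  expect_equal(100 * (1 - E_hertz / 100e3), 10, tolerance = 0.1)
})

test_that("calibration methods behave like a fitted model object", {
  cur <- simulate_curve(E = 100e3, v = 0.5, R = 1e-6, hmax = 0.5e-6,
                        noise_sd_fraction = 0.005, seed = 9,
                        model = "polynomial-N3")
  cal <- afm_calibrate(cur)
  expect_named(coef(cal), c("R", "E"))
  expect_length(residuals(cal), cur$n)
  expect_equal(fitted(cal) + residuals(cal), cur$F, tolerance = 1e-12)
  expect_equal(predict(cal, type = "fit"), fitted(cal), tolerance = 1e-12)
  # calibrated physical model tracks the data to within a few % of Fmax
  expect_lt(max(abs(predict(cal, cur$h, type = "model") - cur$F)) / cur$Fmax,
            0.05)
  expect_output(print(cal), "Tip radius")
  expect_output(print(summary(cal)), "Tangent line")
  sims <- simulate(cal, nsim = 2, seed = 5)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "force_curve")
  f <- tempfile(fileext = ".png")
  grDevices::png(f); plot(cal); grDevices::dev.off()
  expect_true(file.exists(f)); unlink(f)
})

test_that("curve file round trip preserves data in both unit systems", {
  cur <- simulate_curve(E = 100e3, v = 0.5, R = 1e-6, hmax = 0.5e-6,
                        noise_sd_fraction = 0.01, seed = 2,
                        model = "polynomial-N3")
  for (units in c("si", "nm")) {
    f <- tempfile(fileext = ".csv")
    write_force_curve(cur, f, units = units)
    back <- read_force_curve(f, units = units)
    expect_equal(back$h, cur$h, tolerance = 1e-12)
    expect_equal(back$F, cur$F, tolerance = 1e-12)
    unlink(f)
  }
  # malformed input reports the offending line
  f <- tempfile(fileext = ".csv")
  writeLines(c("# comment", "1e-9,2e-9", "oops,not-a-number"), f)
  expect_error(read_force_curve(f), "line 3")
  unlink(f)
  expect_error(read_force_curve("/nonexistent/file.csv"), "not found")
})
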