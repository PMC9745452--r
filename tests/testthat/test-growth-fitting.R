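test_that("one-phase fit recovers generating parameters on noiseless data", {
  d <- noiseless_points(DESIGN_40_TIMES, ymax = 5, k = 0.0622)
  f <- fit_one_phase(d$times, d$values)
  expect_s3_class(f, "growth_fit")
  expect_true(f$converged)
  expect_equal(f$ymax, 5, tolerance = 1e-6)
  expect_equal(f$k, 0.0622, tolerance = 1e-6)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
})

test_that("noiseless recovery holds across the parameter box (property)", {
  set.seed(21)
  for (i in 1:20) {
    ymax <- runif(1, 1, 200); k <- runif(1, 0.01, 0.5)
    times <- seq(0.2, 5, length.out = 8) / k   # grid spanning the rise
    d <- noiseless_points(times, ymax, k, n = 2)
    f <- fit_one_phase(d$times, d$values)
    expect_lt(abs(f$k - k) / k, 1e-6)
    expect_lt(abs(f$ymax - ymax) / ymax, 1e-6)
  }
})

test_that("degenerate inputs are flagged, not mis-fitted", {
  t <- DESIGN_40_TIMES
  zero <- fit_one_phase(t, rep(0, 6))
  expect_true(zero$degenerate)
  expect_false(zero$converged)
  # linear (non-saturating) data drives k to the lower bound
  lin <- fit_one_phase(t, 0.1 * t)
  expect_true(lin$degenerate)
  expect_match(lin$diagnostic, "bound")
  expect_error(fit_one_phase(c(10, 10, 20), c(1, 1, 2)),
               "3 distinct time points")
  expect_error(fit_one_phase(t, c(-1, 1, 2, 3, 4, 5)), "non-negative")
})

test_that("linear fit matches OLS ground truth", {
  t <- DESIGN_40_TIMES
  f <- fit_linear(t, 2 * t)
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$r_squared, 1)
  const <- fit_linear(t, rep(3, 6))
  expect_equal(const$slope, 0, tolerance = 1e-12)
  expect_equal(const$r_squared, 0)
  expect_error(fit_linear(c(5, 5), c(1, 2)), "2 distinct time points")
  # noisy slope lands within 3 SE of truth (OLS sampling theory)
  set.seed(31)
  tt <- rep(seq(1, 60, length.out = 20), 3)
  fn <- fit_linear(tt, 2 * tt + rnorm(60))
  expect_lt(abs(fn$slope - 2), 3 * fn$slope_se)
})

test_that("predict obeys the model contracts", {
  d <- noiseless_points(DESIGN_40_TIMES, 5, 0.0622)
  f <- fit_one_phase(d$times, d$values)
  expect_equal(predict(f, 0), 0)
  expect_equal(predict(f, 1e6), 5, tolerance = 1e-9)
  # Ymax = 5, k = ln(10)/37 passes within 0.005 of 4.0 at t = 25.9
  g <- f; g$ymax <- 5; g$k <- log(10) / 37
  expect_equal(predict(g, 25.9), 4, tolerance = 0.001)
  expect_error(predict(f, -1), "non-negative")
  expect_error(predict(fit_one_phase(DESIGN_40_TIMES, rep(0, 6)), 10),
               "non-converged")
})

test_that("time_to_threshold inverts the fitted curve", {
  d <- noiseless_points(DESIGN_40_TIMES, 5, log(10) / 37)
  f <- fit_one_phase(d$times, d$values)
  t4 <- time_to_threshold(f, 4)
  expect_equal(t4, -log(1 - 4 / 5) / (log(10) / 37), tolerance = 1e-9)
  expect_equal(t4, 25.87, tolerance = 1e-3)           # ~ 25.9 s
  expect_equal(predict(f, t4), 4, tolerance = 1e-9)
  # half-rise symmetry: t(Ymax/2) = ln(2)/k
  expect_equal(time_to_threshold(f, f$ymax / 2), log(2) / f$k,
               tolerance = 1e-9)
  expect_error(time_to_threshold(f, 6), "unreachable threshold.*5")
  lf <- fit_linear(DESIGN_40_TIMES, 2 * DESIGN_40_TIMES + 1)
  expect_equal(predict(lf, time_to_threshold(lf, 40)), 40,
               tolerance = 1e-9)
})

test_that("threshold/predict round-trip is exact over the rise (property)", {
  set.seed(41)
  for (i in 1:10) {
    ymax <- runif(1, 2, 50); k <- runif(1, 0.02, 0.3)
    d <- noiseless_points(seq(0.3, 5, length.out = 8) / k, ymax, k)
    f <- fit_one_phase(d$times, d$values)
    for (t0 in runif(4, 0.01, 5 / k)) {
      expect_equal(time_to_threshold(f, predict(f, t0)), t0,
                   tolerance = 1e-6)
    }
  }
})

test_that("r_squared is equivariant under time rescaling", {
  set.seed(51)
  t <- DESIGN_40_TIMES
  y <- one_phase_mean(t, 10, 0.08) + rnorm(6, 0, 0.3)
  y <- pmax(y, 0)
  f1 <- fit_one_phase(t, y)
  f2 <- fit_one_phase(t * 10, y)   # seconds -> deciseconds
  expect_equal(f2$k, f1$k / 10, tolerance = 1e-5)
  expect_equal(f2$r_squared, f1$r_squared, tolerance = 1e-8)
})

test_that("fits serialise to JSON records", {
  d <- noiseless_points(DESIGN_40_TIMES, 5, 0.0622)
  f <- fit_one_phase(d$times, d$values)
  path <- withr::local_tempfile(fileext = ".json")
  df <- fits_to_json(list(f), path)
  expect_true(file.exists(path))
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$k, f$k, tolerance = 1e-12)
  expect_equal(back$model, "one_phase_association")
})
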