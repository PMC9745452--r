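test_that("truth_from_decay_time inverts the decay definition", {
  expect_equal(truth_from_decay_time(46.9)$k, log(10) / 46.9,
               tolerance = 1e-12)
  expect_equal(truth_from_decay_time(46.9)$k, 0.04910, tolerance = 1e-4)
  expect_equal(truth_from_decay_time(log(10))$k, 1, tolerance = 1e-12)
  # plateau solved from the 4-mm anchor: published pair (37.0 s, 25.9 s)
  tr <- truth_from_decay_time(37.0, anchor = c(25.9, 4))
  expect_equal(tr$ymax, 5.00, tolerance = 1e-3)
  # anchor later than the plateau allows -> calibration error
  expect_error(truth_from_decay_time(2, anchor = c(60, 4)),
               "inconsistent anchor")
  expect_error(truth_from_decay_time(-1), "t90 must be")
  expect_error(response_truth(5, 0.1, noise_sd = 1, noise_cv = 0.1),
               "exactly one")
})

test_that("pop_probability is a monotone logistic with power dominance", {
  pm <- list(`40` = c(intercept = -6, slope = 0.06),
             `50` = c(intercept = -5, slope = 0.08))
  expect_equal(pop_probability(40, 80, list(`40` = c(intercept = -4,
                                                     slope = 0.05))),
               0.5, tolerance = 1e-12)   # logistic midpoint
  flat <- pop_probability(40, c(0, 30, 60),
                          list(`40` = c(intercept = -2, slope = 0)))
  expect_true(all(flat == flat[1]))
  expect_lt(pop_probability(40, 60, list(`40` = c(intercept = -20,
                                                  slope = 0))), 1e-8)
  tt <- seq(0, 60, by = 5)
  p40 <- pop_probability(40, tt, pm); p50 <- pop_probability(50, tt, pm)
  expect_true(all(diff(p40) >= 0))
  expect_true(all(p50 > p40))
})

test_that("simulate_experiment is deterministic and noiseless-exact", {
  cfg <- mini_config(noiseless = TRUE)
  r1 <- simulate_experiment(cfg, seed = 5)
  expect_identical(r1, simulate_experiment(cfg, seed = 5))
  expect_false(identical(r1, simulate_experiment(cfg, seed = 6)))
  # noiseless records sit exactly on their truth curves
  tr <- cfg$truths[["40.10.depth"]]
  expect_equal(r1$depth_a_mm,
               tr$ymax * (1 - exp(-tr$k * r1$time_s)), tolerance = 1e-12)
  # geometry coupling c = 0.5 a, d = 0.8 b (synthetic convention)
  expect_equal(r1$depth_c_mm, 0.5 * r1$depth_a_mm, tolerance = 1e-12)
  expect_equal(r1$surf_d_mm, 0.8 * r1$diam_b_mm, tolerance = 1e-12)
  expect_equal(nrow(r1), length(DESIGN_40_TIMES) * cfg$n_per_cell)
  # simulated records pass validation, including the strict design
  expect_equal(nrow(validate_records(r1, strict_design = TRUE)$records),
               nrow(r1))
})

test_that("per-cell streams make cells independent of design extension", {
  small <- experiment_config(times = list(`40` = c(10, 20)), forces = 10,
                             n_per_cell = 4)
  big <- experiment_config(times = list(`40` = c(10, 20, 30)),
                           forces = c(10, 30), n_per_cell = 4)
  rs <- simulate_experiment(small, seed = 9)
  rb <- simulate_experiment(big, seed = 9)
  shared <- rb[rb$cf_g == 10 & rb$time_s %in% c(10, 20), ]
  rownames(shared) <- NULL
  expect_equal(shared, rs)
})

test_that("noise is truncated at zero by resampling, no point mass", {
  tr <- response_truth(ymax = 0.5, k = 0.05, noise_sd = 0.4)
  d <- simulate_response_endpoints(tr, c(2, 5), 500, seed = 13)
  expect_true(all(d$value >= 0))
  expect_lt(mean(d$value == 0), 0.005)
})

test_that("simulate_li_trace has the stated grid and curve", {
  tr <- response_truth(ymax = 100, k = 0.1, noise_sd = 0)
  x <- simulate_li_trace(tr, 60, rate = 10)
  expect_length(x$times, 601)
  # 1 - exp(-ln 10) = 0.9 of plateau at t = ln(10)/k
  t90 <- log(10) / 0.1
  expect_equal(x$li_values[which.min(abs(x$times - t90))], 90,
               tolerance = 1e-3)
  n1 <- simulate_li_trace(response_truth(100, 0.1, noise_sd = 2),
                          30, 10, seed = 3)
  n2 <- simulate_li_trace(response_truth(100, 0.1, noise_sd = 2),
                          30, 10, seed = 3)
  expect_identical(n1, n2)
})

test_that("calibration round-trips through the full estimator", {
  cal <- calibration_table()
  # every bundled decay time: calibrate -> noiseless simulate -> fit ->
  # decay statistic returns the calibrating t90
  for (p in c("40", "50")) {
    times <- if (p == "40") DESIGN_40_TIMES else DESIGN_50_TIMES
    for (cf in c("10", "30", "50")) {
      for (resp in c("li_drop", "depth", "diameter")) {
        t90 <- cal$decay_times_s[[resp]][[p]][[cf]]
        tr <- truth_from_decay_time(t90, ymax = 10, noise_sd = 0)
        d <- simulate_response_endpoints(tr, times, 2, seed = 1)
        f <- fit_one_phase(d$time_s, d$value)
        expect_equal(time_to_90_decay(f)$t90, t90, tolerance = 1e-6)
      }
    }
  }
})

test_that("generator pop incidence yields a positive trend in expectation", {
  cfg <- experiment_config(times = list(`50` = DESIGN_50_TIMES),
                           forces = 30, n_per_cell = 10)
  zs <- sapply(1:40, function(s) {
    rec <- simulate_experiment(cfg, seed = 1000 + s)
    agg <- aggregate(steam_pop ~ time_s, rec, sum)
    tryCatch(cochran_armitage_trend(agg$steam_pop, rep(10, nrow(agg)),
                                    scores = agg$time_s)$z_statistic,
             error = function(e) NA)   # all-zero pop tables carry no signal
  })
  expect_gt(mean(zs, na.rm = TRUE), 0.5)
})
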