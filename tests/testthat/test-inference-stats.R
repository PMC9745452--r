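test_that("pearson_correlation matches hand-computed oracles", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_correlation(x, x)$r, 1)
  expect_equal(pearson_correlation(x, -2 * x + 7)$r, -1)
  # hand arithmetic: r = 6.5 / sqrt(5 * 8.75)
  cr <- pearson_correlation(x, c(1, 2, 3, 5))
  expect_equal(cr$r, 6.5 / sqrt(5 * 8.75), tolerance = 1e-12)
  expect_equal(cr$r, 0.9827, tolerance = 1e-4)
  expect_equal(cr$n, 4)
  expect_error(pearson_correlation(c(1, 1, 1), c(1, 2, 3)),
               "constant input")
  expect_error(pearson_correlation(1:2, 1:2), "at least 3")
})

test_that("trend test reproduces the hand-enumerated Z values", {
  flat <- cochran_armitage_trend(c(5, 5, 5), c(10, 10, 10),
                                 scores = c(1, 2, 3))
  expect_equal(flat$z_statistic, 0)
  expect_equal(flat$p_value, 1)
  # numerator 5, variance 25/9 -> Z = 3 exactly
  up <- cochran_armitage_trend(c(0, 0, 5), c(10, 10, 10),
                               scores = c(1, 2, 3))
  expect_equal(up$z_statistic, 3, tolerance = 1e-12)
  # reversal symmetry
  dn <- cochran_armitage_trend(c(5, 0, 0), c(10, 10, 10),
                               scores = c(1, 2, 3))
  expect_equal(dn$z_statistic, -3, tolerance = 1e-12)
  expect_error(cochran_armitage_trend(c(0, 0), c(5, 5), c(1, 2)),
               "zero variance")
  expect_error(cochran_armitage_trend(c(1, 2), c(5, 5), c(2, 1)),
               "strictly increasing")
})

test_that("trend Z is invariant under positive affine score maps", {
  s <- c(10, 20, 30, 40)
  x <- c(0, 1, 2, 4); n <- rep(10, 4)
  z0 <- cochran_armitage_trend(x, n, s)$z_statistic
  for (ab in list(c(2, 0), c(0.1, 5), c(7, -3))) {
    z <- cochran_armitage_trend(x, n, ab[1] * s + ab[2])$z_statistic
    expect_equal(z, z0, tolerance = 1e-12)
  }
})

test_that("Monte-Carlo permutation agrees with exact enumeration", {
  set.seed(71)
  tables <- list(list(x = c(0, 1, 3), n = c(5, 5, 5)),
                 list(x = c(2, 0, 1), n = c(4, 5, 6)),
                 list(x = c(0, 2, 4), n = c(5, 4, 5)),
                 list(x = c(1, 1, 4), n = c(5, 5, 5)))
  for (tb in tables) {
    ex <- cochran_armitage_trend(tb$x, tb$n, seq_along(tb$n),
                                 exact = TRUE)
    mc <- cochran_armitage_trend(tb$x, tb$n, seq_along(tb$n),
                                 n_perm = 1e4)
    expect_lt(abs(mc$p_mc - ex$p_exact), 0.02)
  }
})

test_that("trend-test type-I error is near nominal under the null", {
  set.seed(81)
  rej <- 0L; n_ok <- 0L
  for (i in 1:2000) {
    x <- rbinom(6, 10, 0.5)
    if (sum(x) == 0L || sum(x) == 60L) next
    n_ok <- n_ok + 1L
    p <- cochran_armitage_trend(x, rep(10, 6),
                                scores = DESIGN_40_TIMES)$p_value
    if (p < 0.05) rej <- rej + 1L
  }
  expect_gte(rej / n_ok, 0.03)
  expect_lte(rej / n_ok, 0.07)
})

test_that("one-sided alternatives and sign conventions are coherent", {
  x <- c(0, 1, 4); n <- c(10, 10, 10)
  two <- cochran_armitage_trend(x, n, 1:3)
  up <- cochran_armitage_trend(x, n, 1:3, alternative = "greater")
  expect_equal(two$p_value, 2 * up$p_value, tolerance = 1e-12)
})

test_that("compare_power_groups marks separation and skips orphan cells", {
  set.seed(91)
  base <- expand.grid(time_s = c(10, 20), replicate = 1:10)
  mk <- function(power, mu)
    make_record(power_w = power, time_s = base$time_s,
                replicate = base$replicate,
                li_drop_ohm = rnorm(nrow(base), mu, 1))
  rec <- rbind(mk(40, 0), mk(50, 5))
  out <- compare_power_groups(rec, "li_drop_ohm")
  expect_true(all(out$significant))
  # identical samples -> p = 1, no mark
  same <- rbind(make_record(power_w = 40, replicate = 1:5,
                            li_drop_ohm = c(1, 2, 3, 4, 5)),
                make_record(power_w = 50, replicate = 1:5,
                            li_drop_ohm = c(1, 2, 3, 4, 5)))
  s <- compare_power_groups(same, "li_drop_ohm")
  expect_equal(s$p_value, 1)
  expect_false(s$significant)
  # a 5 s cell existing only at 50 W is skipped and logged
  orphan <- rbind(rec, make_record(power_w = 50, time_s = 5,
                                   replicate = 1:10))
  o <- compare_power_groups(orphan, "li_drop_ohm")
  expect_false(5 %in% o$time_s)
  expect_true(5 %in% attr(o, "skipped")$time_s)
})
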