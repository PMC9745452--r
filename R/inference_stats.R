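# Correlation, trend, and group-comparison statistics.
#
# The Cochran-Armitage trend test is implemented in full (asymptotic Z,
# exact permutation by enumeration, Monte-Carlo permutation); Pearson's
# p-value and the Welch comparison delegate to stats::cor.test /
# stats::t.test behind the module's result types.

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-zero variance.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return Object of class `correlation_result`: `r`, `p_value`, `n`.
#' @export
pearson_correlation <- function(x, y, alternative = "two.sided") {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("constant input: correlation undefined for zero variance",
         call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson",
                        alternative = alternative)
  structure(list(r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x)),
            class = "correlation_result")
}

ca_z <- function(successes, totals, scores) {
  N <- sum(totals); S <- sum(successes)
  pbar <- S / N
  num <- sum(scores * (successes - totals * pbar))
  v <- pbar * (1 - pbar) * (sum(totals * scores^2) -
                            sum(totals * scores)^2 / N)
  if (v <= 0) return(NA_real_)
  num / sqrt(v)
}

# Exact permutation null of the trend statistic: condition on the pooled
# success count S; group success counts follow a multivariate
# hypergeometric law. Enumerates all compositions (feasible for N <= ~30).
ca_exact_p <- function(successes, totals, scores, z_obs,
                       alternative = "two.sided") {
  g <- length(totals); S <- sum(successes); N <- sum(totals)
  p_extreme <- 0
  rec <- function(i, rem, xs, logw) {
    if (i == g) {
      if (rem > totals[g]) return(invisible(NULL))
      xs[g] <- rem
      logw <- logw + lchoose(totals[g], rem)
      z <- ca_z(xs, totals, scores)
      if (is.na(z)) z <- 0
      hit <- switch(alternative,
                    two.sided = abs(z) >= abs(z_obs) - 1e-12,
                    greater = z >= z_obs - 1e-12,
                    less = z <= z_obs + 1e-12)
      if (hit) p_extreme <<- p_extreme + exp(logw - lchoose(N, S))
      return(invisible(NULL))
    }
    for (x in 0:min(totals[i], rem)) {
      xs[i] <- x
      rec(i + 1L, rem - x, xs, logw + lchoose(totals[i], x))
    }
  }
  rec(1L, S, integer(g), 0)
  min(1, p_extreme)
}

#' Cochran-Armitage test for trend in proportions
#'
#' Tests for a monotone trend in success probability across ordered groups
#' (here: steam-pop incidence across RF delivery times). The statistic is
#' \deqn{Z = \frac{\sum_i s_i (x_i - n_i \bar p)}{\sqrt{\bar p (1-\bar p)\left[\sum_i n_i s_i^2 - (\sum_i n_i s_i)^2 / N\right]}}}
#' with group scores \eqn{s_i}, successes \eqn{x_i}, sizes \eqn{n_i} and
#' pooled proportion \eqn{\bar p}; Z is invariant under positive affine
#' transformation of the scores and flips sign when the group order is
#' reversed. P-values are asymptotic normal by default; `exact = TRUE`
#' enumerates the conditional permutation null exactly (multivariate
#' hypergeometric given the pooled success count), and `n_perm > 0` draws
#' a Monte-Carlo permutation p instead.
#'
#' @param successes,totals Integer vectors per ordered group,
#'   `0 <= successes <= totals`, >= 2 groups.
#' @param scores Strictly increasing group scores; defaults to the
#'   delivery times when groups are so labelled, else `1:g`.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @param exact Compute the exact permutation p by enumeration.
#' @param n_perm If > 0, Monte-Carlo permutation p with this many draws.
#' @return Object of class `trend_test_result`: `z_statistic`, `p_value`,
#'   `scores`, `method`, and `p_exact` / `p_mc` when requested.
#' @examples
#' cochran_armitage_trend(c(0, 0, 5), c(10, 10, 10), scores = c(1, 2, 3))
#' @export
cochran_armitage_trend <- function(successes, totals, scores = NULL,
                                   alternative = c("two.sided", "greater",
                                                   "less"),
                                   exact = FALSE, n_perm = 0) {
  alternative <- match.arg(alternative)
  successes <- as.numeric(successes); totals <- as.numeric(totals)
  if (length(successes) != length(totals) || length(totals) < 2L)
    stop("need >= 2 groups with matching successes/totals", call. = FALSE)
  if (any(successes < 0) || any(successes > totals) || any(totals <= 0))
    stop("require 0 <= successes <= totals, totals > 0", call. = FALSE)
  if (is.null(scores)) scores <- seq_along(totals)
  scores <- as.numeric(scores)
  if (length(scores) != length(totals) || any(diff(scores) <= 0))
    stop("scores must be strictly increasing, one per group", call. = FALSE)

  S <- sum(successes); N <- sum(totals)
  if (S == 0 || S == N)
    stop("zero variance: pooled table is all-failure or all-success",
         call. = FALSE)

  z <- ca_z(successes, totals, scores)
  p_asym <- switch(alternative,
                   two.sided = 2 * stats::pnorm(-abs(z)),
                   greater = stats::pnorm(z, lower.tail = FALSE),
                   less = stats::pnorm(z))

  res <- list(z_statistic = z, p_value = p_asym, scores = scores,
              method = "asymptotic", alternative = alternative)

  if (exact) {
    res$p_exact <- ca_exact_p(successes, totals, scores, z,
                              alternative = alternative)
    res$p_value <- res$p_exact
    res$method <- "exact_permutation"
  }
  if (n_perm > 0) {
    g <- length(totals)
    # draw group success splits from the conditional null by permuting
    # the pooled 0/1 outcomes across groups
    pool <- rep(c(1, 0), c(S, N - S))
    idx <- rep(seq_len(g), totals)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      xs <- tapply(sample(pool), idx, sum)
      zb <- ca_z(as.numeric(xs), totals, scores)
      if (is.na(zb)) zb <- 0
      hit <- switch(alternative,
                    two.sided = abs(zb) >= abs(z) - 1e-12,
                    greater = zb >= z - 1e-12,
                    less = zb <= z + 1e-12)
      if (hit) hits <- hits + 1L
    }
    res$p_mc <- hits / n_perm
    if (!exact) {
      res$p_value <- res$p_mc
      res$method <- "mc_permutation"
    }
  }
  structure(res, class = "trend_test_result")
}

#' Per-time comparison of the two power groups
#'
#' Welch's unequal-variance two-sample comparison of a response between
#' the 40 W and 50 W groups at each shared (delivery time, contact force)
#' cell, two-sided at alpha = 0.05, no multiplicity correction (matching
#' the per-point asterisk-marking convention of dose-response figures).
#' Cells present in only one power group (the 5 s point exists only in the
#' 50 W design) are skipped and logged.
#'
#' @param records Records data.frame in the [records_schema()] layout.
#' @param response Column to compare (e.g. `"li_drop_ohm"`,
#'   `"depth_a_mm"`).
#' @param alpha Significance level for the `significant` mark.
#' @return data.frame with one row per tested (cf_g, time_s) cell:
#'   `statistic`, `p_value`, `significant`; skipped cells are returned in
#'   the `"skipped"` attribute with reasons.
#' @export
compare_power_groups <- function(records, response = "li_drop_ohm",
                                 alpha = 0.05) {
  stopifnot(is.data.frame(records), response %in% names(records))
  out <- list(); skipped <- list()
  for (cf in sort(unique(records$cf_g))) {
    for (tt in sort(unique(records$time_s[records$cf_g == cf]))) {
      g40 <- records[records$cf_g == cf & records$time_s == tt &
                     records$power_w == 40, response]
      g50 <- records[records$cf_g == cf & records$time_s == tt &
                     records$power_w == 50, response]
      if (length(g40) < 2L || length(g50) < 2L) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          cf_g = cf, time_s = tt,
          reason = sprintf("insufficient replicates (40 W: %d, 50 W: %d)",
                           length(g40), length(g50)),
          stringsAsFactors = FALSE)
        next
      }
      tst <- if (stats::sd(g40) == 0 && stats::sd(g50) == 0 &&
                 g40[1] == g50[1])
        list(statistic = 0, p.value = 1)  # identical constant samples
      else stats::t.test(g40, g50, var.equal = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        cf_g = cf, time_s = tt, response = response,
        statistic = unname(tst$statistic), p_value = tst$p.value,
        significant = tst$p.value < alpha, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(cf_g = numeric(), time_s = numeric(),
                         response = character(), statistic = numeric(),
                         p_value = numeric(), significant = logical())
  attr(res, "skipped") <- if (length(skipped)) do.call(rbind, skipped)
                          else NULL
  res
}

#' @export
print.trend_test_result <- function(x, ...) {
  cat(sprintf("<trend_test> Z = %.4f, p = %.4g (%s, %s)\n",
              x$z_statistic, x$p_value, x$method, x$alternative))
  invisible(x)
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation> r = %.4f, p = %.4g, n = %d\n",
              x$r, x$p_value, x$n))
  invisible(x)
}
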