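# Growth-curve fitting: one-phase association (saturating exponential) and
# ordinary linear fits of a response against RF delivery time, plus
# prediction and threshold-crossing inversion.
#
# The one-phase model Y(t) = Ymax * (1 - exp(-k t)) is fitted by profiled
# least squares: for fixed k the plateau has the closed-form solution
# Ymax(k) = sum(y g) / sum(g^2) with g = 1 - exp(-k t), so the sum of
# squares is minimised over k alone by bounded Brent search, then polished
# on a shrinking bracket. This is far more robust than a 2-D solver on
# noiseless or degenerate data and reaches the same optimum.

K_LOWER <- 1e-6
K_UPPER <- 10

new_growth_fit <- function(model, response_label, n_points, t_max,
                           r_squared, converged, degenerate, diagnostic,
                           ymax = NA_real_, k = NA_real_,
                           slope = NA_real_, intercept = NA_real_,
                           slope_se = NA_real_) {
  structure(list(model = model, response_label = response_label,
                 ymax = ymax, k = k, slope = slope, intercept = intercept,
                 slope_se = slope_se, r_squared = r_squared,
                 n_points = n_points, t_max = t_max, converged = converged,
                 degenerate = degenerate, diagnostic = diagnostic),
            class = "growth_fit")
}

r2_of <- function(values, fitted, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(values))
  ssres <- sum(weights * (values - fitted)^2)
  sstot <- sum(weights * (values - stats::weighted.mean(values, weights))^2)
  if (sstot <= .Machine$double.eps * max(1, sum(values^2))) return(0)
  max(0, min(1, 1 - ssres / sstot))
}

#' Fit a one-phase association growth curve
#'
#' Least-squares fit of the zero-intercept saturating exponential
#' \deqn{Y(t) = Y_{max}\,(1 - e^{-k t})}
#' to pooled endpoint observations (each duration is a different lesion, so
#' all replicates at all durations enter as independent points). Plateau
#' `ymax` carries the response units; `k` (1/s) sets the kinetics. Fits
#' whose rate lands within 1% of the search bounds `[1e-6, 10]` 1/s, or
#' with a non-positive plateau, are flagged degenerate; downstream decay
#' statistics refuse to run on degenerate fits.
#'
#' @param times RF delivery times (s), at least 3 distinct values.
#' @param values Non-negative response observations, same length.
#' @param weights Optional non-negative case weights (default unweighted).
#' @param response_label One of `"li_drop"`, `"depth"`, `"diameter"`,
#'   `"volume"` (metadata only).
#' @return Object of class `growth_fit` with fields `model`, `ymax`, `k`,
#'   `r_squared`, `n_points`, `converged`, `degenerate`, `diagnostic`.
#' @seealso [fit_linear()], [time_to_threshold()], [time_to_90_decay()]
#' @examples
#' t <- c(10, 20, 30, 40, 50, 60)
#' y <- 5 * (1 - exp(-0.0622 * t))
#' fit_one_phase(t, y)
#' @export
fit_one_phase <- function(times, values, weights = NULL,
                          response_label = c("li_drop", "depth",
                                             "diameter", "volume")) {
  response_label <- match.arg(response_label)
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values))
    stop("times and values must have equal length", call. = FALSE)
  if (length(unique(times)) < 3L)
    stop("need at least 3 distinct time points", call. = FALSE)
  if (any(!is.finite(times)) || any(!is.finite(values)))
    stop("non-finite inputs", call. = FALSE)
  if (any(times < 0)) stop("times must be non-negative", call. = FALSE)
  if (any(values < 0)) stop("values must be non-negative", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(values))
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)

  n <- length(values)
  t_max <- max(times)

  if (all(values == 0)) {
    return(new_growth_fit("one_phase_association", response_label, n, t_max,
                          r_squared = 0, converged = FALSE, degenerate = TRUE,
                          diagnostic = "all response values are zero"))
  }

  prof_ymax <- function(k) {
    g <- 1 - exp(-k * times)
    den <- sum(weights * g^2)
    if (den <= 0) return(0)
    sum(weights * values * g) / den
  }
  sse <- function(k) {
    g <- 1 - exp(-k * times)
    ym <- prof_ymax(k)
    sum(weights * (values - ym * g)^2)
  }

  # coarse log-spaced scan guards Brent against flat/multimodal stretches
  grid <- exp(seq(log(K_LOWER), log(K_UPPER), length.out = 60))
  sse_grid <- vapply(grid, sse, numeric(1))
  i0 <- which.min(sse_grid)
  lo <- grid[max(1L, i0 - 1L)]; hi <- grid[min(length(grid), i0 + 1L)]
  opt <- stats::optimize(sse, interval = c(lo, hi), tol = 1e-12)
  # one polish pass on a tight bracket around the optimum
  span <- max(opt$minimum * 1e-3, 1e-9)
  opt2 <- stats::optimize(sse, interval = c(max(K_LOWER, opt$minimum - span),
                                            min(K_UPPER, opt$minimum + span)),
                          tol = .Machine$double.eps^0.75)
  k_hat <- if (opt2$objective <= opt$objective) opt2$minimum else opt$minimum
  ymax_hat <- prof_ymax(k_hat)

  fitted <- ymax_hat * (1 - exp(-k_hat * times))
  r2 <- r2_of(values, fitted, weights)

  degenerate <- FALSE; diagnostic <- NA_character_
  if (k_hat <= K_LOWER * 1.01 || k_hat >= K_UPPER * 0.99) {
    degenerate <- TRUE
    diagnostic <- sprintf(
      "rate estimate k = %.3g 1/s within 1%% of search bound [%g, %g]; %s",
      k_hat, K_LOWER, K_UPPER,
      if (k_hat <= K_LOWER * 1.01)
        "response looks non-saturating (near-linear) over the observed times"
      else "response saturates faster than the time resolution")
  } else if (ymax_hat <= 0) {
    degenerate <- TRUE
    diagnostic <- "non-positive plateau estimate"
  }

  new_growth_fit("one_phase_association", response_label, n, t_max,
                 r_squared = r2, converged = !degenerate,
                 degenerate = degenerate, diagnostic = diagnostic,
                 ymax = ymax_hat, k = k_hat)
}

#' Fit a straight line to response versus time
#'
#' Ordinary least squares `value ~ time` with intercept, used for responses
#' that grow linearly over the observed window (lesion volume over 5-60 s).
#'
#' @inheritParams fit_one_phase
#' @return Object of class `growth_fit` with `model = "linear"`, fields
#'   `slope` (response units per s), `intercept`, `slope_se`, `r_squared`.
#' @export
fit_linear <- function(times, values, weights = NULL,
                       response_label = c("volume", "li_drop", "depth",
                                          "diameter")) {
  response_label <- match.arg(response_label)
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values))
    stop("times and values must have equal length", call. = FALSE)
  if (length(unique(times)) < 2L)
    stop("need at least 2 distinct time points", call. = FALSE)
  fit <- if (is.null(weights)) stats::lm(values ~ times)
         else stats::lm(values ~ times, weights = weights)
  co <- stats::coef(fit)
  # summary.lm warns on an exactly collinear (zero-residual) fit; the SE
  # is still well defined (zero), so keep it quiet
  se <- tryCatch(
    suppressWarnings(summary(fit)$coefficients["times", "Std. Error"]),
    error = function(e) NA_real_)
  new_growth_fit("linear", response_label, length(values), max(times),
                 r_squared = r2_of(values, stats::fitted(fit), weights),
                 converged = TRUE, degenerate = FALSE,
                 diagnostic = NA_character_,
                 slope = unname(co["times"]), intercept = unname(co[1]),
                 slope_se = se)
}

#' Predict the fitted mean response
#'
#' @param object A converged [fit_one_phase()] or [fit_linear()] fit.
#' @param t Times (s), non-negative.
#' @param ... Unused.
#' @return Numeric vector of model means at `t`; zero at `t = 0` for the
#'   one-phase model.
#' @export
predict.growth_fit <- function(object, t, ...) {
  t <- as.numeric(t)
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  if (!isTRUE(object$converged))
    stop("cannot predict from a non-converged fit: ", object$diagnostic,
         call. = FALSE)
  switch(object$model,
         one_phase_association = object$ymax * (1 - exp(-object$k * t)),
         linear = object$intercept + object$slope * t,
         stop("unknown model ", object$model, call. = FALSE))
}

#' Time for the fitted curve to reach a response threshold
#'
#' Closed-form inversion of the fitted mean. For the one-phase model
#' \eqn{t = -\ln(1 - y^*/Y_{max})/k}; thresholds at or above the plateau
#' are unreachable and raise an error carrying the plateau value. For the
#' linear model \eqn{t = (y^* - intercept)/slope}.
#'
#' @param fit A converged `growth_fit`.
#' @param y_star Positive threshold in response units (e.g. 4 mm depth,
#'   the atrial-wall transmurality target).
#' @return Crossing time (s); `predict(fit, result)` equals `y_star` to
#'   1e-9 relative.
#' @export
time_to_threshold <- function(fit, y_star) {
  stopifnot(inherits(fit, "growth_fit"))
  if (!isTRUE(fit$converged))
    stop("fit not converged: ", fit$diagnostic, call. = FALSE)
  if (!is.finite(y_star) || y_star <= 0)
    stop("y_star must be positive", call. = FALSE)
  if (fit$model == "one_phase_association") {
    if (y_star >= fit$ymax)
      stop(sprintf(
        "unreachable threshold: y_star = %g is at or above the plateau Ymax = %g",
        y_star, fit$ymax), call. = FALSE)
    -log(1 - y_star / fit$ymax) / fit$k
  } else {
    if (fit$slope <= 0)
      stop("non-positive slope: threshold never reached", call. = FALSE)
    (y_star - fit$intercept) / fit$slope
  }
}

#' Serialise fits to JSON-ready records
#'
#' @param fits List of `growth_fit` objects (optionally named).
#' @param path Optional file to write JSON to.
#' @return (Invisibly when writing) a data.frame with one row per fit.
#' @export
fits_to_json <- function(fits, path = NULL) {
  if (inherits(fits, "growth_fit")) fits <- list(fits)
  df <- do.call(rbind, lapply(fits, function(f)
    data.frame(model = f$model, response = f$response_label,
               ymax = f$ymax, k = f$k, slope = f$slope,
               intercept = f$intercept, r_squared = f$r_squared,
               n_points = f$n_points, converged = f$converged,
               stringsAsFactors = FALSE)))
  if (!is.null(path)) {
    jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
    return(invisible(df))
  }
  df
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit:%s> %s, n = %d, R^2 = %.4f\n",
              x$model, x$response_label, x$n_points, x$r_squared))
  if (x$model == "one_phase_association")
    cat(sprintf("  Ymax = %.4g, k = %.4g 1/s (t90 = %.1f s)\n",
                x$ymax, x$k, log(10) / x$k))
  else
    cat(sprintf("  slope = %.4g /s, intercept = %.4g\n",
                x$slope, x$intercept))
  if (isTRUE(x$degenerate)) cat("  DEGENERATE: ", x$diagnostic, "\n")
  invisible(x)
}
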