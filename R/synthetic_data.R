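# Synthetic-experiment generator: a stated world with the statistical
# structure the analysis assumes. Mean responses follow the one-phase
# association curve; endpoint noise is additive Gaussian (absolute SD for
# lesion axes, CV-proportional for the LI drop), truncated at zero by
# resampling; steam pops follow a per-power logistic in delivery time.
# Every cell of the factorial design gets its own RNG stream derived from
# the master seed, so adding cells never perturbs existing ones.

#' Generating truth for one response
#'
#' @param ymax Plateau, response units (> 0).
#' @param k Rate constant (1/s, > 0); the decay time is `ln(10)/k`.
#' @param noise_sd Additive noise SD (response units). Exactly one of
#'   `noise_sd`/`noise_cv` must be given (0 is a valid SD).
#' @param noise_cv Multiplicative coefficient of variation: per-point SD is
#'   `noise_cv` x mean.
#' @return Object of class `response_truth`.
#' @export
response_truth <- function(ymax, k, noise_sd = NULL, noise_cv = NULL) {
  if (!is.finite(ymax) || ymax <= 0) stop("ymax must be > 0", call. = FALSE)
  if (!is.finite(k) || k <= 0) stop("k must be > 0", call. = FALSE)
  if (is.null(noise_sd) == is.null(noise_cv))
    stop("exactly one of noise_sd / noise_cv must be set", call. = FALSE)
  structure(list(ymax = ymax, k = k, noise_sd = noise_sd,
                 noise_cv = noise_cv),
            class = "response_truth")
}

truth_mean <- function(truth, t) truth$ymax * (1 - exp(-truth$k * t))

truth_sd <- function(truth, t) {
  if (!is.null(truth$noise_sd)) rep(truth$noise_sd, length(t))
  else truth$noise_cv * truth_mean(truth, t)
}

#' Calibrate a generating truth from a published decay time
#'
#' Inverts the decay-time definition: a one-phase curve with decay time
#' `t90` has rate constant `k = ln(10)/t90`. The plateau is either solved
#' from an anchor point `(t*, y*)` on the curve,
#' `ymax = y* / (1 - exp(-k t*))`, or set to a stated default.
#'
#' @param t90 Decay time (s, > 0).
#' @param anchor Optional `c(t, y)`: a time (s) and the response the curve
#'   passes through there (e.g. the 4 mm depth-crossing time).
#' @param ymax Default plateau used when no anchor is given.
#' @param noise_sd,noise_cv Passed to [response_truth()].
#' @return `response_truth`.
#' @examples
#' truth_from_decay_time(37.0, anchor = c(25.9, 4))  # ymax ~ 5 mm
#' @export
truth_from_decay_time <- function(t90, anchor = NULL, ymax = 1,
                                  noise_sd = NULL, noise_cv = NULL) {
  if (!is.finite(t90) || t90 <= 0) stop("t90 must be > 0", call. = FALSE)
  if (is.null(noise_sd) && is.null(noise_cv)) noise_sd <- 0
  k <- log(10) / t90
  if (!is.null(anchor)) {
    stopifnot(length(anchor) == 2L)
    t_star <- anchor[1]; y_star <- anchor[2]
    if (t_star <= 0 || y_star <= 0)
      stop("anchor must have positive time and response", call. = FALSE)
    ymax <- y_star / (1 - exp(-k * t_star))
    if (!is.finite(ymax) || ymax <= y_star)
      stop(sprintf(
        "inconsistent anchor: implied plateau %.4g <= anchor response %.4g",
        ymax, y_star), call. = FALSE)
  }
  response_truth(ymax = ymax, k = k, noise_sd = noise_sd,
                 noise_cv = noise_cv)
}

#' Steam-pop probability
#'
#' Logistic dose-response in delivery time:
#' `p(t) = plogis(intercept + slope * t)` with per-power parameters.
#' With a positive slope the probability is monotone non-decreasing in
#' time; the default 50 W curve dominates the 40 W curve at every time
#' (pops come earlier and more often at higher power).
#'
#' @param power Ablation power (W), used to select the curve.
#' @param t Delivery time(s) (s), >= 0.
#' @param pop_model Named list of `c(intercept, slope)` per power (names
#'   `"40"`, `"50"`, ...), as in `experiment_config()$pop_model`.
#' @return Probabilities in `[0, 1]`.
#' @export
pop_probability <- function(power, t, pop_model) {
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  pm <- pop_model[[as.character(power)]]
  if (is.null(pm)) stop("no pop model for power ", power, call. = FALSE)
  stats::plogis(pm[["intercept"]] + pm[["slope"]] * t)
}

#' The bundled calibration table
#'
#' Reads the calibration shipped with the package: published decay times
#' per (power, contact force) for the LI drop, lesion depth and lesion
#' diameter, the 4-mm depth-crossing anchors, the assumed plateaus (LI
#' drop 120 ohm, diameter 8 mm; provenance "assumed" - the source prints
#' no plateaus), default noise scales, and the synthetic steam-pop model.
#'
#' @return Nested list mirroring the JSON file.
#' @export
calibration_table <- function() {
  path <- system.file("extdata", "calibrated_truths.json",
                      package = "lesionkinetics", mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Factorial experiment configuration
#'
#' Builds the full generator configuration. With no arguments this is the
#' calibrated default world: the published factorial design (40 W at
#' 10-60 s, 50 W at 5-60 s, contact forces 10/30/50 g, n = 10 per cell)
#' with truths calibrated from the bundled decay-time table.
#'
#' @param truths Named list of [response_truth()] keyed
#'   `"<power>.<cf>.<response>"` with responses `li_drop`, `depth`,
#'   `diameter`; defaults to the calibrated table.
#' @param times Named list of per-power time grids (s).
#' @param forces Contact-force levels (g).
#' @param n_per_cell Replicates per (power, cf, time) cell.
#' @param pop_model Per-power logistic `c(intercept, slope)`.
#' @param noiseless Zero out all noise (useful for round-trip checks).
#' @param seed Default master seed carried in the config.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(truths = NULL, times = DESIGN_TIMES,
                              forces = DESIGN_FORCES, n_per_cell = 10,
                              pop_model = NULL, noiseless = FALSE,
                              seed = 1L) {
  cal <- calibration_table()
  if (is.null(pop_model))
    pop_model <- lapply(cal$pop_model, function(x)
      c(intercept = x$intercept, slope = x$slope))
  if (is.null(truths)) {
    truths <- list()
    for (p in names(times)) {
      for (cf in forces) {
        cfs <- as.character(cf)
        li_sd_args <- if (noiseless) list(noise_sd = 0)
                      else list(noise_cv = cal$noise$li_drop_cv)
        truths[[paste(p, cfs, "li_drop", sep = ".")]] <-
          do.call(truth_from_decay_time,
                  c(list(t90 = cal$decay_times_s$li_drop[[p]][[cfs]],
                         ymax = cal$assumed_plateaus$li_drop$value),
                    li_sd_args))
        truths[[paste(p, cfs, "depth", sep = ".")]] <-
          truth_from_decay_time(
            cal$decay_times_s$depth[[p]][[cfs]],
            anchor = c(cal$depth_4mm_anchor_s[[p]][[cfs]],
                       cal$anchor_depth_mm),
            noise_sd = if (noiseless) 0 else cal$noise$depth_sd_mm)
        truths[[paste(p, cfs, "diameter", sep = ".")]] <-
          truth_from_decay_time(
            cal$decay_times_s$diameter[[p]][[cfs]],
            ymax = cal$assumed_plateaus$diameter$value,
            noise_sd = if (noiseless) 0 else cal$noise$diameter_sd_mm)
      }
    }
  }
  structure(list(times = times, forces = forces, n_per_cell = n_per_cell,
                 truths = truths, pop_model = pop_model,
                 geometry = list(c_over_a = cal$geometry_coupling$c_over_a,
                                 d_over_b = cal$geometry_coupling$d_over_b),
                 noiseless = noiseless, seed = as.integer(seed)),
            class = "experiment_config")
}

# Deterministic per-cell sub-seed: a fixed integer hash of (master, power,
# cf, time) kept below 2^31. Stated rule, so streams are reproducible and
# independent of cell enumeration order.
cell_seed <- function(master, power, cf, time_s) {
  h <- (as.double(master) * 1009 + power * 131071 + cf * 8191 +
        round(time_s * 100) * 127) %% 2147483629
  as.integer(h)
}

# Gaussian draw truncated at zero by resampling (no point mass at 0).
rnorm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  for (i in 1:100) {
    bad <- x < 0
    if (!any(bad)) break
    x[bad] <- stats::rnorm(sum(bad), mean[bad], sd[bad])
  }
  x[x < 0] <- 0  # pathological sd only
  x
}

#' Simulate endpoint observations of one response in one setting
#'
#' @param truth A [response_truth()].
#' @param times Delivery times (s) at which lesions are made.
#' @param n_per_time Replicates per time.
#' @param seed Seed for this cell's stream (optional).
#' @return data.frame with columns `time_s`, `replicate`, `value`.
#' @export
simulate_response_endpoints <- function(truth, times, n_per_time,
                                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tt <- rep(times, each = n_per_time)
  mu <- truth_mean(truth, tt)
  sd <- truth_sd(truth, tt)
  data.frame(time_s = tt,
             replicate = rep(seq_len(n_per_time), times = length(times)),
             value = rnorm_pos(length(tt), mu, sd))
}

#' Simulate a full factorial experiment
#'
#' Draws one synthetic experiment from a configuration: for every
#' (power, contact force, time) cell, `n_per_cell` lesions with jointly
#' generated geometry - maximum depth `a` and maximum diameter `b` from
#' their truths, coupled axes `c = 0.5 a` and `d = 0.8 b` (a synthetic
#' convention so volume is computable) - an endpoint LI drop, and a
#' Bernoulli steam-pop flag from the logistic pop model. Identical seeds
#' give identical output.
#'
#' @param config An [experiment_config()].
#' @param seed Master seed; defaults to `config$seed`.
#' @return Records data.frame in the [records_schema()] layout.
#' @export
simulate_experiment <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "experiment_config"))
  rows <- list()
  for (p in names(config$times)) {
    power <- as.numeric(p)
    for (cf in config$forces) {
      cfs <- as.character(cf)
      key <- function(resp) config$truths[[paste(p, cfs, resp, sep = ".")]]
      for (tt in config$times[[p]]) {
        set.seed(cell_seed(seed, power, cf, tt))
        n <- config$n_per_cell
        a <- rnorm_pos(n, rep(truth_mean(key("depth"), tt), n),
                       truth_sd(key("depth"), rep(tt, n)))
        b <- rnorm_pos(n, rep(truth_mean(key("diameter"), tt), n),
                       truth_sd(key("diameter"), rep(tt, n)))
        li <- rnorm_pos(n, rep(truth_mean(key("li_drop"), tt), n),
                        truth_sd(key("li_drop"), rep(tt, n)))
        pop <- stats::rbinom(n, 1,
                             pop_probability(power, tt, config$pop_model))
        rows[[length(rows) + 1L]] <- data.frame(
          power_w = power, cf_g = cf, time_s = tt, li_drop_ohm = li,
          depth_a_mm = a, diam_b_mm = b,
          depth_c_mm = config$geometry$c_over_a * a,
          surf_d_mm = config$geometry$d_over_b * b,
          steam_pop = pop, replicate = seq_len(n))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a continuous LI trace
#'
#' Samples the one-phase mean curve of a truth at a fixed rate and adds
#' seeded Gaussian noise (absolute `noise_sd`, or `noise_cv` x mean).
#' The trace is monotone in expectation, not pathwise.
#'
#' @param truth A [response_truth()] for the LI drop.
#' @param duration Trace length (s, > 0).
#' @param rate Sampling rate (Hz, >= 1); a `duration` s trace at `rate` Hz
#'   has `duration * rate + 1` samples (t = 0 included).
#' @param seed Optional seed.
#' @return An [li_trace()].
#' @export
simulate_li_trace <- function(truth, duration, rate = 10, seed = NULL) {
  if (duration <= 0) stop("duration must be > 0", call. = FALSE)
  if (rate < 1) stop("rate must be >= 1 Hz", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  tt <- seq(0, duration, by = 1 / rate)
  mu <- truth_mean(truth, tt)
  sd <- truth_sd(truth, tt)
  li_trace(tt, stats::rnorm(length(tt), mu, sd))
}

#' @export
print.response_truth <- function(x, ...) {
  noise <- if (!is.null(x$noise_sd)) sprintf("sd = %g", x$noise_sd)
           else sprintf("cv = %g", x$noise_cv)
  cat(sprintf("<response_truth> ymax = %.4g, k = %.4g 1/s (t90 = %.1f s), %s\n",
              x$ymax, x$k, log(10) / x$k, noise))
  invisible(x)
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("<experiment_config> powers {%s} W, CF {%s} g, n = %d/cell, %s\n",
              paste(names(x$times), collapse = ", "),
              paste(x$forces, collapse = ", "), x$n_per_cell,
              if (x$noiseless) "noiseless" else "default noise"))
  invisible(x)
}
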