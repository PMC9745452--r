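# Pipeline: records in, Table-1-analogue report out. Every report cell is
# computed by a module operation (fit_one_phase / time_to_90_decay /
# time_to_threshold / pearson_correlation / cochran_armitage_trend); the
# pipeline only orchestrates, logs and formats.

RESPONSE_COLUMNS <- c(li_drop = "li_drop_ohm", depth = "depth_a_mm",
                      diameter = "diam_b_mm")

#' Run the full analysis on a records table
#'
#' For every (power, contact force) setting: fits one-phase association
#' curves of LI drop, lesion depth and lesion diameter against delivery
#' time and a linear fit of lesion volume; computes each saturating fit's
#' time to 90% decay; inverts the depth fit at the transmurality threshold
#' (default 4 mm); correlates the LI drop with depth, diameter and volume
#' across lesions; and tests steam-pop incidence for trend in delivery
#' time. Settings or responses whose fit fails or is degenerate are
#' skipped with a logged reason, never silently.
#'
#' @param records Records data.frame ([records_schema()]); validated first.
#' @param depth_threshold_mm Depth threshold for the crossing-time table.
#' @param strict_design,include_pops Passed to [validate_records()].
#' @param alpha Significance level for correlation/trend marks.
#' @return Object of class `summary_report`: data.frames `decay_table`,
#'   `threshold_table`, `correlation_table`, `trend_table`,
#'   `fit_diagnostics`, plus `log` (character) and `issues` (rejected
#'   rows). Deterministic given its inputs.
#' @export
run_full_analysis <- function(records, depth_threshold_mm = 4,
                              strict_design = FALSE, include_pops = TRUE,
                              alpha = 0.05) {
  val <- validate_records(records, strict_design = strict_design,
                          include_pops = include_pops)
  rec <- val$records
  log <- character()
  if (nrow(val$issues))
    log <- c(log, sprintf("validation rejected %d row(s)", nrow(val$issues)))
  if (nrow(rec) == 0L)
    stop("no records remain after validation; rejected rows:\n",
         paste(sprintf("  row %d: %s", val$issues$row, val$issues$reason),
               collapse = "\n"), call. = FALSE)

  settings <- unique(rec[, c("power_w", "cf_g")])
  settings <- settings[order(settings$power_w, settings$cf_g), ,
                       drop = FALSE]

  decay <- threshold <- corr <- trend <- diag <- list()
  fits <- list()

  for (i in seq_len(nrow(settings))) {
    pw <- settings$power_w[i]; cf <- settings$cf_g[i]
    sub <- rec[rec$power_w == pw & rec$cf_g == cf, , drop = FALSE]
    tag <- sprintf("%g W/%g g", pw, cf)
    sub$volume <- lesion_volume(data.frame(a = sub$depth_a_mm,
                                           b = sub$diam_b_mm,
                                           c = sub$depth_c_mm,
                                           d = sub$surf_d_mm))

    for (resp in names(RESPONSE_COLUMNS)) {
      fit <- tryCatch(
        fit_one_phase(sub$time_s, sub[[RESPONSE_COLUMNS[[resp]]]],
                      response_label = resp),
        error = function(e) e)
      if (inherits(fit, "error")) {
        log <- c(log, sprintf("%s %s: fit failed (%s)", tag, resp,
                              conditionMessage(fit)))
        next
      }
      fits[[paste(pw, cf, resp, sep = ".")]] <- fit
      diag[[length(diag) + 1L]] <- data.frame(
        power_w = pw, cf_g = cf, response = resp, model = fit$model,
        r_squared = fit$r_squared, n_points = fit$n_points,
        converged = fit$converged, degenerate = fit$degenerate)
      if (fit$degenerate) {
        log <- c(log, sprintf("%s %s: degenerate fit skipped (%s)",
                              tag, resp, fit$diagnostic))
        next
      }
      dr <- time_to_90_decay(fit)
      decay[[length(decay) + 1L]] <- data.frame(
        power_w = pw, cf_g = cf, response = resp, t90_s = dr$t90,
        method = dr$method)
    }

    # volume grows linearly over the observed window
    vfit <- tryCatch(fit_linear(sub$time_s, sub$volume,
                                response_label = "volume"),
                     error = function(e) e)
    if (!inherits(vfit, "error")) {
      fits[[paste(pw, cf, "volume", sep = ".")]] <- vfit
      diag[[length(diag) + 1L]] <- data.frame(
        power_w = pw, cf_g = cf, response = "volume", model = vfit$model,
        r_squared = vfit$r_squared, n_points = vfit$n_points,
        converged = vfit$converged, degenerate = vfit$degenerate)
    } else {
      log <- c(log, sprintf("%s volume: linear fit failed (%s)", tag,
                            conditionMessage(vfit)))
    }

    dfit <- fits[[paste(pw, cf, "depth", sep = ".")]]
    if (!is.null(dfit) && !dfit$degenerate) {
      tx <- tryCatch(time_to_threshold(dfit, depth_threshold_mm),
                     error = function(e) e)
      threshold[[length(threshold) + 1L]] <- data.frame(
        power_w = pw, cf_g = cf, threshold_mm = depth_threshold_mm,
        time_s = if (inherits(tx, "error")) NA_real_ else tx,
        status = if (inherits(tx, "error")) "unreachable" else "ok")
      if (inherits(tx, "error"))
        log <- c(log, sprintf("%s: %s", tag, conditionMessage(tx)))
    }

    for (resp in c("depth", "diameter", "volume")) {
      yy <- switch(resp, depth = sub$depth_a_mm,
                   diameter = sub$diam_b_mm, volume = sub$volume)
      cr <- tryCatch(pearson_correlation(sub$li_drop_ohm, yy),
                     error = function(e) e)
      if (inherits(cr, "error")) {
        log <- c(log, sprintf("%s li_drop~%s: correlation skipped (%s)",
                              tag, resp, conditionMessage(cr)))
        next
      }
      corr[[length(corr) + 1L]] <- data.frame(
        power_w = pw, cf_g = cf, response = resp, r = cr$r,
        p_value = cr$p_value, n = cr$n, significant = cr$p_value < alpha)
    }

    agg <- stats::aggregate(steam_pop ~ time_s, data = sub,
                            FUN = function(x) c(sum(x), length(x)))
    succ <- agg$steam_pop[, 1]; tot <- agg$steam_pop[, 2]
    tr <- tryCatch(
      cochran_armitage_trend(succ, tot, scores = agg$time_s),
      error = function(e) e)
    if (inherits(tr, "error")) {
      log <- c(log, sprintf("%s: pop trend skipped (%s)", tag,
                            conditionMessage(tr)))
    } else {
      trend[[length(trend) + 1L]] <- data.frame(
        power_w = pw, cf_g = cf, z = tr$z_statistic, p_value = tr$p_value,
        significant = tr$p_value < alpha)
    }
  }

  bind <- function(x) if (length(x)) do.call(rbind, x) else NULL
  structure(list(decay_table = bind(decay),
                 threshold_table = bind(threshold),
                 correlation_table = bind(corr),
                 trend_table = bind(trend),
                 fit_diagnostics = bind(diag),
                 fits = fits, issues = val$issues, log = log),
            class = "summary_report")
}

#' Read / write records CSV
#'
#' `write_records()` serialises a records data.frame with full numeric
#' precision (17 significant digits) so that write-then-read round-trips
#' bit-identically; `read_records()` checks the schema, collects malformed
#' rows into the issue report via [validate_records()] rather than
#' dropping them, and passes unknown extra columns through with a warning
#' (tolerant reader).
#'
#' @param path CSV file path.
#' @param records Records data.frame.
#' @param validate Run [validate_records()] on read (default `TRUE`).
#' @return `read_records()`: list with `records` and `issues` when
#'   `validate` is `TRUE`, else the raw data.frame. `write_records()`:
#'   the path, invisibly.
#' @export
read_records <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(records_schema(), names(df))
  if (length(missing_cols))
    stop("records file lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(df), records_schema())
  if (length(extra))
    warning("unknown column(s) passed through: ",
            paste(extra, collapse = ", "), call. = FALSE)
  if (!is.numeric(df$steam_pop))
    stop("schema error: steam_pop must be coded 0/1", call. = FALSE)
  # measurement columns are doubles regardless of how the CSV prints them
  for (col in setdiff(records_schema(), c("steam_pop", "replicate")))
    df[[col]] <- as.numeric(df[[col]])
  if (!validate) return(df)
  validate_records(df)
}

#' @rdname read_records
#' @export
write_records <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- records
  for (col in names(out))
    if (is.numeric(out[[col]]))
      out[[col]] <- sprintf("%.17g", out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Render a summary report to files
#'
#' @param report A [run_full_analysis()] report.
#' @param dir Output directory (created if needed).
#' @param format `"csv"` (the four tables plus diagnostics) or `"md"`
#'   (one markdown summary).
#' @param plots Also write one PNG per fitted setting-response: the data,
#'   the fitted curve and the decay boundary.
#' @param records Records table (required for `plots = TRUE`).
#' @return Character vector of files written, invisibly.
#' @export
render_report <- function(report, dir, format = "csv", plots = FALSE,
                          records = NULL) {
  stopifnot(inherits(report, "summary_report"))
  if (!format %in% c("csv", "md"))
    stop("unknown format '", format, "'; supported: csv, md",
         call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  tables <- c("decay_table", "threshold_table", "correlation_table",
              "trend_table", "fit_diagnostics")
  if (format == "csv") {
    for (tb in tables) {
      if (is.null(report[[tb]])) next
      f <- file.path(dir, paste0(tb, ".csv"))
      utils::write.csv(report[[tb]], f, row.names = FALSE)
      written <- c(written, f)
    }
  } else {
    f <- file.path(dir, "report.md")
    con <- file(f, "w"); on.exit(close(con), add = TRUE)
    writeLines("# Ablation kinetics summary", con)
    for (tb in tables) {
      df <- report[[tb]]
      if (is.null(df)) next
      writeLines(c("", paste("##", gsub("_", " ", tb)), ""), con)
      hdr <- paste("|", paste(names(df), collapse = " | "), "|")
      sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
      body <- apply(df, 1, function(r)
        paste("|", paste(format(r, trim = TRUE), collapse = " | "), "|"))
      writeLines(c(hdr, sep, body), con)
    }
    if (length(report$log))
      writeLines(c("", "## Log", "", paste("-", report$log)), con)
    written <- c(written, f)
  }
  if (plots) {
    if (is.null(records))
      stop("plots = TRUE requires the records table", call. = FALSE)
    written <- c(written, plot_fits(report, records, dir))
  }
  invisible(written)
}

plot_fits <- function(report, records, dir) {
  written <- character()
  for (key in names(report$fits)) {
    fit <- report$fits[[key]]
    if (!isTRUE(fit$converged)) next
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    pw <- as.numeric(parts[1]); cf <- as.numeric(parts[2])
    resp <- parts[3]
    sub <- records[records$power_w == pw & records$cf_g == cf, ,
                   drop = FALSE]
    yy <- switch(resp,
                 li_drop = sub$li_drop_ohm, depth = sub$depth_a_mm,
                 diameter = sub$diam_b_mm,
                 volume = lesion_volume(data.frame(a = sub$depth_a_mm,
                                                   b = sub$diam_b_mm,
                                                   c = sub$depth_c_mm,
                                                   d = sub$surf_d_mm)))
    f <- file.path(dir, sprintf("fit_%gW_%gg_%s.png", pw, cf, resp))
    grDevices::png(f, width = 600, height = 450)
    plot(sub$time_s, yy, pch = 16, col = "grey40",
         xlab = "RF delivery time (s)", ylab = resp,
         main = sprintf("%g W / %g g: %s", pw, cf, resp))
    tgrid <- seq(0, max(sub$time_s), length.out = 200)
    graphics::lines(tgrid, predict(fit, tgrid), col = "firebrick", lwd = 2)
    if (fit$model == "one_phase_association")
      graphics::abline(v = log(10) / fit$k, lty = 2, col = "steelblue")
    grDevices::dev.off()
    written <- c(written, f)
  }
  written
}

#' Read / write an experiment configuration file
#'
#' JSON is the native format; YAML files are read too when the optional
#' `yaml` package is installed.
#'
#' @param path Config file (`.json`, or `.yaml`/`.yml` with the yaml
#'   package available).
#' @param config An [experiment_config()].
#' @return `read_config()`: an `experiment_config`. `write_config()`: the
#'   path, invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML config requires the 'yaml' package; use JSON",
           call. = FALSE)
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  truths <- lapply(raw$truths, function(x)
    response_truth(ymax = x$ymax, k = x$k,
                   noise_sd = x$noise_sd, noise_cv = x$noise_cv))
  experiment_config(truths = truths,
                    times = lapply(raw$times, as.numeric),
                    forces = as.numeric(raw$forces),
                    n_per_cell = raw$n_per_cell,
                    pop_model = lapply(raw$pop_model, function(x)
                      c(intercept = x[["intercept"]],
                        slope = x[["slope"]])),
                    seed = raw$seed %||% 1L)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  out <- list(times = config$times, forces = config$forces,
              n_per_cell = config$n_per_cell,
              truths = lapply(config$truths, unclass),
              pop_model = lapply(config$pop_model, as.list),
              seed = config$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a machine-readable run manifest
#'
#' Records the provenance of a pipeline run: package version, master seed,
#' MD5 of the config file (if any), timestamp and input/output paths.
#'
#' @param path Output JSON path.
#' @param seed Master seed used.
#' @param config_path Optional config file to fingerprint.
#' @param inputs,outputs Character vectors of paths.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, seed = NA_integer_, config_path = NULL,
                           inputs = character(), outputs = character()) {
  manifest <- list(
    package = "lesionkinetics",
    version = as.character(utils::packageVersion("lesionkinetics")),
    seed = seed,
    config_md5 = if (!is.null(config_path) && file.exists(config_path))
      unname(tools::md5sum(config_path)) else NA_character_,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = inputs, outputs = outputs)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(manifest)
}

#' @export
print.summary_report <- function(x, ...) {
  cat("<summary_report>\n")
  for (tb in c("decay_table", "threshold_table", "correlation_table",
               "trend_table"))
    cat(sprintf("  %s: %d row(s)\n", tb,
                if (is.null(x[[tb]])) 0L else nrow(x[[tb]])))
  if (length(x$log)) cat("  log:", length(x$log), "message(s)\n")
  invisible(x)
}
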