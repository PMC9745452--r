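# Domain types, validation, and lesion-volume computation.
#
# Records are carried as plain data.frames in the canonical CSV schema
# (one row per RF application); small constructors return classed lists
# for the scalar domain objects.

# Factorial design constants of the ex vivo protocol: powers (W), contact
# forces (g) and the per-power RF delivery time grids (s).
DESIGN_POWERS <- c(40, 50)
DESIGN_FORCES <- c(10, 30, 50)
DESIGN_TIMES <- list(`40` = c(10, 20, 30, 40, 50, 60),
                     `50` = c(5, 10, 20, 30, 40, 50, 60))

#' Canonical column names of the records table
#'
#' One row per RF application: ablation setting, delivery time, endpoint
#' local-impedance (LI) drop, the four lesion axes, steam-pop flag and
#' replicate id.
#'
#' @return Character vector of required column names.
#' @export
records_schema <- function() {
  c("power_w", "cf_g", "time_s", "li_drop_ohm",
    "depth_a_mm", "diam_b_mm", "depth_c_mm", "surf_d_mm",
    "steam_pop", "replicate")
}

#' Ablation setting (power and contact force)
#'
#' @param power_w Ablation power in watts. The study design uses 40 or 50 W.
#' @param cf_g Contact force in grams. The study design uses 10, 30 or 50 g.
#' @param strict_design If `TRUE`, values outside the factorial design are
#'   rejected; if `FALSE` any positive values are accepted.
#' @return Object of class `ablation_setting`.
#' @export
ablation_setting <- function(power_w, cf_g, strict_design = FALSE) {
  stopifnot(length(power_w) == 1L, length(cf_g) == 1L)
  if (!is.finite(power_w) || power_w <= 0)
    stop("power_w must be a positive number", call. = FALSE)
  if (!is.finite(cf_g) || cf_g <= 0)
    stop("cf_g must be a positive number", call. = FALSE)
  if (strict_design) {
    if (!power_w %in% DESIGN_POWERS)
      stop(sprintf("power_w = %g W is outside the design set {%s}",
                   power_w, paste(DESIGN_POWERS, collapse = ", ")),
           call. = FALSE)
    if (!cf_g %in% DESIGN_FORCES)
      stop(sprintf("cf_g = %g g is outside the design set {%s}",
                   cf_g, paste(DESIGN_FORCES, collapse = ", ")),
           call. = FALSE)
  }
  structure(list(power_w = power_w, cf_g = cf_g),
            class = "ablation_setting")
}

#' Lesion geometry from the four calliper axes
#'
#' Axes follow the standard sectioned-lesion convention: `a` maximum depth,
#' `b` maximum diameter, `c` depth at the maximum diameter, `d` surface
#' maximum diameter, all in mm. All axes must be non-negative and the depth
#' of the widest section cannot exceed the maximum depth (`c <= a`).
#' `d > b` is allowed: in shallow lesions the surface diameter may exceed
#' the subsurface maximum.
#'
#' @param a,b,c,d Numeric vectors (recycled to common length), mm.
#' @return Object of class `lesion_geometry`: a data.frame with columns
#'   `a`, `b`, `c`, `d`.
#' @export
lesion_geometry <- function(a, b, c, d) {
  g <- data.frame(a = as.numeric(a), b = as.numeric(b),
                  c = as.numeric(c), d = as.numeric(d))
  for (ax in c("a", "b", "c", "d")) {
    v <- g[[ax]]
    if (any(!is.finite(v)))
      stop(sprintf("axis '%s' contains non-finite values", ax), call. = FALSE)
    if (any(v < 0))
      stop(sprintf("axis '%s' must be non-negative", ax), call. = FALSE)
  }
  if (any(g$c > g$a + 1e-12))
    stop("depth-at-max-diameter exceeds max depth (c > a)", call. = FALSE)
  class(g) <- c("lesion_geometry", "data.frame")
  g
}

#' Lesion volume from calliper axes
#'
#' Computes the two-frustum volume approximation
#' \deqn{V = \frac{\pi}{6}\left(a b^2 + \frac{c d^2}{2}\right)}
#' in mm^3, where `a` is maximum depth, `b` maximum diameter, `c` depth at
#' the maximum diameter and `d` surface maximum diameter (mm). The halved
#' term applies to `c d^2` only. The volume scales cubically under uniform
#' rescaling of all axes and is monotone in each axis.
#'
#' @param geometry A [lesion_geometry()] object, or any data.frame carrying
#'   columns `a`, `b`, `c`, `d` in mm.
#' @return Numeric vector of volumes (mm^3).
#' @examples
#' lesion_volume(lesion_geometry(4, 8, 2, 6))  # (pi/6) * 292
#' @export
lesion_volume <- function(geometry) {
  if (!is.data.frame(geometry) || !all(c("a", "b", "c", "d") %in% names(geometry)))
    stop("geometry must carry columns a, b, c, d", call. = FALSE)
  if (!inherits(geometry, "lesion_geometry"))
    geometry <- lesion_geometry(geometry$a, geometry$b, geometry$c, geometry$d)
  with(geometry, (pi / 6) * (a * b^2 + c * d^2 / 2))
}

#' Continuous local-impedance trace
#'
#' @param times Sample times (s), strictly increasing, starting at 0.
#' @param li_values LI samples (ohm), same length as `times`.
#' @return Object of class `li_trace`.
#' @export
li_trace <- function(times, li_values) {
  times <- as.numeric(times)
  li_values <- as.numeric(li_values)
  if (length(times) != length(li_values))
    stop("times and li_values must have equal length", call. = FALSE)
  if (length(times) && abs(times[1]) > 1e-9)
    stop("trace must start at t = 0", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  structure(list(times = times, li_values = li_values), class = "li_trace")
}

#' Validate a records table
#'
#' Checks every row of a records data.frame against the domain invariants
#' (positive delivery time, non-negative LI drop, geometry axes >= 0 with
#' `c <= a`, steam_pop coded 0/1, replicate a positive integer unique within
#' its setting-by-time cell) and returns the clean rows together with an
#' issue report for the rejected ones. Nothing is dropped silently.
#'
#' @param records data.frame in the [records_schema()] layout.
#' @param strict_design Reject settings outside the 40/50 W x 10/30/50 g
#'   factorial design and its time grids.
#' @param include_pops If `FALSE`, rows with `steam_pop == 1` are filtered
#'   out (reported in the issue table with reason `"steam-pop filtered"`).
#'   The default keeps them: pop lesions were measured and analysed like the
#'   rest.
#' @return List with `records` (validated data.frame) and `issues`
#'   (data.frame with columns `row`, `reason`).
#' @export
validate_records <- function(records, strict_design = FALSE,
                             include_pops = TRUE) {
  if (!is.data.frame(records))
    stop("records must be a data.frame", call. = FALSE)
  if (nrow(records) == 0L)
    stop("empty dataset: no records to validate", call. = FALSE)
  missing_cols <- setdiff(records_schema(), names(records))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)

  reasons <- rep(NA_character_, nrow(records))
  flag <- function(bad, msg) {
    bad <- which(bad & is.na(reasons))
    reasons[bad] <<- msg
  }

  num_bad <- function(v) !is.finite(suppressWarnings(as.numeric(v)))
  for (col in setdiff(records_schema(), "steam_pop"))
    flag(num_bad(records[[col]]), sprintf("non-numeric value in %s", col))

  flag(records$time_s <= 0, "non-positive delivery time")
  flag(records$li_drop_ohm < 0, "negative LI drop")
  for (col in c("depth_a_mm", "diam_b_mm", "depth_c_mm", "surf_d_mm"))
    flag(records[[col]] < 0, sprintf("negative axis %s", col))
  flag(records$depth_c_mm > records$depth_a_mm + 1e-12,
       "depth-at-max-diameter exceeds max depth")
  flag(!records$steam_pop %in% c(0, 1), "steam_pop must be coded 0/1")
  flag(records$replicate < 1 | records$replicate != round(records$replicate),
       "replicate must be a positive integer")

  if (strict_design) {
    flag(!records$power_w %in% DESIGN_POWERS, "power outside design")
    flag(!records$cf_g %in% DESIGN_FORCES, "contact force outside design")
    on_grid <- mapply(function(p, t) {
      p %in% DESIGN_POWERS && t %in% DESIGN_TIMES[[as.character(p)]]
    }, records$power_w, records$time_s)
    flag(!on_grid, "delivery time outside design grid")
  }

  # replicate uniqueness within (power, cf, time) among otherwise-clean rows
  ok <- is.na(reasons)
  key <- paste(records$power_w, records$cf_g, records$time_s,
               records$replicate)
  dup <- ok & duplicated(key) & key %in% key[ok][duplicated(key[ok])]
  flag(dup, "duplicate replicate id within setting-time cell")

  if (!include_pops)
    flag(records$steam_pop == 1, "steam-pop filtered")

  issues <- data.frame(row = which(!is.na(reasons)),
                       reason = reasons[!is.na(reasons)],
                       stringsAsFactors = FALSE)
  clean <- records[is.na(reasons), , drop = FALSE]
  rownames(clean) <- NULL
  list(records = clean, issues = issues)
}

#' @export
print.ablation_setting <- function(x, ...) {
  cat(sprintf("<ablation_setting> %g W / %g g\n", x$power_w, x$cf_g))
  invisible(x)
}

#' @export
print.li_trace <- function(x, ...) {
  cat(sprintf("<li_trace> %d samples over %.2f s\n",
              length(x$times), max(x$times)))
  invisible(x)
}
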