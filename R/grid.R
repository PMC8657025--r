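#' Regular sampling grid for sensor time series
#'
#' A `time_grid` is the shared time axis of a reconstruction problem: a start
#' time, a fixed step (15 minutes for the nitrate response) and a number of
#' steps. Timestamps label the *start* of each sampling window and windows are
#' half-open, `[t, t + step)`, so no raw observation can be counted twice when
#' finer-grained covariates are aggregated onto the grid.
#'
#' @param start first timestamp; a `POSIXct`, or a string parsed as UTC.
#' @param step step length in seconds (default `900`, i.e. 15 minutes).
#' @param n number of steps (positive integer).
#' @return An object of class `time_grid` with fields `start`, `step`, `n`.
#' @examples
#' g <- time_grid("2018-10-01 00:00:00", step = 900, n = 96)
#' head(grid_times(g))
#' @export
time_grid <- function(start, step = 900, n) {
  if (is.character(start)) start <- parse_timestamps(start)
  if (!inherits(start, "POSIXct") || length(start) != 1L || is.na(start))
    stop("`start` must be a single valid timestamp")
  step <- as.numeric(step)
  if (!is.finite(step) || step <= 0)
    stop("`step` must be a positive number of seconds")
  n <- as.integer(n)
  if (is.na(n) || n < 1L)
    stop("`n` must be a positive integer")
  structure(list(start = as.POSIXct(as.numeric(start), tz = "UTC",
                                    origin = "1970-01-01"),
                 step = step, n = n),
            class = "time_grid")
}

#' Timestamps of a time grid
#'
#' @param grid a [time_grid()].
#' @return `POSIXct` vector of length `grid$n`: `start + (0:(n-1)) * step`.
#' @export
grid_times <- function(grid) {
  stopifnot(inherits(grid, "time_grid"))
  grid$start + (seq_len(grid$n) - 1L) * grid$step
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("<time_grid> %d steps of %gs from %s UTC\n", x$n, x$step,
              format(x$start, "%Y-%m-%d %H:%M:%S")))
  invisible(x)
}

same_grid <- function(a, b) {
  inherits(a, "time_grid") && inherits(b, "time_grid") &&
    abs(as.numeric(a$start) - as.numeric(b$start)) < 1e-6 &&
    a$step == b$step && a$n == b$n
}

# Parse ISO-8601-ish timestamps as UTC; error names the first offending entry
# so input problems in delimited files point at a row.
parse_timestamps <- function(x) {
  x <- as.character(x)
  fmts <- c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
            "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M", "%Y-%m-%d")
  out <- rep(as.POSIXct(NA), length(x))
  todo <- !is.na(x) & nzchar(x)
  for (f in fmts) {
    if (!any(todo)) break
    p <- as.POSIXct(x[todo], tz = "UTC", format = f)
    hit <- !is.na(p)
    out[which(todo)[hit]] <- p[hit]
    todo[todo] <- !hit
  }
  if (any(todo)) {
    i <- which(todo)[1L]
    stop(sprintf("unparseable timestamp at row %d: \"%s\"", i, x[i]),
         call. = FALSE)
  }
  out
}

#' Sensor series on a regular grid
#'
#' Couples a value vector to a [time_grid()] with an explicit missing mask
#' (`NA` entries). Non-missing entries must be finite; `NaN` on input is
#' treated as missing (a common sentinel in exported sensor tables).
#'
#' @param values numeric vector, one entry per grid step; `NA`/`NaN` = missing.
#' @param grid a [time_grid()] of matching length.
#' @param name variable name, e.g. `"nitrate"`.
#' @param units unit label, e.g. `"umol/L"`.
#' @return An object of class `sensor_series`.
#' @export
sensor_series <- function(values, grid, name = "value", units = "") {
  stopifnot(inherits(grid, "time_grid"))
  values <- as.numeric(values)
  values[is.nan(values)] <- NA_real_
  if (length(values) != grid$n)
    stop(sprintf("length(values) [%d] != grid$n [%d]", length(values), grid$n))
  if (any(is.infinite(values)))
    stop("non-missing sensor values must be finite")
  structure(list(values = values, grid = grid,
                 name = as.character(name), units = as.character(units)),
            class = "sensor_series")
}

#' @export
length.sensor_series <- function(x) x$grid$n

#' @export
print.sensor_series <- function(x, ...) {
  nmiss <- sum(is.na(x$values))
  cat(sprintf("<sensor_series> %s [%s]: %d steps, %d missing (%.1f%%)\n",
              x$name, x$units, length(x), nmiss, 100 * nmiss / length(x)))
  print(x$grid)
  invisible(x)
}

#' @export
as.data.frame.sensor_series <- function(x, ...) {
  data.frame(timestamp = grid_times(x$grid), value = x$values)
}

#' Aggregate an irregular or finer-grained series onto a grid
#'
#' Averages raw observations into the half-open grid windows
#' `[t, t + step)`. This is how 1-minute covariates (temperature,
#' conductance, dissolved oxygen, turbidity) and 5-minute water-elevation
#' records meet the 15-minute response grid. A window holding no raw
#' observation becomes missing; raw `NA` values are dropped before averaging,
#' so a window is present whenever at least one raw value in it is.
#'
#' @param times raw timestamps (`POSIXct` or parseable strings).
#' @param values raw values, same length as `times`.
#' @param grid target [time_grid()].
#' @param name,units labels for the returned series.
#' @return A [sensor_series()] on `grid`.
#' @export
align_to_grid <- function(times, values, grid, name = "value", units = "") {
  if (is.character(times) || is.factor(times)) times <- parse_timestamps(times)
  stopifnot(inherits(times, "POSIXct"), inherits(grid, "time_grid"))
  values <- as.numeric(values)
  if (length(times) != length(values))
    stop("`times` and `values` must have equal length")
  idx <- floor((as.numeric(times) - as.numeric(grid$start)) / grid$step) + 1
  keep <- !is.na(values) & !is.nan(values) & !is.na(idx) &
    idx >= 1 & idx <= grid$n
  out <- rep(NA_real_, grid$n)
  if (any(keep)) {
    idxk <- idx[keep]
    sums <- rowsum(values[keep], idxk)
    cnts <- rowsum(rep(1, sum(keep)), idxk)
    out[as.integer(rownames(sums))] <- sums[, 1L] / cnts[, 1L]
  }
  sensor_series(out, grid, name = name, units = units)
}

#' Turbidity transform
#'
#' Natural `log(x + 1)` of turbidity (FNU). Turbidity has a strongly
#' right-skewed marginal distribution in rivers and is log-transformed before
#' entering the additive model. Missing maps to missing; negative turbidity is
#' a domain error (it signals an upstream QA/QC problem and is rejected
#' loudly rather than clamped).
#'
#' @param x turbidity readings (FNU), `NA` allowed.
#' @return `log1p(x)`.
#' @export
log_turbidity <- function(x) {
  x <- as.numeric(x)
  if (any(!is.na(x) & x < 0))
    stop("negative turbidity value(s); turbidity must be >= 0", call. = FALSE)
  log1p(x)
}

#' Sensor precision rule
#'
#' The nitrate sensor's stated precision: plus-or-minus `abs_halfwidth`
#' (2 umol/L) for readings below `threshold` (20 umol/L) and plus-or-minus
#' `rel_halfwidth` (10%) of the reading above it. The defaults are continuous
#' at the threshold (2 = 0.10 x 20); a spec that is not continuous is allowed
#' but flagged with a warning.
#'
#' @param threshold reading (umol/L) at which the rule switches.
#' @param abs_halfwidth absolute half-width (umol/L) below the threshold.
#' @param rel_halfwidth relative half-width (fraction) above the threshold.
#' @return An object of class `precision_spec`.
#' @seealso [precision_halfwidth()], [pwpi()]
#' @export
precision_spec <- function(threshold = 20, abs_halfwidth = 2,
                           rel_halfwidth = 0.10) {
  if (!all(is.finite(c(threshold, abs_halfwidth, rel_halfwidth))) ||
      threshold <= 0 || abs_halfwidth <= 0 || rel_halfwidth <= 0)
    stop("all precision_spec fields must be positive and finite")
  if (abs(abs_halfwidth - rel_halfwidth * threshold) > 1e-8)
    warning("precision rule is discontinuous at the threshold (abs_halfwidth != rel_halfwidth * threshold)")
  structure(list(threshold = threshold, abs_halfwidth = abs_halfwidth,
                 rel_halfwidth = rel_halfwidth),
            class = "precision_spec")
}

#' Precision half-width at given readings
#'
#' @param x readings (umol/L).
#' @param spec a [precision_spec()].
#' @return numeric vector: `abs_halfwidth` where `x < threshold`, else
#'   `rel_halfwidth * |x|`. Readings at exactly the threshold use the relative
#'   rule (identical value under the default, continuous spec).
#' @export
precision_halfwidth <- function(x, spec = precision_spec()) {
  stopifnot(inherits(spec, "precision_spec"))
  ifelse(x < spec$threshold, spec$abs_halfwidth, spec$rel_halfwidth * abs(x))
}
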