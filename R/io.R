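#' Read sensor series from a delimited text file
#'
#' Expects a CSV with a timestamp column (ISO-8601, parsed as UTC) and one
#' column per variable. Empty strings, `"NA"` and `"NaN"` are read as
#' missing. Each variable is aggregated onto the target grid with
#' [align_to_grid()]; when no grid is supplied, a regular grid is inferred
#' from the timestamps (start = earliest, step = median spacing).
#'
#' @param path file path.
#' @param grid optional [time_grid()]; inferred when `NULL`.
#' @param timestamp_col name of the timestamp column.
#' @param column_map optional named character vector renaming file columns
#'   to variable names, e.g. `c(surfWaterNitrateMean = "nitrate")`.
#' @param sep field separator.
#' @return named list of [sensor_series()]; the grid is attached as
#'   attribute `"grid"`.
#' @export
read_sensor_csv <- function(path, grid = NULL, timestamp_col = "timestamp",
                            column_map = NULL, sep = ",") {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- utils::read.csv(path, sep = sep, na.strings = c("", "NA", "NaN"),
                        check.names = FALSE, stringsAsFactors = FALSE)
  if (!timestamp_col %in% names(df))
    stop(sprintf("schema error: missing required column(s): %s",
                 timestamp_col), call. = FALSE)
  if (!is.null(column_map)) {
    hit <- match(names(column_map), names(df))
    names(df)[hit[!is.na(hit)]] <- column_map[!is.na(hit)]
  }
  times <- parse_timestamps(df[[timestamp_col]])
  vars <- setdiff(names(df), timestamp_col)
  if (!length(vars))
    stop("schema error: no variable columns beside the timestamp",
         call. = FALSE)
  if (is.null(grid)) {
    st <- sort(unique(as.numeric(times)))
    if (length(st) < 2) stop("cannot infer a grid from fewer than 2 timestamps")
    step <- stats::median(diff(st))
    n <- round((st[length(st)] - st[1]) / step) + 1
    grid <- time_grid(as.POSIXct(st[1], tz = "UTC", origin = "1970-01-01"),
                      step, n)
  }
  units_tab <- c(nitrate = "umol/L", temperature = "degC",
                 conductance = "uS/cm", dissolved_oxygen = "mg/L",
                 turbidity = "FNU", elevation = "m")
  out <- lapply(vars, function(v) {
    vals <- suppressWarnings(as.numeric(df[[v]]))
    align_to_grid(times, vals, grid, name = v,
                  units = if (v %in% names(units_tab)) units_tab[[v]] else "")
  })
  names(out) <- vars
  attr(out, "grid") <- grid
  out
}

#' Write a reconstruction to CSV
#'
#' Columns `timestamp, value, lower95, upper95, method`; timestamps in
#' ISO-8601 UTC; missing entries written as `NA`. [read_reconstruction()]
#' round-trips the file.
#'
#' @param x a [reconstruct()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_reconstruction <- function(x, path) {
  stopifnot(inherits(x, "reconstruction"))
  df <- as.data.frame(x)
  df$timestamp <- format(df$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(df, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a reconstruction CSV back into a reconstruction object
#'
#' The inverse of [write_reconstruction()] (the fitted models are not
#' stored in the file, so `gam` and `runs` are empty).
#'
#' @param path file path.
#' @return object of class `reconstruction`.
#' @export
read_reconstruction <- function(path) {
  df <- utils::read.csv(path, na.strings = c("", "NA", "NaN"),
                        stringsAsFactors = FALSE)
  need <- c("timestamp", "value", "lower95", "upper95", "method")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("schema error: missing required column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  times <- parse_timestamps(df$timestamp)
  step <- stats::median(diff(as.numeric(times)))
  grid <- time_grid(times[1], step, nrow(df))
  structure(list(grid = grid, value = as.numeric(df$value),
                 lower95 = as.numeric(df$lower95),
                 upper95 = as.numeric(df$upper95),
                 method = as.character(df$method),
                 gam = NULL,
                 runs = data.frame(), control = NULL,
                 observed = NULL, name = "nitrate", units = "umol/L"),
            class = "reconstruction")
}

# known configuration keys, module-prefixed
CONFIG_SCHEMA <- list(
  `recon.arima_window` = "integer", `recon.min_history` = "integer",
  `recon.level` = "numeric", `recon.feedback` = "logical",
  `recon.strict` = "logical",
  `gam.k` = "integer", `gam.bs` = "character", `gam.engine` = "character",
  `gam.candidates` = "character",
  `arima.max_p` = "integer", `arima.max_q` = "integer",
  `arima.max_d` = "integer", `arima.stepwise` = "logical",
  `arima.kpss_level` = "numeric",
  `synth.n_days` = "integer", `synth.baseline` = "numeric",
  `synth.diel_amplitude` = "numeric", `synth.seasonal_amplitude` = "numeric",
  `synth.ar1_phi` = "numeric", `synth.noise_sd` = "numeric",
  `synth.n_events` = "integer", `synth.event_magnitude` = "numeric")

#' Read a flat key-value configuration file
#'
#' YAML with flat, module-prefixed keys (e.g. `recon.arima_window: 400`,
#' `gam.k: 12`). Unknown keys are rejected with an error listing them.
#'
#' @param path file path.
#' @return named list of validated settings.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) return(list())
  if (!is.list(cfg) || is.null(names(cfg)) || any(!nzchar(names(cfg))))
    stop("config must be a flat key: value mapping", call. = FALSE)
  unknown <- setdiff(names(cfg), names(CONFIG_SCHEMA))
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  for (k in names(cfg)) {
    want <- CONFIG_SCHEMA[[k]]
    v <- cfg[[k]]
    ok <- switch(want,
                 integer = is.numeric(v) && length(v) == 1 && v == round(v),
                 numeric = is.numeric(v) && length(v) == 1,
                 logical = is.logical(v) && length(v) == 1,
                 character = is.character(v) && length(v) == 1)
    if (!ok)
      stop(sprintf("config key %s must be %s", k, want), call. = FALSE)
    if (want == "integer") cfg[[k]] <- as.integer(v)
  }
  cfg
}

# fold validated config keys into a recon_control
apply_config <- function(cfg, control = recon_control()) {
  get <- function(k, default) if (!is.null(cfg[[k]])) cfg[[k]] else default
  cands <- get("gam.candidates", NULL)
  recon_control(
    arima_window = get("recon.arima_window", control$arima_window),
    min_history = get("recon.min_history", control$min_history),
    level = get("recon.level", control$level),
    feedback = get("recon.feedback", control$feedback),
    strict = get("recon.strict", control$strict),
    k = get("gam.k", control$k),
    bs = get("gam.bs", control$bs),
    engine = get("gam.engine", control$engine),
    candidates = if (is.null(cands)) control$candidates
                 else trimws(strsplit(cands, ",")[[1]]),
    max_p = get("arima.max_p", control$max_p),
    max_q = get("arima.max_q", control$max_q),
    max_d = get("arima.max_d", control$max_d),
    stepwise_order = get("arima.stepwise", control$stepwise_order),
    kpss_level = get("arima.kpss_level", control$kpss_level),
    verbose = control$verbose)
}
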