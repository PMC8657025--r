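#' Randomly remove point observations
#'
#' Samples `floor(fraction * n_observed)` observed positions uniformly
#' without replacement and sets them missing — the point-missingness
#' scenarios (20%, 30%, 40% removal).
#'
#' @param y a [sensor_series()].
#' @param fraction fraction of *observed* entries to remove, in `[0, 1)`.
#' @param seed optional integer; when given, the removal is reproducible.
#' @return list with `series` (degraded copy) and `plan` (a `removal_plan`:
#'   removed indices, scenario label, seed).
#' @export
remove_points <- function(y, fraction, seed = NULL) {
  stopifnot(inherits(y, "sensor_series"))
  if (!is.numeric(fraction) || fraction < 0 || fraction >= 1)
    stop("`fraction` must be in [0, 1)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  obs_idx <- which(!is.na(y$values))
  m <- floor(fraction * length(obs_idx))
  removed <- sort(if (m > 0) sample(obs_idx, m) else integer(0))
  out <- y
  out$values[removed] <- NA_real_
  plan <- structure(list(indices = removed,
                         scenario = sprintf("pct%d", round(100 * fraction)),
                         seed = seed),
                    class = "removal_plan")
  list(series = out, plan = plan)
}

#' Randomly remove contiguous blocks of observations
#'
#' Places `n_blocks` non-overlapping runs of `block_length` consecutive grid
#' positions (start positions uniform; collisions with already-placed blocks
#' are resampled, up to 1000 attempts per block) and removes every observed
#' value they cover. Blocks may overlap pre-existing gaps; such positions
#' simply contribute nothing to evaluation. `block_length = 96` is a day of
#' 15-minute data, `672` a week.
#'
#' @param y a [sensor_series()].
#' @param n_blocks number of blocks (default 10).
#' @param block_length run length in grid steps.
#' @param seed optional integer for reproducibility.
#' @return list with `series` and `plan` (removed *observed* indices, all
#'   block start positions, scenario label, seed).
#' @export
remove_blocks <- function(y, n_blocks = 10, block_length, seed = NULL) {
  stopifnot(inherits(y, "sensor_series"))
  n <- y$grid$n
  block_length <- as.integer(block_length)
  n_blocks <- as.integer(n_blocks)
  if (block_length < 1 || block_length > n)
    stop("`block_length` must be in [1, n_steps]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  starts <- integer(0)
  for (b in seq_len(n_blocks)) {
    placed <- FALSE
    for (attempt in seq_len(1000)) {
      s <- sample.int(n - block_length + 1L, 1L)
      if (!any(s <= starts + block_length - 1L & s + block_length - 1L >= starts)) {
        starts <- c(starts, s)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop(sprintf("placement error: could not place %d disjoint blocks of length %d",
                   n_blocks, block_length), call. = FALSE)
  }
  starts <- sort(starts)
  covered <- unlist(lapply(starts, function(s) s:(s + block_length - 1L)))
  removed <- sort(intersect(covered, which(!is.na(y$values))))
  out <- y
  out$values[removed] <- NA_real_
  label <- if (block_length == 96L && n_blocks == 10L) "day10"
           else if (block_length == 672L && n_blocks == 10L) "week10"
           else sprintf("block%dx%d", n_blocks, block_length)
  plan <- structure(list(indices = removed, starts = starts,
                         block_length = block_length, scenario = label,
                         seed = seed),
                    class = "removal_plan")
  list(series = out, plan = plan)
}

parse_scenario <- function(scenario) {
  if (grepl("^pct[0-9]+$", scenario)) {
    list(type = "points",
         fraction = as.numeric(sub("pct", "", scenario)) / 100)
  } else if (scenario == "day10") {
    list(type = "blocks", n_blocks = 10L, block_length = 96L)
  } else if (scenario == "week10") {
    list(type = "blocks", n_blocks = 10L, block_length = 672L)
  } else {
    stop(sprintf("unknown scenario \"%s\"", scenario), call. = FALSE)
  }
}

#' Run the removal-and-reconstruction performance study
#'
#' For each scenario and repetition: remove data from the response, rerun
#' the full reconstruction on the degraded series (GAM selection is refit on
#' the degraded complete rows, so no information leaks from the removed
#' values), and score the reconstructed values against the held-out
#' observations with [rmse()], [pwpi()] and [r_squared()]. Repetition `r`
#' uses seed `base_seed + r`, so a result table is exactly reproducible.
#'
#' @param y response [sensor_series()].
#' @param covariates named list of covariate series (see [build_design()]).
#' @param scenarios subset of `pct20`, `pct30`, `pct40`, `day10`, `week10`
#'   (any `pctNN` label is accepted).
#' @param n_reps repetitions per scenario.
#' @param base_seed integer seed offset.
#' @param control a [recon_control()].
#' @param spec a [precision_spec()] for the PWPI.
#' @param progress print one line per repetition.
#' @return data frame with one row per scenario x repetition: `scenario`,
#'   `rep`, `rmse`, `pwpi`, `r2`, `n_evaluated`, `n_unfilled`.
#' @export
run_scenarios <- function(y, covariates,
                          scenarios = c("pct20", "pct30", "pct40",
                                        "day10", "week10"),
                          n_reps = 10, base_seed = 1,
                          control = recon_control(),
                          spec = precision_spec(), progress = FALSE) {
  res <- vector("list", length(scenarios) * n_reps)
  k <- 0L
  for (sc in scenarios) {
    info <- parse_scenario(sc)
    for (r in seq_len(n_reps)) {
      seed <- base_seed + r
      deg <- if (info$type == "points")
        remove_points(y, info$fraction, seed = seed)
      else
        remove_blocks(y, info$n_blocks, info$block_length, seed = seed)
      rec <- suppressWarnings(reconstruct(deg$series, covariates, control))
      idx <- deg$plan$indices
      true <- y$values[idx]
      pred <- rec$value[idx]
      n_unf <- sum(rec$method[idx] %in% "UNFILLED")
      ok <- !is.na(pred)
      row <- data.frame(scenario = sc, rep = r,
                        rmse = NA_real_, pwpi = NA_real_, r2 = NA_real_,
                        n_evaluated = length(idx), n_unfilled = n_unf,
                        stringsAsFactors = FALSE)
      if (any(ok)) {
        row$rmse <- rmse(true, pred)
        row$pwpi <- pwpi(true, pred, spec)
        row$r2 <- tryCatch(r_squared(true, pred), error = function(e) NA_real_)
      } else {
        warning(sprintf("%s rep %d: no evaluable removed positions", sc, r),
                call. = FALSE)
      }
      k <- k + 1L
      res[[k]] <- row
      if (progress)
        message(sprintf("%s rep %d: rmse %.3f pwpi %.3f (n=%d)", sc, r,
                        row$rmse, row$pwpi, row$n_evaluated))
    }
  }
  do.call(rbind, res[seq_len(k)])
}

#' Summarize a scenario result table
#'
#' Per-scenario median and quartiles of RMSE, PWPI and R-squared.
#' Repetitions with missing metrics are excluded from the quantiles and
#' counted in `dropped`.
#'
#' @param results a [run_scenarios()] result (or a data frame with the same
#'   columns).
#' @return data frame with one row per scenario.
#' @export
summarize_scenarios <- function(results) {
  stopifnot(is.data.frame(results), nrow(results) > 0,
            all(c("scenario", "rmse", "pwpi") %in% names(results)))
  q <- function(x, p) if (all(is.na(x))) NA_real_ else
    unname(stats::quantile(x, p, na.rm = TRUE))
  do.call(rbind, lapply(split(results, results$scenario), function(d) {
    data.frame(scenario = d$scenario[1], n_reps = nrow(d),
               dropped = sum(is.na(d$rmse)),
               rmse_q1 = q(d$rmse, 0.25), rmse_median = q(d$rmse, 0.5),
               rmse_q3 = q(d$rmse, 0.75),
               pwpi_q1 = q(d$pwpi, 0.25), pwpi_median = q(d$pwpi, 0.5),
               pwpi_q3 = q(d$pwpi, 0.75),
               r2_median = q(d$r2, 0.5),
               stringsAsFactors = FALSE)
  }))
}
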