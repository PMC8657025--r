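#' Reconstruction settings
#'
#' Tunable parameters of the hybrid sweep.
#'
#' @param arima_window number of preceding working values an ARIMA run is
#'   fit on (default 500 steps, i.e. about 5.2 days of 15-minute data).
#' @param min_history minimum filled history required before an ARIMA run;
#'   runs with less history are left `UNFILLED` (default 50).
#' @param level prediction-interval level (default 0.95).
#' @param feedback should reconstructed values feed the lag covariates and
#'   subsequent ARIMA histories (default `TRUE`)? With `FALSE`, lags count
#'   as available only at timestamps whose predecessors were *observed*.
#' @param strict if `TRUE`, a timestamp is GAM-eligible only when all seven
#'   candidate columns are present; by default only the columns the selected
#'   model actually uses are required.
#' @param k,bs,engine passed to [fit_gam()] / [stepwise_gam()].
#' @param candidates candidate columns for stepwise selection.
#' @param max_p,max_q,max_d,stepwise_order,kpss_level passed to
#'   [select_arima_order()].
#' @param verbose log one line per ARIMA run (start, length, order, AIC).
#' @return A list of class `recon_control`.
#' @export
recon_control <- function(arima_window = 500L, min_history = 50L,
                          level = 0.95, feedback = TRUE, strict = FALSE,
                          k = 10, bs = "tp", engine = "auto",
                          candidates = gam_candidates(),
                          max_p = 5, max_q = 5, max_d = 2,
                          stepwise_order = TRUE, kpss_level = 0.05,
                          verbose = FALSE) {
  arima_window <- as.integer(arima_window)
  min_history <- as.integer(min_history)
  if (min_history < 3L) stop("`min_history` must be >= 3")
  if (min_history > arima_window)
    stop("`min_history` must be <= `arima_window`")
  stopifnot(level > 0, level < 1)
  structure(list(arima_window = arima_window, min_history = min_history,
                 level = level, feedback = isTRUE(feedback),
                 strict = isTRUE(strict), k = k, bs = bs, engine = engine,
                 candidates = candidates, max_p = max_p, max_q = max_q,
                 max_d = max_d, stepwise_order = isTRUE(stepwise_order),
                 kpss_level = kpss_level, verbose = isTRUE(verbose)),
            class = "recon_control")
}

#' Which model reconstructs a given timestamp?
#'
#' `"GAM"` iff every column the selected model requires is non-missing in
#' the design row; otherwise `"ARIMA"`. A covariate that stepwise selection
#' dropped does not block the GAM even when missing.
#'
#' @param design a [build_design()] data frame.
#' @param t row index.
#' @param required character vector of required columns (e.g. the
#'   `selected` field of a [stepwise_gam()] fit).
#' @return `"GAM"` or `"ARIMA"`.
#' @export
choose_method <- function(design, t, required) {
  d <- as.data.frame(design)
  for (trm in required) if (is.na(d[[trm]][t])) return("ARIMA")
  "GAM"
}

#' Reconstruct missing observations in a sensor series
#'
#' The hybrid GAM/ARIMA framework. A penalized-spline additive model of the
#' response on the covariates (plus response lags 1 and 2) is selected once
#' by stepwise AIC on the rows where everything is observed. The series is
#' then swept chronologically; each missing timestamp is predicted
#'
#' * by the GAM, when every column the selected model requires is available
#'   there (lags count previously reconstructed values as available), or
#' * by an ARIMA model otherwise: each maximal consecutive stretch of
#'   ARIMA timestamps is forecast in one multi-step call from a single
#'   model selected by AIC and fit to the `arima_window` working values
#'   immediately preceding the stretch — so prediction intervals widen with
#'   the number of steps into the gap. If a GAM-eligible timestamp
#'   interrupts such a stretch it is predicted by the GAM and the remainder
#'   of the gap starts a fresh ARIMA run.
#'
#' Every reconstructed value enters the working series at once, feeding the
#' lag covariates and later ARIMA histories. Timestamps whose preceding
#' filled history is shorter than `min_history` (a gap at the very start of
#' the record) are labelled `UNFILLED`. Observed values are never altered;
#' their interval bounds equal the observation.
#'
#' @param y response [sensor_series()] with missing entries to fill.
#' @param covariates named list of covariate [sensor_series()] on the same
#'   grid (see [build_design()]).
#' @param control a [recon_control()].
#' @param gam_fit optionally a pre-selected `sf_gam` (skips stepwise
#'   selection; it must have been fit to the same design columns).
#' @return An object of class `reconstruction`: the grid, per-timestamp
#'   `value`, `lower95`/`upper95` bounds, a `method` label in
#'   `OBSERVED | GAM | ARIMA | UNFILLED`, the selected GAM (`gam`), one row
#'   per ARIMA run (`runs`), and the input series (`observed`).
#' @examples
#' \donttest{
#' synth <- generate_synthetic(synth_control(n_days = 30), seed = 1)
#' rec <- reconstruct(synth$series$nitrate, synth$series[-1])
#' summary(rec)
#' }
#' @export
reconstruct <- function(y, covariates, control = recon_control(),
                        gam_fit = NULL) {
  stopifnot(inherits(y, "sensor_series"), inherits(control, "recon_control"))
  design0 <- build_design(y, covariates)
  if (is.null(gam_fit)) {
    gam_fit <- stepwise_gam(design0, y, candidates = control$candidates,
                            k = control$k, bs = control$bs,
                            engine = control$engine)
  }
  stopifnot(inherits(gam_fit, "sf_gam"))
  required <- if (control$strict) control$candidates else gam_fit$selected
  req_cov <- setdiff(required, c("lag1", "lag2"))
  need_lag1 <- "lag1" %in% required
  need_lag2 <- "lag2" %in% required

  n <- y$grid$n
  obs <- y$values
  is_obs <- !is.na(obs)
  cov_ok <- rep(TRUE, n)
  d0 <- as.data.frame(design0)
  for (trm in req_cov) cov_ok <- cov_ok & !is.na(d0[[trm]])

  value <- obs
  lower <- obs
  upper <- obs
  method <- ifelse(is_obs, "OBSERVED", NA_character_)
  working <- obs
  filled <- is_obs

  miss_idx <- which(!is_obs)
  runs_log <- list()

  if (length(miss_idx)) {
    # --- batch fast path -------------------------------------------------
    # Missing timestamps whose required lags are *observed* (not merely
    # filled) can be predicted in one vectorized GAM call: their inputs do
    # not depend on any other reconstruction, so the result is identical to
    # the sequential sweep.
    lag_ok0 <- rep(TRUE, n)
    if (need_lag1) lag_ok0 <- lag_ok0 & !is.na(d0$lag1)
    if (need_lag2) lag_ok0 <- lag_ok0 & !is.na(d0$lag2)
    batch <- miss_idx[cov_ok[miss_idx] & lag_ok0[miss_idx]]
    if (length(batch)) {
      pr <- predict_gam(gam_fit, d0[batch, , drop = FALSE],
                        level = control$level)
      ok <- !is.na(pr$fit)
      bi <- batch[ok]
      value[bi] <- pr$fit[ok]
      lower[bi] <- pr$lower[ok]
      upper[bi] <- pr$upper[ok]
      method[bi] <- "GAM"
      working[bi] <- pr$fit[ok]
      filled[bi] <- TRUE
    }

    # --- sequential sweep ------------------------------------------------
    remaining <- miss_idx[is.na(method[miss_idx])]
    if (length(remaining)) {
      rowpred <- make_row_predictor(gam_fit, design0, level = control$level)
      gam_row <- function(t) {
        l1 <- if (t > 1) working[t - 1] else NA_real_
        l2 <- if (t > 2) working[t - 2] else NA_real_
        if (!is.null(rowpred)) return(rowpred(t, l1, l2))
        nd <- d0[t, , drop = FALSE]
        nd$lag1 <- l1; nd$lag2 <- l2
        pr <- predict_gam(gam_fit, nd, level = control$level)
        c(pr$fit, pr$lower, pr$upper)
      }
      lag_avail <- function(t) {
        ok1 <- !need_lag1 || (t > 1 && filled[t - 1] &&
                                (control$feedback || is_obs[t - 1]))
        ok2 <- !need_lag2 || (t > 2 && filled[t - 2] &&
                                (control$feedback || is_obs[t - 2]))
        ok1 && ok2
      }
      gam_eligible <- function(t) cov_ok[t] && lag_avail(t)

      i <- 1L
      while (i <= length(remaining)) {
        t <- remaining[i]
        if (filled[t]) { i <- i + 1L; next }
        if (gam_eligible(t)) {
          p <- gam_row(t)
          if (!is.na(p[1])) {
            value[t] <- p[1]; lower[t] <- p[2]; upper[t] <- p[3]
            method[t] <- "GAM"; working[t] <- p[1]; filled[t] <- TRUE
            i <- i + 1L
            next
          }
        }
        # ARIMA run starting at t
        hist <- arima_history(working, t, control$arima_window,
                              control$min_history)
        # horizon: the run can extend at most to the next observed timestamp
        hmax <- 1L
        while (t + hmax <= n && !is_obs[t + hmax] && !filled[t + hmax])
          hmax <- hmax + 1L
        if (is.null(hist)) {
          method[t] <- "UNFILLED"
          i <- i + 1L
          next
        }
        fit <- tryCatch({
          ord <- if (length(hist) >= 50)
            select_arima_order(hist, max_p = control$max_p,
                               max_q = control$max_q, max_d = control$max_d,
                               stepwise = control$stepwise_order,
                               kpss_level = control$kpss_level)
          else c(0L, 1L, 0L)
          suppressWarnings(fit_arima(hist, ord))
        }, error = function(e) suppressWarnings(fit_arima(hist, c(0L, 1L, 0L))))
        fc <- forecast(fit, h = hmax, level = control$level)
        j <- 1L
        while (j <= hmax) {
          tt <- t + j - 1L
          value[tt] <- fc$mean[j]; lower[tt] <- fc$lower[j]
          upper[tt] <- fc$upper[j]
          method[tt] <- "ARIMA"; working[tt] <- fc$mean[j]; filled[tt] <- TRUE
          j <- j + 1L
          tn <- t + j - 1L
          if (j <= hmax && gam_eligible(tn)) break  # GAM splits the run
        }
        runs_log[[length(runs_log) + 1L]] <-
          data.frame(start = t, length = j - 1L,
                     history = length(hist),
                     p = fit$order[1], d = fit$order[2], q = fit$order[3],
                     aic = fit$aic)
        if (control$verbose)
          message(sprintf(
            "ARIMA run at %d: length %d, history %d, order (%d,%d,%d), AIC %.1f",
            t, j - 1L, length(hist), fit$order[1], fit$order[2],
            fit$order[3], fit$aic))
        while (i <= length(remaining) && remaining[i] < t + j - 1L)
          i <- i + 1L
      }
    }
  }
  value[method %in% "UNFILLED"] <- NA_real_

  runs <- if (length(runs_log)) do.call(rbind, runs_log) else
    data.frame(start = integer(), length = integer(), history = integer(),
               p = integer(), d = integer(), q = integer(), aic = numeric())
  if (any(method %in% "UNFILLED"))
    warning(sprintf("%d timestamp(s) left UNFILLED (history shorter than min_history)",
                    sum(method %in% "UNFILLED")), call. = FALSE)

  structure(list(grid = y$grid, value = value, lower95 = lower,
                 upper95 = upper, method = method, gam = gam_fit,
                 runs = runs, control = control, observed = y,
                 name = y$name, units = y$units),
            class = "reconstruction")
}

#' History window preceding an ARIMA run
#'
#' Returns the working-series values at grid positions
#' `t - window, ..., t - 1`, truncated at the start of the series, and
#' shrunk to the longest *filled* suffix if any entry inside the window is
#' unfilled. Returns `NULL` (a history error) when fewer than `min_history`
#' values remain — the caller then labels the run `UNFILLED`.
#'
#' @param working numeric working series (observed plus already
#'   reconstructed values; `NA` where unfilled).
#' @param t start index of the run.
#' @param window window length (default 500).
#' @param min_history minimum usable history.
#' @return numeric vector, or `NULL` if the usable history is too short.
#' @export
arima_history <- function(working, t, window = 500L, min_history = 50L) {
  if (t <= 1L) return(NULL)
  lo <- max(1L, t - window)
  vals <- working[lo:(t - 1L)]
  usable <- !is.na(vals)
  if (!all(usable)) {
    last_bad <- max(which(!usable))
    vals <- if (last_bad < length(vals)) vals[(last_bad + 1L):length(vals)]
            else numeric(0)
  }
  if (length(vals) < min_history) return(NULL)
  vals
}

#' @export
print.reconstruction <- function(x, ...) {
  tab <- table(factor(x$method, c("OBSERVED", "GAM", "ARIMA", "UNFILLED")))
  cat(sprintf("<reconstruction> %s [%s], %d timestamps\n", x$name, x$units,
              x$grid$n))
  cat(sprintf("  OBSERVED %d | GAM %d | ARIMA %d | UNFILLED %d\n",
              tab["OBSERVED"], tab["GAM"], tab["ARIMA"], tab["UNFILLED"]))
  cat("  GAM terms:", if (length(x$gam$selected))
    paste(x$gam$selected, collapse = ", ") else "(intercept only)", "\n")
  if (nrow(x$runs)) cat(sprintf("  ARIMA runs: %d (median length %g)\n",
                                nrow(x$runs), stats::median(x$runs$length)))
  invisible(x)
}

#' @export
summary.reconstruction <- function(object, ...) {
  rec <- object$method %in% c("GAM", "ARIMA")
  w <- object$upper95[rec] - object$lower95[rec]
  out <- list(
    n = object$grid$n,
    counts = table(factor(object$method,
                          c("OBSERVED", "GAM", "ARIMA", "UNFILLED"))),
    gam_terms = object$gam$selected,
    gam_aic = object$gam$aic,
    gam_sigma2 = object$gam$sigma2,
    runs = object$runs,
    interval_width = if (length(w))
      stats::quantile(w, c(0, 0.25, 0.5, 0.75, 1), na.rm = TRUE) else NULL)
  class(out) <- "summary.reconstruction"
  out
}

#' @export
print.summary.reconstruction <- function(x, ...) {
  cat("Hybrid GAM/ARIMA reconstruction\n")
  cat(sprintf("  timestamps: %d\n", x$n))
  print(x$counts)
  cat("  selected GAM terms:", if (length(x$gam_terms))
    paste(x$gam_terms, collapse = ", ") else "(intercept only)", "\n")
  cat(sprintf("  GAM AIC %.1f, residual variance %.4g\n", x$gam_aic,
              x$gam_sigma2))
  if (nrow(x$runs)) {
    cat(sprintf("  ARIMA runs: %d\n", nrow(x$runs)))
  }
  if (!is.null(x$interval_width)) {
    cat("  95% interval width of reconstructed values:\n")
    print(round(x$interval_width, 4))
  }
  invisible(x)
}

#' @export
as.data.frame.reconstruction <- function(x, ...) {
  data.frame(timestamp = grid_times(x$grid), value = x$value,
             lower95 = x$lower95, upper95 = x$upper95, method = x$method)
}

#' Plot a reconstruction
#'
#' Observed values in grey, reconstructed values coloured by method with
#' their 95% interval ribbons.
#'
#' @param x a [reconstruct()] result.
#' @param from,to optional index range to display.
#' @param ... passed to `plot`.
#' @export
plot.reconstruction <- function(x, from = 1L, to = x$grid$n, ...) {
  idx <- seq(from, to)
  tt <- grid_times(x$grid)[idx]
  ylim <- range(c(x$value[idx], x$lower95[idx], x$upper95[idx]), na.rm = TRUE)
  graphics::plot(tt, x$value[idx], type = "n", xlab = "time",
                 ylab = paste0(x$name, " [", x$units, "]"), ylim = ylim, ...)
  rec <- idx[x$method[idx] %in% c("GAM", "ARIMA")]
  if (length(rec)) {
    graphics::segments(tt[match(rec, idx)], x$lower95[rec],
                       tt[match(rec, idx)], x$upper95[rec],
                       col = grDevices::adjustcolor("darkgreen", 0.25))
    cols <- ifelse(x$method[rec] == "GAM", "darkgreen", "darkorange3")
    graphics::points(tt[match(rec, idx)], x$value[rec], col = cols,
                     pch = 16, cex = 0.5)
  }
  obsv <- idx[x$method[idx] %in% "OBSERVED"]
  if (length(obsv))
    graphics::points(tt[match(obsv, idx)], x$value[obsv], col = "grey30",
                     pch = 16, cex = 0.35)
  graphics::legend("topleft", bty = "n",
                   legend = c("observed", "GAM", "ARIMA"),
                   col = c("grey30", "darkgreen", "darkorange3"), pch = 16)
  invisible(x)
}

#' Residuals of a reconstruction against a reference series
#'
#' @param object a [reconstruct()] result.
#' @param reference optional [sensor_series()] or numeric vector of true
#'   values; defaults to the observed input (in which case residuals are 0
#'   at observed timestamps and `NA` at reconstructed ones).
#' @param ... unused.
#' @export
residuals.reconstruction <- function(object, reference = NULL, ...) {
  ref <- if (is.null(reference)) object$observed$values
         else if (inherits(reference, "sensor_series")) reference$values
         else as.numeric(reference)
  object$value - ref
}
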