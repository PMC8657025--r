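#' KPSS level-stationarity statistic
#'
#' Kwiatkowski-Phillips-Schmidt-Shin statistic for the null hypothesis that a
#' series is level-stationary: the scaled partial-sum statistic
#' `sum(S_t^2) / (n^2 * lrv)` with a Bartlett-kernel (Newey-West) long-run
#' variance estimate. Used to pick the differencing order `d` before the
#' ARMA order search.
#'
#' @param x numeric series without missing values.
#' @param lags truncation lag of the Bartlett kernel; default
#'   `trunc(4 * (n/100)^0.25)` (the usual "short" bandwidth).
#' @return the statistic (numeric scalar), with the bandwidth as attribute
#'   `"lags"`.
#' @export
kpss_statistic <- function(x, lags = NULL) {
  x <- as.numeric(x)
  if (anyNA(x)) stop("`x` must not contain missing values")
  n <- length(x)
  if (n < 10) stop("series too short for the KPSS statistic")
  if (is.null(lags)) lags <- trunc(4 * (n / 100)^0.25)
  e <- x - mean(x)
  S <- cumsum(e)
  lrv <- sum(e^2) / n
  if (lags > 0) {
    for (l in seq_len(lags)) {
      w <- 1 - l / (lags + 1)
      lrv <- lrv + 2 * w * sum(e[seq_len(n - l)] * e[(l + 1):n]) / n
    }
  }
  if (lrv <= 0) lrv <- sum(e^2) / n
  structure(sum(S^2) / (n^2 * lrv), lags = lags)
}

# 5% default; interpolation is not needed, the standard table levels suffice
kpss_critical <- function(level) {
  tab <- c(`0.10` = 0.347, `0.05` = 0.463, `0.025` = 0.574, `0.01` = 0.739)
  key <- sprintf("%.10g", level)
  hit <- match(key, sprintf("%.10g", c(0.10, 0.05, 0.025, 0.01)))
  if (is.na(hit)) stop("kpss level must be one of 0.10, 0.05, 0.025, 0.01")
  tab[[hit]]
}

# repeated KPSS testing: difference while level stationarity is rejected
kpss_ndiffs <- function(x, level = 0.05, max_d = 2) {
  crit <- kpss_critical(level)
  d <- 0L
  z <- x
  while (d < max_d && length(z) > 10 &&
         as.numeric(kpss_statistic(z)) > crit) {
    z <- diff(z)
    d <- d + 1L
  }
  d
}

#' Select an ARIMA order by AIC
#'
#' Chooses the differencing order `d` (0-2) by repeated KPSS testing at the
#' 5% level, then searches `(p, q)` with `p, q <= 5` at that `d` by a
#' stepwise neighbourhood search minimizing AIC, starting from the models
#' `(0,0)`, `(1,0)`, `(0,1)` and `(2,2)` and moving to the best of the
#' current model's neighbours (`p` or `q` changed by one, or both) until no
#' neighbour improves. A mean term is included when `d = 0`. During the
#' search, candidate models are scored by the conditional-sum-of-squares
#' approximation `n * log(sigma2_CSS) + 2 * npar` (the winning order is
#' subsequently refit by full maximum likelihood in [fit_arima()]); set
#' `approximation = FALSE` to score by exact ML AIC throughout.
#'
#' @param y numeric series, no missing values, length >= 50.
#' @param max_p,max_q,max_d search bounds (defaults 5, 5, 2).
#' @param stepwise logical; `FALSE` searches the full `(p, q)` grid.
#' @param kpss_level level of the KPSS test (0.10, 0.05, 0.025 or 0.01).
#' @param approximation score candidates by CSS approximation (default).
#' @return integer vector `c(p, d, q)` with the searched AIC table as
#'   attribute `"search"`.
#' @export
select_arima_order <- function(y, max_p = 5, max_q = 5, max_d = 2,
                               stepwise = TRUE, kpss_level = 0.05,
                               approximation = TRUE) {
  y <- as.numeric(y)
  if (anyNA(y)) stop("`y` must not contain missing values")
  if (length(y) < 50)
    stop("history error: need at least 50 observations to select an order",
         call. = FALSE)
  d <- kpss_ndiffs(y, level = kpss_level, max_d = max_d)
  z <- if (d > 0) diff(y, differences = d) else y
  incl_mean <- d == 0L
  nz <- length(z)

  seen <- new.env(parent = emptyenv())
  score <- function(p, q) {
    key <- paste(p, q)
    if (!is.null(seen[[key]])) return(seen[[key]])
    a <- suppressWarnings(tryCatch({
      if (approximation) {
        f <- stats::arima(z, order = c(p, 0L, q), include.mean = incl_mean,
                          method = "CSS")
        nz * log(f$sigma2) + 2 * (p + q + 1 + incl_mean)
      } else {
        stats::arima(z, order = c(p, 0L, q), include.mean = incl_mean,
                     method = "CSS-ML")$aic
      }
    }, error = function(e) Inf))
    seen[[key]] <- a
    a
  }

  starts <- unique(list(c(0L, 0L), c(1L, 0L), c(0L, 1L),
                        c(min(2L, max_p), min(2L, max_q))))
  starts <- Filter(function(s) s[1] <= max_p && s[2] <= max_q, starts)
  if (!stepwise) {
    grid <- expand.grid(p = 0:max_p, q = 0:max_q)
    grid$aic <- mapply(score, grid$p, grid$q)
    best <- grid[which.min(grid$aic), ]
    res <- c(p = best$p, d = d, q = best$q)
  } else {
    best <- starts[[1]]
    best_aic <- score(best[1], best[2])
    for (s in starts[-1]) {
      a <- score(s[1], s[2])
      if (a < best_aic) { best <- s; best_aic <- a }
    }
    repeat {
      nb <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1), c(1, 1), c(-1, -1))
      improved <- FALSE
      for (step in nb) {
        p <- best[1] + step[1]; q <- best[2] + step[2]
        if (p < 0 || q < 0 || p > max_p || q > max_q) next
        a <- score(p, q)
        if (a < best_aic - 1e-8) {
          best <- c(p, q); best_aic <- a; improved <- TRUE
        }
      }
      if (!improved) break
    }
    res <- c(p = best[1], d = d, q = best[2])
  }
  tab <- data.frame(key = ls(seen),
                    aic = vapply(ls(seen), function(k) seen[[k]], numeric(1)))
  structure(as.integer(res), names = c("p", "d", "q"), search = tab)
}

#' Fit an ARIMA(p,d,q) model by Gaussian maximum likelihood
#'
#' Wraps `stats::arima` (CSS-initialized full ML via the Kalman filter,
#' falling back to pure ML if that fails). A mean term is included only when
#' `d = 0`, matching the base-R convention, so an ARIMA(0,1,0) fit yields
#' flat (martingale) forecasts. If the ML optimum is non-invertible the MA
#' polynomial is re-parameterized by reflecting the offending roots outside
#' the unit circle (with the innovation variance rescaled accordingly) and a
#' warning is issued.
#'
#' @param y numeric training series, no missing values.
#' @param order integer vector `c(p, d, q)`, e.g. from
#'   [select_arima_order()].
#' @return An object of class `sf_arima` with fields `order`, `ar`, `ma`,
#'   `mean` (intercept, `NA` when `d > 0`), `sigma2`, `aic`, `n` and the
#'   underlying `stats::arima` `model`.
#' @export
fit_arima <- function(y, order) {
  y <- as.numeric(y)
  if (anyNA(y)) stop("`y` must not contain missing values")
  order <- as.integer(order)
  stopifnot(length(order) == 3, all(order >= 0))
  incl_mean <- order[2] == 0L
  model <- tryCatch(
    stats::arima(y, order = order, include.mean = incl_mean,
                 method = "CSS-ML"),
    error = function(e) tryCatch(
      stats::arima(y, order = order, include.mean = incl_mean,
                   method = "ML"),
      error = function(e2)
        stop(sprintf("ARIMA(%d,%d,%d) fit failed: %s", order[1], order[2],
                     order[3], conditionMessage(e2)), call. = FALSE)))
  cf <- stats::coef(model)
  ar <- unname(cf[grep("^ar", names(cf))])
  ma <- unname(cf[grep("^ma", names(cf))])
  mu <- if ("intercept" %in% names(cf)) unname(cf["intercept"]) else NA_real_
  sigma2 <- model$sigma2
  # invertibility: reflect MA roots strictly inside the unit circle
  if (length(ma)) {
    rts <- polyroot(c(1, ma))
    inside <- Mod(rts) < 1 - 1e-8
    if (any(inside)) {
      warning("non-invertible MA optimum; reflecting root(s) outside the unit circle")
      sigma2 <- sigma2 * prod(Mod(rts[inside])^2)
      rts[inside] <- 1 / Conj(rts[inside])
      pc <- Re(poly_from_roots(rts))
      ma <- pc[-1] / pc[1]
      model$coef[grep("^ma", names(cf))] <- ma
      model$sigma2 <- sigma2
    }
  }
  structure(list(model = model, order = stats::setNames(order, c("p", "d", "q")),
                 ar = ar, ma = ma, mean = mu, sigma2 = sigma2,
                 aic = model$aic, n = length(y), y = y,
                 y_last = y[length(y)]),
            class = "sf_arima")
}

# monic polynomial with the given roots, coefficients in ascending order,
# normalized to constant term 1
poly_from_roots <- function(rts) {
  p <- 1
  for (r in rts) p <- c(p, 0) - c(0, p) / r
  p / p[1]
}

#' @export
print.sf_arima <- function(x, ...) {
  cat(sprintf("<sf_arima> ARIMA(%d,%d,%d), n = %d\n",
              x$order[1], x$order[2], x$order[3], x$n))
  if (length(x$ar)) cat("  ar:", paste(sprintf("%.4f", x$ar), collapse = " "), "\n")
  if (length(x$ma)) cat("  ma:", paste(sprintf("%.4f", x$ma), collapse = " "), "\n")
  if (is.finite(x$mean)) cat(sprintf("  mean: %.4f\n", x$mean))
  cat(sprintf("  sigma2 = %.5g, AIC = %.2f\n", x$sigma2, x$aic))
  invisible(x)
}

#' @export
coef.sf_arima <- function(object, ...) stats::coef(object$model)

#' @export
residuals.sf_arima <- function(object, ...) as.numeric(stats::residuals(object$model))

#' One-step-ahead in-sample predictions of an ARIMA fit
#' @param object an `sf_arima`.
#' @param ... unused.
#' @export
fitted.sf_arima <- function(object, ...) {
  object$y - as.numeric(stats::residuals(object$model))
}

#' Forecast generic
#' @param object a fitted model.
#' @param ... passed to methods.
#' @export
forecast <- function(object, ...) UseMethod("forecast")

#' Multi-step ARIMA forecast with 95% prediction intervals
#'
#' Forecast means are the conditional expectations given the training
#' series; the step-`j` forecast variance accumulates the psi-weights,
#' `sigma2 * sum_{i<j} psi_i^2`, so the interval half-width is
#' non-decreasing in the horizon. For a random walk the means are flat at
#' the last training value; for a stationary fit they decay to the
#' unconditional mean as the horizon grows.
#'
#' @param object an `sf_arima` fit.
#' @param h forecast horizon (>= 1).
#' @param level interval level (default 0.95).
#' @param ... unused.
#' @return A data frame of class `sf_forecast` with columns `step`, `mean`,
#'   `lower`, `upper`.
#' @export
forecast.sf_arima <- function(object, h, level = 0.95, ...) {
  stopifnot(h >= 1)
  pr <- stats::predict(object$model, n.ahead = h)
  z <- stats::qnorm((1 + level) / 2)
  m <- as.numeric(pr$pred)
  se <- as.numeric(pr$se)
  out <- data.frame(step = seq_len(h), mean = m,
                    lower = m - z * se, upper = m + z * se)
  attr(out, "level") <- level
  class(out) <- c("sf_forecast", "data.frame")
  out
}
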