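#' Fit the penalized-spline additive model
#'
#' Fits `y = b0 + sum_k s_k(x_k) + e`, `e ~ N(0, sigma2)`, with one penalized
#' spline per requested column. Smoothing parameters are chosen by GCV
#' (`mgcv::gam`, `method = "GCV.Cp"`) for moderate sample sizes and by fast
#' REML with discretized covariates (`mgcv::bam`) for large ones; a fixed
#' smoothing parameter can be forced through `sp` (e.g. `sp = 1e8` shrinks
#' each smooth to its penalty null space, a straight line for these bases).
#'
#' A column with too few distinct values to support a spline basis enters as
#' a plain linear term.
#'
#' @param design a [build_design()] data frame (or any data frame containing
#'   the term columns).
#' @param y response [sensor_series()] or numeric vector.
#' @param terms character vector of term columns (subset of
#'   [gam_candidates()]); empty for an intercept-only model.
#' @param k basis dimension per smooth (default 10).
#' @param bs basis type: `"tp"` thin-plate regression spline (default) or
#'   `"cr"` cubic regression spline.
#' @param sp fixed smoothing parameter(s), recycled over smooths; `NULL`
#'   (default) selects them automatically.
#' @param engine `"auto"` (default; `bam` when the training set has >= 2000
#'   rows, `gam` otherwise), `"gam"`, or `"bam"`.
#' @param rows optional integer vector of training rows; defaults to all rows
#'   where `y` and every term column are non-missing.
#' @return An object of class `sf_gam`: the mgcv fit plus `terms`, `rows`,
#'   `n`, `edf` (trace of the hat matrix), `rss`,
#'   `sigma2` (`RSS / (n - edf)`) and `aic` (see [gam_aic()]).
#' @export
fit_gam <- function(design, y, terms = character(), k = 10,
                    bs = c("tp", "cr"), sp = NULL,
                    engine = c("auto", "gam", "bam"), rows = NULL) {
  bs <- match.arg(bs)
  engine <- match.arg(engine)
  yv <- if (inherits(y, "sensor_series")) y$values else as.numeric(y)
  d <- as.data.frame(design)
  if (length(terms)) {
    bad <- setdiff(terms, names(d))
    if (length(bad))
      stop(sprintf("unknown term column(s): %s", paste(bad, collapse = ", ")))
  }
  if (nrow(d) != length(yv)) stop("design and response lengths differ")
  if (is.null(rows)) {
    ok <- !is.na(yv)
    for (trm in terms) ok <- ok & !is.na(d[[trm]])
    rows <- which(ok)
  }
  n <- length(rows)
  if (n < 2L)
    stop("too few training rows", call. = FALSE)
  if (length(terms) && n < max(10 * length(terms), k + 1))
    stop(sprintf("rank error: %d training rows for %d term(s) (need >= %d)",
                 n, length(terms), max(10 * length(terms), k + 1)),
         call. = FALSE)
  dtr <- d[rows, , drop = FALSE]
  dtr$.y <- yv[rows]

  smooth_terms <- character(0)
  linear_terms <- character(0)
  rhs <- character(0)
  for (trm in terms) {
    nu <- length(unique(dtr[[trm]]))
    ki <- min(k, nu - 1L)
    if (ki >= 3L) {
      smooth_terms <- c(smooth_terms, trm)
      rhs <- c(rhs, sprintf("s(%s, k = %d, bs = \"%s\")", trm, ki, bs))
    } else {
      linear_terms <- c(linear_terms, trm)
      rhs <- c(rhs, trm)
    }
  }
  fml <- stats::as.formula(paste(".y ~", if (length(rhs))
    paste(rhs, collapse = " + ") else "1"))
  if (!is.null(sp) && length(smooth_terms))
    sp <- rep_len(sp, length(smooth_terms))
  else
    sp <- NULL

  use_bam <- switch(engine, bam = TRUE, gam = FALSE,
                    auto = n >= 2000 && length(smooth_terms) > 0)
  fit <- if (use_bam) {
    mgcv::bam(fml, data = dtr, sp = sp, discrete = TRUE, nthreads = 1)
  } else {
    mgcv::gam(fml, data = dtr, sp = sp, method = "GCV.Cp")
  }

  rss <- sum(stats::residuals(fit)^2)
  edf <- sum(fit$edf)
  sigma2 <- if (n - edf > sqrt(.Machine$double.eps)) rss / (n - edf) else rss / n
  out <- list(fit = fit, terms = terms, selected = terms,
              smooth_terms = smooth_terms, linear_terms = linear_terms,
              k = k, bs = bs, engine = if (use_bam) "bam" else "gam",
              rows = rows, n = n, edf = edf, rss = rss,
              sigma2 = sigma2)
  out$aic <- gaussian_gam_aic(n, rss, edf)
  class(out) <- "sf_gam"
  out
}

# AIC = -2 * Gaussian log-likelihood at the profile MLE sigma2 = RSS/n,
# plus 2 * (edf + 1); the +1 counts the variance parameter. For an
# unpenalized fit with p columns this reduces to the textbook Gaussian AIC
# with p + 2 parameters.
gaussian_gam_aic <- function(n, rss, edf) {
  sig2ml <- max(rss / n, .Machine$double.xmin)
  n * log(2 * pi * sig2ml) + n + 2 * (edf + 1)
}

#' Gaussian AIC of an additive-model fit
#'
#' `-2 * logLik + 2 * (edf + 1)`, with the Gaussian log-likelihood evaluated
#' at the fitted values and the profile variance estimate `RSS/n`, and the
#' effective degrees of freedom `edf` equal to the trace of the hat matrix.
#' The `+ 1` counts the variance parameter, so an unpenalized linear fit with
#' `p` covariates scores exactly the textbook Gaussian AIC with `p + 2`
#' parameters. This is the criterion compared by [stepwise_gam()].
#'
#' @param object an `sf_gam` fit.
#' @return numeric scalar.
#' @export
gam_aic <- function(object) {
  stopifnot(inherits(object, "sf_gam"))
  object$aic
}

#' @export
print.sf_gam <- function(x, ...) {
  cat("<sf_gam> additive model (", x$engine, ")\n", sep = "")
  cat("  terms:", if (length(x$terms)) paste(x$terms, collapse = ", ")
      else "(intercept only)", "\n")
  cat(sprintf("  n = %d, edf = %.2f, sigma2 = %.4g, AIC = %.2f\n",
              x$n, x$edf, x$sigma2, x$aic))
  invisible(x)
}

#' @export
coef.sf_gam <- function(object, ...) stats::coef(object$fit)

#' @export
fitted.sf_gam <- function(object, ...) as.numeric(stats::fitted(object$fit))

#' @export
residuals.sf_gam <- function(object, ...) as.numeric(stats::residuals(object$fit))

#' Forward/backward stepwise term selection by AIC
#'
#' Starting from the intercept-only model, alternates single-term additions
#' and removals, at each step accepting the move with the largest AIC
#' decrease, and stops when no move decreases the AIC. All candidate fits use
#' the same training rows — the rows where the response and *all* candidates
#' are present — so their AICs are comparable. Exact AIC ties prefer the
#' smaller model, then the earlier candidate in [gam_candidates()] order.
#'
#' @inheritParams fit_gam
#' @param candidates character vector of candidate columns.
#' @param trace print each accepted move.
#' @return The best `sf_gam`; its `selected` field holds the chosen term set
#'   and `path` records the accepted moves.
#' @export
stepwise_gam <- function(design, y, candidates = gam_candidates(), k = 10,
                         bs = c("tp", "cr"), engine = c("auto", "gam", "bam"),
                         trace = FALSE) {
  bs <- match.arg(bs)
  engine <- match.arg(engine)
  yv <- if (inherits(y, "sensor_series")) y$values else as.numeric(y)
  d <- as.data.frame(design)
  ok <- !is.na(yv)
  for (trm in candidates) ok <- ok & !is.na(d[[trm]])
  rows <- which(ok)
  if (!length(rows))
    stop("selection error: no rows complete for all candidates",
         call. = FALSE)

  cache <- new.env(parent = emptyenv())
  fit_set <- function(terms) {
    key <- paste0("m:", paste(sort(terms), collapse = "|"))
    if (!is.null(cache[[key]])) return(cache[[key]])
    f <- tryCatch(
      fit_gam(design, yv, terms = terms, k = k, bs = bs, engine = engine,
              rows = rows),
      error = function(e) NULL)
    cache[[key]] <- if (is.null(f)) list(aic = Inf) else f
    cache[[key]]
  }

  current <- character(0)
  curfit <- fit_set(current)
  path <- data.frame(move = "<start>", term = NA_character_,
                     aic = curfit$aic, stringsAsFactors = FALSE)
  for (iter in seq_len(100)) {
    # removals first so an exact tie prefers the smaller model
    drops <- intersect(candidates, current)
    adds <- setdiff(candidates, current)
    moves <- rbind(
      if (length(drops)) data.frame(move = "drop", term = drops,
                                    stringsAsFactors = FALSE),
      if (length(adds)) data.frame(move = "add", term = adds,
                                   stringsAsFactors = FALSE))
    if (is.null(moves) || !nrow(moves)) break
    moves$aic <- vapply(seq_len(nrow(moves)), function(i) {
      trms <- if (moves$move[i] == "add") c(current, moves$term[i])
              else setdiff(current, moves$term[i])
      fit_set(trms)$aic
    }, numeric(1))
    best <- which.min(moves$aic)  # first minimum: drop moves listed first
    if (!(moves$aic[best] < curfit$aic - 1e-8)) break
    current <- if (moves$move[best] == "add") c(current, moves$term[best])
               else setdiff(current, moves$term[best])
    curfit <- fit_set(current)
    if (trace)
      message(sprintf("step %d: %s %s -> AIC %.3f", iter, moves$move[best],
                      moves$term[best], curfit$aic))
    path <- rbind(path, data.frame(move = moves$move[best],
                                   term = moves$term[best],
                                   aic = curfit$aic,
                                   stringsAsFactors = FALSE))
  }
  curfit$selected <- curfit$terms
  curfit$path <- path
  curfit$candidates <- candidates
  curfit
}

#' Predict from an additive-model fit with 95% prediction intervals
#'
#' Point prediction is `b0 + sum_k s_k(x_k)`; the interval is
#' `mean +/- z * sqrt(se_fit^2 + sigma2)` where `se_fit` is the standard
#' error of the fitted mean and `sigma2` the residual variance, so the
#' half-width can never drop below `z * sqrt(sigma2)`. Rows missing a column
#' the fit requires get `NA` in every output column (the reconstructor treats
#' that as "fall back to ARIMA").
#'
#' @param object an `sf_gam`.
#' @param newdata data frame (e.g. a [build_design()] result).
#' @param level interval level (default 0.95).
#' @return data frame with columns `fit`, `se_fit`, `lower`, `upper`.
#' @export
predict_gam <- function(object, newdata, level = 0.95) {
  stopifnot(inherits(object, "sf_gam"), level > 0, level < 1)
  nd <- as.data.frame(newdata)
  need <- object$terms
  ok <- rep(TRUE, nrow(nd))
  for (trm in need) ok <- ok & !is.na(nd[[trm]])
  out <- data.frame(fit = rep(NA_real_, nrow(nd)), se_fit = NA_real_,
                    lower = NA_real_, upper = NA_real_)
  if (any(ok)) {
    pr <- mgcv::predict.gam(object$fit, nd[ok, , drop = FALSE], se.fit = TRUE)
    z <- stats::qnorm((1 + level) / 2)
    hw <- z * sqrt(as.numeric(pr$se.fit)^2 + object$sigma2)
    out$fit[ok] <- as.numeric(pr$fit)
    out$se_fit[ok] <- as.numeric(pr$se.fit)
    out$lower[ok] <- out$fit[ok] - hw
    out$upper[ok] <- out$fit[ok] + hw
  }
  out
}

# Fast single-row predictor used in the sequential reconstruction sweep.
#
# During a gap the only columns that change between consecutive predictions
# are the response lags, so the linear-predictor matrix of every *other*
# term can be evaluated once for all rows; per row only the lag smooths'
# basis columns are re-evaluated (mgcv::PredictMat) before taking
# x' beta and x' Vp x. Falls back to predict_gam() when a lag entered the
# model as a parametric (linear) term.
make_row_predictor <- function(object, design, level = 0.95) {
  fit <- object$fit
  nd <- as.data.frame(design)[, setdiff(names(design), ".complete"),
                              drop = FALSE]
  lag_names <- intersect(c("lag1", "lag2"), object$terms)
  if (any(lag_names %in% object$linear_terms)) return(NULL)
  # placeholder lag values so the one-shot lpmatrix call succeeds
  med <- stats::median(nd$lag1, na.rm = TRUE)
  if (!is.finite(med)) med <- 0
  for (v in c("lag1", "lag2")) nd[[v]][is.na(nd[[v]])] <- med
  covs_ok <- rep(TRUE, nrow(nd))
  for (trm in setdiff(object$terms, c("lag1", "lag2")))
    covs_ok <- covs_ok & !is.na(as.data.frame(design)[[trm]])
  nd2 <- nd
  for (trm in setdiff(names(nd2), c("lag1", "lag2")))
    nd2[[trm]][is.na(nd2[[trm]])] <- stats::median(nd2[[trm]], na.rm = TRUE)
  Xp <- try(mgcv::predict.gam(fit, nd2, type = "lpmatrix"), silent = TRUE)
  if (inherits(Xp, "try-error")) return(NULL)
  beta <- stats::coef(fit)
  Vp <- fit$Vp
  lag_smooths <- list()
  for (sm in fit$smooth) {
    v <- sm$term[1]
    if (v %in% c("lag1", "lag2"))
      lag_smooths[[v]] <- list(sm = sm, cols = sm$first.para:sm$last.para)
  }
  z <- stats::qnorm((1 + level) / 2)
  sigma2 <- object$sigma2
  function(t, lag1, lag2) {
    if (!covs_ok[t]) return(c(NA_real_, NA_real_, NA_real_))
    x <- Xp[t, ]
    for (v in names(lag_smooths)) {
      val <- if (v == "lag1") lag1 else lag2
      if (is.na(val)) return(c(NA_real_, NA_real_, NA_real_))
      ls <- lag_smooths[[v]]
      df1 <- stats::setNames(data.frame(val), v)
      x[ls$cols] <- mgcv::PredictMat(ls$sm, df1)
    }
    m <- sum(x * beta)
    se2 <- as.numeric(x %*% Vp %*% x)
    hw <- z * sqrt(max(se2, 0) + sigma2)
    c(m, m - hw, m + hw)
  }
}
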