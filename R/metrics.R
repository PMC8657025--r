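#' Root-mean-square error
#'
#' `sqrt(mean((predicted - true)^2))` over pairs where both entries are
#' present.
#'
#' @param true,predicted equal-length numeric vectors.
#' @return RMSE in the units of the series (umol/L for nitrate).
#' @export
rmse <- function(true, predicted) {
  p <- pair_up(true, predicted)
  sqrt(mean((p$predicted - p$true)^2))
}

#' Proportion of predictions within the sensor precision interval (PWPI)
#'
#' The fraction of pairs with `|predicted - true| <= halfwidth(true)`, the
#' half-width following the sensor precision rule (by default plus-or-minus
#' 2 umol/L below 20 umol/L and plus-or-minus 10% of the reading above).
#' The boundary counts as inside.
#'
#' @param true,predicted equal-length numeric vectors (`true` on the sensor
#'   scale, since the precision rule is evaluated at the true reading).
#' @param spec a [precision_spec()].
#' @return fraction in `[0, 1]`.
#' @export
pwpi <- function(true, predicted, spec = precision_spec()) {
  p <- pair_up(true, predicted)
  hw <- precision_halfwidth(p$true, spec)
  mean(abs(p$predicted - p$true) <= hw)
}

#' Squared Pearson correlation between true and predicted values
#'
#' @param true,predicted equal-length numeric vectors; at least 3 complete
#'   pairs and non-zero variance in both.
#' @return R-squared in `[0, 1]`.
#' @export
r_squared <- function(true, predicted) {
  p <- pair_up(true, predicted, min_n = 3L)
  if (stats::sd(p$true) == 0 || stats::sd(p$predicted) == 0)
    stop("r_squared undefined: zero variance", call. = FALSE)
  stats::cor(p$true, p$predicted)^2
}

pair_up <- function(true, predicted, min_n = 1L) {
  if (length(true) != length(predicted))
    stop("`true` and `predicted` must have equal length", call. = FALSE)
  ok <- !is.na(true) & !is.na(predicted)
  if (sum(ok) < min_n)
    stop(sprintf("need at least %d complete pair(s)", min_n), call. = FALSE)
  list(true = true[ok], predicted = predicted[ok])
}
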