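#' Candidate covariate columns of the additive model
#'
#' The seven candidate columns considered by stepwise selection: the five
#' water-quality covariates (turbidity entering as `log_turbidity`) plus the
#' two autoregressive response lags. This order is also the deterministic
#' tie-break order of [stepwise_gam()].
#'
#' @return character vector of column names.
#' @export
gam_candidates <- function() {
  c("temperature", "conductance", "dissolved_oxygen",
    "log_turbidity", "elevation", "lag1", "lag2")
}

COVARIATE_NAMES <- c("temperature", "conductance", "dissolved_oxygen",
                     "turbidity", "elevation")

#' Assemble the design matrix for the additive model
#'
#' Builds the seven candidate columns on the response grid: the five aligned
#' covariates (turbidity log-transformed via [log_turbidity()]) and the two
#' lagged response columns `lag1`, `lag2`. Lags are drawn from the *working*
#' response — during reconstruction this is the series updated with values
#' already reconstructed, so a point following a filled gap can still be
#' predicted by the GAM. The `.complete` column flags rows where all seven
#' candidates are present (the rows usable for model selection).
#'
#' @param y response [sensor_series()] (nitrate).
#' @param covariates named list of [sensor_series()] on the same grid, with
#'   names `temperature`, `conductance`, `dissolved_oxygen`, `turbidity` (or
#'   `log_turbidity` if already transformed) and `elevation`.
#' @param working optional numeric vector to draw the lag columns from
#'   (defaults to `y$values`).
#' @return A `data.frame` of class `recon_design` with columns
#'   `temperature`, `conductance`, `dissolved_oxygen`, `log_turbidity`,
#'   `elevation`, `lag1`, `lag2`, `.complete`, and the grid as an attribute.
#' @export
build_design <- function(y, covariates, working = NULL) {
  stopifnot(inherits(y, "sensor_series"), is.list(covariates))
  nm <- names(covariates)
  have_logturb <- "log_turbidity" %in% nm
  need <- c("temperature", "conductance", "dissolved_oxygen",
            if (have_logturb) "log_turbidity" else "turbidity", "elevation")
  missing_cov <- setdiff(need, nm)
  if (length(missing_cov))
    stop(sprintf("missing covariate series: %s",
                 paste(missing_cov, collapse = ", ")), call. = FALSE)
  for (v in need) {
    s <- covariates[[v]]
    if (!inherits(s, "sensor_series"))
      stop(sprintf("covariate `%s` is not a sensor_series", v))
    if (!same_grid(s$grid, y$grid))
      stop(sprintf("covariate `%s` is not on the response grid", v),
           call. = FALSE)
  }
  n <- y$grid$n
  if (is.null(working)) working <- y$values
  stopifnot(length(working) == n)
  lt <- if (have_logturb) covariates$log_turbidity$values
        else log_turbidity(covariates$turbidity$values)
  d <- data.frame(
    temperature      = covariates$temperature$values,
    conductance      = covariates$conductance$values,
    dissolved_oxygen = covariates$dissolved_oxygen$values,
    log_turbidity    = lt,
    elevation        = covariates$elevation$values,
    lag1             = c(NA_real_, working[-n]),
    lag2             = c(NA_real_, NA_real_, working[seq_len(max(0, n - 2))])
  )
  d$.complete <- stats::complete.cases(d[gam_candidates()])
  attr(d, "grid") <- y$grid
  class(d) <- c("recon_design", "data.frame")
  d
}
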