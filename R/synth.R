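#' Settings of the synthetic river-chemistry generator
#'
#' Defaults describe a 180-day, 15-minute nitrate record from a small
#' stream with co-located sensors: a seasonal cycle, a weak diel cycle,
#' AR(1) short-range noise, a handful of storm events with a fast
#' (sub-24-hour) rise and slower exponential recession, covariates sampled
#' at their native frequencies (1-minute temperature / conductance /
#' dissolved oxygen / turbidity, 5-minute elevation), right-skewed
#' turbidity, and missingness made of MCAR points plus contiguous sensor
#' outages (including one station-wide outage affecting every covariate).
#'
#' The true covariate effects are fixed smooth shapes with closed forms so
#' every downstream module can be tested against known truth: nitrate falls
#' with temperature (`-0.08 * (T - 10)`), rises with log-turbidity
#' (`1.2 * (log1p(turb) - 1)`) and with elevation (`8 * (z - 98)`);
#' conductance and dissolved oxygen have no direct effect. Storm events add
#' `event_magnitude` umol/L at their peak.
#'
#' @param n_days length of the record in days (default 180).
#' @param baseline mean nitrate level (umol/L).
#' @param diel_amplitude,seasonal_amplitude amplitudes (umol/L) of the
#'   24-hour and annual nitrate cycles.
#' @param ar1_phi lag-1 autocorrelation of the nitrate noise (|phi| < 1).
#' @param noise_sd innovation standard deviation (umol/L) of the AR(1)
#'   nitrate noise.
#' @param n_events number of storm events.
#' @param event_magnitude peak nitrate rise per event (umol/L).
#' @param effects named list of true effect functions applied to the
#'   aligned covariates (`temperature`, `log_turbidity`, `elevation`).
#' @param point_rate named per-variable MCAR deletion rate, applied at each
#'   variable's native sampling frequency.
#' @param outage_steps named list of per-variable outage lengths, in native
#'   steps (e.g. `96` is one day of 15-minute nitrate; `1440` one day of a
#'   1-minute covariate).
#' @param station_outage_days length (days) of one outage common to all
#'   five covariate sensors (a shared power/telemetry failure); `0` for
#'   none.
#' @param start first timestamp (UTC).
#' @return list of class `synth_control`.
#' @export
synth_control <- function(n_days = 180L, baseline = 6,
                          diel_amplitude = 0.8, seasonal_amplitude = 2,
                          ar1_phi = 0.8, noise_sd = 0.5,
                          n_events = 6L, event_magnitude = 40,
                          effects = list(
                            temperature   = function(x) -0.08 * (x - 10),
                            log_turbidity = function(u) 1.2 * (u - 1),
                            elevation     = function(z) 8 * (z - 98)),
                          point_rate = c(nitrate = 0.02, temperature = 0.001,
                                         conductance = 0.001,
                                         dissolved_oxygen = 0.001,
                                         turbidity = 0.001,
                                         elevation = 0.001),
                          outage_steps = list(nitrate = 96L,
                                              temperature = integer(0),
                                              conductance = 1440L,
                                              dissolved_oxygen = integer(0),
                                              turbidity = 1440L,
                                              elevation = integer(0)),
                          station_outage_days = 2,
                          start = "2018-10-01 00:00:00") {
  stopifnot(n_days >= 1, abs(ar1_phi) < 1, noise_sd >= 0,
            diel_amplitude >= 0, seasonal_amplitude >= 0,
            n_events >= 0, event_magnitude >= 0,
            all(point_rate >= 0 & point_rate < 1))
  structure(list(n_days = as.integer(n_days), baseline = baseline,
                 diel_amplitude = diel_amplitude,
                 seasonal_amplitude = seasonal_amplitude,
                 ar1_phi = ar1_phi, noise_sd = noise_sd,
                 n_events = as.integer(n_events),
                 event_magnitude = event_magnitude, effects = effects,
                 point_rate = point_rate, outage_steps = outage_steps,
                 station_outage_days = station_outage_days, start = start),
            class = "synth_control")
}

# stationary AR(1) path with innovation sd `sd`
ar1_noise <- function(n, phi, sd) {
  if (sd == 0) return(numeric(n))
  innov <- stats::rnorm(n, 0, sd)
  if (phi == 0) return(innov)
  x0 <- stats::rnorm(1, 0, sd / sqrt(1 - phi^2))
  as.numeric(stats::filter(innov, phi, method = "recursive", init = x0))
}

# storm pulse: fast rise, exponential recession, normalized to peak 1
event_pulse <- function(u, rise = 0.1, recession = 1.75) {
  p <- ifelse(u >= 0, (1 - exp(-u / rise)) * exp(-u / recession), 0)
  ustar <- rise * log(1 + recession / rise)
  p / ((1 - exp(-ustar / rise)) * exp(-ustar / recession))
}

event_intensity <- function(tau, event_times) {
  e <- numeric(length(tau))
  for (t0 in event_times) e <- e + event_pulse(tau - t0)
  e
}

# per-stage substream seeds: fixed offsets so adding a variable never
# perturbs the draws of another
substream <- function(seed, k) {
  as.integer((as.numeric(seed) + k * 1000003) %% (.Machine$integer.max - 1)) + 1L
}

#' Generate a synthetic nitrate + covariate dataset with known truth
#'
#' Builds the covariates first at their native frequencies (temperature:
#' seasonal + diel sinusoids; elevation: baseflow plus event pulses with
#' exponential recession; turbidity: slowly-varying log-normal baseline plus
#' event spikes; conductance: baseline with event dilution dips; dissolved
#' oxygen: diel cycle anti-correlated with temperature), aligns them to the
#' 15-minute grid, and then composes nitrate as baseline + seasonal + diel
#' + the fixed covariate effects + the storm-event term + AR(1) noise.
#' Missingness (MCAR points and contiguous outages, per
#' [synth_control()]) is injected afterwards, so the pre-degradation truth
#' is known exactly.
#'
#' @param control a [synth_control()].
#' @param seed integer seed; the same `control` and `seed` reproduce the
#'   output bitwise.
#' @return list with
#'   `series`: named list of degraded [sensor_series()] on the 15-minute
#'   grid (`nitrate`, `temperature`, `conductance`, `dissolved_oxygen`,
#'   `turbidity`, `elevation`);
#'   `truth`: list with the `deterministic` nitrate component, the AR(1)
#'   `noise` (their sum `latent` is the pre-degradation nitrate), the true
#'   `effects`, `event_times` (days from start), per-variable injected
#'   missing `masks` on the grid, and the `clean` (pre-degradation) aligned
#'   series; and `grid`, the 15-minute [time_grid()].
#' @export
generate_synthetic <- function(control = synth_control(), seed = 1L) {
  stopifnot(inherits(control, "synth_control"))
  nd <- control$n_days
  grid15 <- time_grid(control$start, 900, nd * 96L)
  grid1  <- time_grid(control$start, 60,  nd * 1440L)
  grid5  <- time_grid(control$start, 300, nd * 288L)
  tau15 <- (seq_len(grid15$n) - 1) / 96
  tau1  <- (seq_len(grid1$n) - 1) / 1440
  tau5  <- (seq_len(grid5$n) - 1) / 288
  doy0 <- 274  # 1 October

  set.seed(substream(seed, 1))
  event_times <- if (control$n_events > 0)
    sort(stats::runif(control$n_events, 2, max(2.5, nd - 3))) else numeric(0)
  e1  <- event_intensity(tau1, event_times)
  e5  <- event_intensity(tau5, event_times)
  e15 <- event_intensity(tau15, event_times)

  seasonal <- function(tau, peak_doy, amp)
    amp * cos(2 * pi * (tau + doy0 - peak_doy) / 365.25)

  set.seed(substream(seed, 2))
  temp_det <- 10 + seasonal(tau1, 195, 8) + 3 * sin(2 * pi * (tau1 - 0.25))
  temperature <- temp_det + stats::rnorm(grid1$n, 0, 0.3)

  set.seed(substream(seed, 3))
  conductance <- 500 + seasonal(tau1, 30, 60) - 200 * e1 / (1 + e1) +
    stats::rnorm(grid1$n, 0, 3)
  conductance <- pmax(conductance, 0)

  set.seed(substream(seed, 4))
  dissolved_oxygen <- 9 - 1.8 * sin(2 * pi * (tau1 - 0.25)) -
    0.15 * (temp_det - 10) + stats::rnorm(grid1$n, 0, 0.15)

  set.seed(substream(seed, 5))
  turbidity <- exp(1 + ar1_noise(grid1$n, 0.9995, 0.02)) + 60 * e1

  set.seed(substream(seed, 6))
  elevation <- 98 + 0.25 * e5 + stats::rnorm(grid5$n, 0, 0.002)

  native <- list(
    temperature      = sensor_series(temperature, grid1, "temperature", "degC"),
    conductance      = sensor_series(conductance, grid1, "conductance", "uS/cm"),
    dissolved_oxygen = sensor_series(dissolved_oxygen, grid1,
                                     "dissolved_oxygen", "mg/L"),
    turbidity        = sensor_series(turbidity, grid1, "turbidity", "FNU"),
    elevation        = sensor_series(elevation, grid5, "elevation", "m"))

  clean15 <- lapply(native, function(s)
    align_to_grid(grid_times(s$grid), s$values, grid15, s$name, s$units))

  eff <- control$effects
  deterministic <- control$baseline +
    seasonal(tau15, 15, control$seasonal_amplitude) +
    control$diel_amplitude * sin(2 * pi * (tau15 - 0.6)) +
    eff$temperature(clean15$temperature$values) +
    eff$log_turbidity(log_turbidity(clean15$turbidity$values)) +
    eff$elevation(clean15$elevation$values) +
    control$event_magnitude * e15

  set.seed(substream(seed, 7))
  noise <- ar1_noise(grid15$n, control$ar1_phi, control$noise_sd)
  latent <- deterministic + noise
  nitrate_clean <- sensor_series(latent, grid15, "nitrate", "umol/L")

  # --- missingness -------------------------------------------------------
  pr <- control$point_rate
  ot <- control$outage_steps
  deg_native <- native
  vars <- names(native)
  for (i in seq_along(vars)) {
    v <- vars[i]
    deg_native[[v]] <- inject_missingness(
      native[[v]], point_rate = if (v %in% names(pr)) pr[[v]] else 0,
      outages = if (v %in% names(ot)) ot[[v]] else integer(0),
      seed = substream(seed, 8 + i))
  }
  if (control$station_outage_days > 0) {
    set.seed(substream(seed, 20))
    t0 <- stats::runif(1, 0, nd - control$station_outage_days)
    t1 <- t0 + control$station_outage_days
    for (v in vars) {
      g <- deg_native[[v]]$grid
      tau <- (seq_len(g$n) - 1) * g$step / 86400
      deg_native[[v]]$values[tau >= t0 & tau < t1] <- NA_real_
    }
  }
  nitrate_deg <- inject_missingness(nitrate_clean,
                                    point_rate = pr[["nitrate"]],
                                    outages = ot[["nitrate"]],
                                    seed = substream(seed, 8))

  deg15 <- lapply(deg_native, function(s)
    align_to_grid(grid_times(s$grid), s$values, grid15, s$name, s$units))

  masks <- c(list(nitrate = is.na(nitrate_deg$values)),
             lapply(vars, function(v)
               is.na(deg15[[v]]$values) & !is.na(clean15[[v]]$values)))
  names(masks) <- c("nitrate", vars)

  list(series = c(list(nitrate = nitrate_deg), deg15),
       truth = structure(list(deterministic = deterministic, noise = noise,
                              latent = latent, effects = eff,
                              event_times = event_times, masks = masks,
                              clean = c(list(nitrate = nitrate_clean),
                                        clean15),
                              seed = seed, control = control),
                         class = "synth_truth"),
       grid = grid15)
}

#' Inject missingness into a sensor series
#'
#' MCAR point deletion at rate `point_rate` plus contiguous outages of the
#' requested lengths, placed uniformly at random without overlapping each
#' other (overlap with pre-existing missing stretches is allowed).
#'
#' @param series a [sensor_series()].
#' @param point_rate per-entry deletion probability in `[0, 1)`.
#' @param outages integer vector of outage lengths, in grid steps.
#' @param seed optional integer for reproducibility.
#' @return the degraded [sensor_series()].
#' @export
inject_missingness <- function(series, point_rate = 0, outages = integer(0),
                               seed = NULL) {
  stopifnot(inherits(series, "sensor_series"),
            point_rate >= 0, point_rate < 1)
  if (!is.null(seed)) set.seed(seed)
  n <- series$grid$n
  out <- series
  if (point_rate > 0)
    out$values[stats::runif(n) < point_rate] <- NA_real_
  starts <- integer(0)
  lens <- integer(0)
  for (L in as.integer(outages)) {
    if (L < 1) next
    if (L > n) stop("outage longer than the series", call. = FALSE)
    for (attempt in seq_len(1000)) {
      s <- sample.int(n - L + 1L, 1L)
      if (!any(s <= starts + lens - 1L & s + L - 1L >= starts)) {
        starts <- c(starts, s); lens <- c(lens, L)
        out$values[s:(s + L - 1L)] <- NA_real_
        break
      }
      if (attempt == 1000)
        stop("could not place non-overlapping outages", call. = FALSE)
    }
  }
  out
}

#' Pair reconstructed values with the generator's ground truth
#'
#' Restricts to the nitrate positions whose missingness was *injected* by
#' the generator, returning `(true, predicted)` pairs for the metric
#' functions. Positions that were already missing in the pre-degradation
#' truth are excluded (for synthetic data the latent truth is complete, so
#' this only matters when a custom truth is supplied).
#'
#' @param reconstruction a [reconstruct()] result on the degraded series.
#' @param truth the `truth` component of [generate_synthetic()].
#' @return data frame with columns `index`, `true`, `predicted`
#'   (`predicted` is `NA` for `UNFILLED` positions).
#' @export
truth_errors <- function(reconstruction, truth) {
  stopifnot(inherits(reconstruction, "reconstruction"),
            inherits(truth, "synth_truth"))
  if (reconstruction$grid$n != length(truth$latent))
    stop("grid mismatch between reconstruction and truth", call. = FALSE)
  idx <- which(truth$masks$nitrate & !is.na(truth$latent))
  data.frame(index = idx, true = truth$latent[idx],
             predicted = reconstruction$value[idx])
}
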