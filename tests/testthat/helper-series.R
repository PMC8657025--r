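# shared fixtures, all built in code

make_grid <- function(n, step = 900, start = "2020-01-01 00:00:00") {
  time_grid(start, step, n)
}

# five covariate series with simple deterministic structure on one grid
make_covariates <- function(grid, seed = 1) {
  set.seed(seed)
  n <- grid$n
  tau <- (seq_len(n) - 1) / 96
  list(
    temperature = sensor_series(10 + 3 * sin(2 * pi * tau) + rnorm(n, 0, 0.1),
                                grid, "temperature", "degC"),
    conductance = sensor_series(500 + rnorm(n, 0, 2), grid, "conductance",
                                "uS/cm"),
    dissolved_oxygen = sensor_series(9 - sin(2 * pi * tau) + rnorm(n, 0, 0.1),
                                     grid, "dissolved_oxygen", "mg/L"),
    turbidity = sensor_series(exp(rnorm(n, 1, 0.4)), grid, "turbidity", "FNU"),
    elevation = sensor_series(98 + 0.05 * sin(2 * pi * tau / 30) +
                                rnorm(n, 0, 0.002), grid, "elevation", "m"))
}

# response that is an exact additive function of the covariates plus AR noise
make_response <- function(grid, covs, noise_sd = 0.2, phi = 0.5, seed = 2) {
  set.seed(seed)
  innov <- rnorm(grid$n, 0, noise_sd)
  eps <- if (noise_sd > 0)
    as.numeric(stats::filter(innov, phi, method = "recursive")) else innov
  vals <- 6 - 0.1 * (covs$temperature$values - 10) +
    1.5 * (log1p(covs$turbidity$values) - 1) +
    8 * (covs$elevation$values - 98) + eps
  sensor_series(vals, grid, "nitrate", "umol/L")
}
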