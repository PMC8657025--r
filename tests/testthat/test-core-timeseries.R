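test_that("time_grid validates its fields and produces regular timestamps", {
  g <- make_grid(96)
  tt <- grid_times(g)
  expect_length(tt, 96)
  expect_true(all(diff(as.numeric(tt)) == 900))
  expect_identical(tt[1], g$start)
  expect_error(time_grid("2020-01-01", step = 0, n = 10), "positive")
  expect_error(time_grid("2020-01-01", step = 900, n = 0), "positive")
  expect_error(time_grid("not a date", 900, 10), "unparseable")
})

test_that("sensor_series enforces length and finiteness, maps NaN to missing", {
  g <- make_grid(4)
  expect_error(sensor_series(1:3, g), "length")
  expect_error(sensor_series(c(1, Inf, 3, 4), g), "finite")
  s <- sensor_series(c(1, NaN, NA, 4), g)
  expect_identical(is.na(s$values), c(FALSE, TRUE, TRUE, FALSE))
})

test_that("align_to_grid averages raw values into half-open windows", {
  g <- make_grid(2)
  # 1-minute values 1..15 inside the first 15-minute window
  tt <- g$start + 60 * (0:14)
  s <- align_to_grid(tt, 1:15, g)
  expect_equal(s$values[1], 8.0)
  expect_true(is.na(s$values[2]))  # second window holds nothing
  # three 5-minute values in one window
  s2 <- align_to_grid(g$start + c(0, 300, 600), c(10, 12, 14), g)
  expect_equal(s2$values[1], 12.0)
  # a value at exactly the second window's start belongs to the second window
  s3 <- align_to_grid(g$start + c(0, 900), c(1, 5), g)
  expect_equal(s3$values, c(1, 5))
})

test_that("aggregation conserves the grand mean for a complete finer grid", {
  g <- make_grid(20)
  set.seed(42)
  for (sub_step in c(60, 300, 450)) {
    m <- 900 / sub_step
    tt <- g$start + sub_step * (0:(20 * m - 1))
    v <- rnorm(20 * m)
    a <- align_to_grid(tt, v, g)
    expect_equal(mean(a$values), mean(v))
  }
})

test_that("unparseable timestamps name the offending row", {
  err <- tryCatch(align_to_grid(c("2020-01-01 00:00:00", "garbage"),
                                c(1, 2), make_grid(2)),
                  error = function(e) conditionMessage(e))
  expect_match(err, "row 2")
  expect_match(err, "garbage")
})

test_that("log_turbidity transforms, propagates missing, rejects negatives", {
  expect_equal(log_turbidity(0), 0)
  expect_equal(log_turbidity(exp(1) - 1), 1)
  expect_true(is.na(log_turbidity(NA)))
  expect_equal(log_turbidity(c(0, NA, exp(2) - 1)), c(0, NA, 2))
  expect_error(log_turbidity(-0.5), "negative")
})

test_that("precision rule is continuous at the threshold and piecewise as stated", {
  spec <- precision_spec()
  expect_equal(spec$abs_halfwidth, spec$rel_halfwidth * spec$threshold)
  eps <- 1e-9
  expect_equal(precision_halfwidth(20 - eps, spec),
               precision_halfwidth(20 + eps, spec), tolerance = 1e-6)
  expect_equal(precision_halfwidth(c(5, 19.99, 30, 100), spec),
               c(2, 2, 3, 10))
  expect_warning(precision_spec(20, 3, 0.1), "discontinuous")
  expect_error(precision_spec(threshold = -1), "positive")
})

test_that("build_design assembles lags and the completeness mask", {
  g <- make_grid(200)
  covs <- make_covariates(g)
  y <- make_response(g, covs)
  d <- build_design(y, covs)
  expect_s3_class(d, "recon_design")
  expect_named(d, c(gam_candidates(), ".complete"), ignore.order = TRUE)
  # lag columns shift the working response
  expect_true(is.na(d$lag1[1]) && is.na(d$lag2[1]) && is.na(d$lag2[2]))
  expect_equal(d$lag1[-1], y$values[-200])
  expect_equal(d$lag2[-(1:2)], y$values[1:198])
  # first rows can never be complete (undefined lags)
  expect_false(any(d$.complete[1:2]))
  expect_true(all(d$.complete[3:200]))
  # a missing covariate breaks completeness at that row only
  covs2 <- covs
  covs2$turbidity$values[50] <- NA
  d2 <- build_design(y, covs2)
  expect_false(d2$.complete[50])
  expect_true(d2$.complete[51])
  # deterministic and idempotent
  expect_identical(build_design(y, covs), d)
})

test_that("build_design rejects mismatched grids and absent covariates", {
  g <- make_grid(50)
  covs <- make_covariates(g)
  y <- make_response(g, covs)
  covs_bad <- covs
  covs_bad$elevation <- sensor_series(rep(98, 49), make_grid(49), "elevation")
  expect_error(build_design(y, covs_bad), "grid")
  expect_error(build_design(y, covs[-1]), "temperature")
})

test_that("reconstruction CSV round-trips values, intervals and method labels", {
  g <- make_grid(300)
  covs <- make_covariates(g)
  y <- make_response(g, covs)
  y$values[c(100, 150)] <- NA
  rec <- suppressWarnings(reconstruct(y, covs))
  path <- withr::local_tempfile(fileext = ".csv")
  write_reconstruction(rec, path)
  back <- read_reconstruction(path)
  expect_equal(back$value, rec$value, tolerance = 1e-12)
  expect_equal(back$lower95, rec$lower95, tolerance = 1e-12)
  expect_equal(back$upper95, rec$upper95, tolerance = 1e-12)
  expect_identical(back$method, rec$method)
  expect_equal(as.numeric(grid_times(back$grid)),
               as.numeric(grid_times(rec$grid)))
})

test_that("read_sensor_csv parses series, treats empty/NA/NaN as missing", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,nitrate",
               "2020-01-01T00:00:00Z,4.2",
               "2020-01-01T00:15:00Z,",
               "2020-01-01T00:30:00Z,NA",
               "2020-01-01T00:45:00Z,NaN",
               "2020-01-01T01:00:00Z,5.0"), path)
  out <- read_sensor_csv(path)
  expect_named(out, "nitrate")
  s <- out$nitrate
  expect_equal(s$grid$step, 900)
  expect_equal(s$values, c(4.2, NA, NA, NA, 5.0))
  expect_error(read_sensor_csv(path, timestamp_col = "time"),
               "missing required column")
})

test_that("config files are validated against the known keys", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("recon.arima_window: 400", "gam.k: 12",
               "recon.feedback: false"), path)
  cfg <- read_config(path)
  expect_identical(cfg$`recon.arima_window`, 400L)
  ctl <- streamfill:::apply_config(cfg)
  expect_identical(ctl$arima_window, 400L)
  expect_identical(ctl$k, 12L)
  expect_false(ctl$feedback)
  writeLines("recon.bogus: 1", path)
  expect_error(read_config(path), "unknown config key.*recon.bogus")
  writeLines("recon.arima_window: maybe", path)
  expect_error(read_config(path), "must be integer")
})
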