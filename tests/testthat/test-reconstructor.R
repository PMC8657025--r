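test_that("choose_method follows covariate availability and the selected set", {
  g <- make_grid(300)
  covs <- make_covariates(g)
  y <- make_response(g, covs)
  covs$conductance$values[100] <- NA
  d <- build_design(y, covs)
  all7 <- gam_candidates()
  expect_identical(choose_method(d, 50, all7), "GAM")
  expect_identical(choose_method(d, 100, all7), "ARIMA")
  # the missing covariate was dropped by selection -> GAM
  expect_identical(choose_method(d, 100, c("temperature", "lag1")), "GAM")
})

test_that("a gap-free series is returned unchanged, all labels OBSERVED", {
  g <- make_grid(400)
  covs <- make_covariates(g)
  y <- make_response(g, covs)
  rec <- reconstruct(y, covs)
  expect_identical(rec$value, y$values)
  expect_identical(rec$lower95, y$values)
  expect_identical(rec$upper95, y$values)
  expect_true(all(rec$method == "OBSERVED"))
  expect_identical(nrow(rec$runs), 0L)
})

test_that("an isolated missing point with covariates present is GAM-filled", {
  g <- make_grid(500)
  covs <- make_covariates(g)
  y0 <- make_response(g, covs)
  y <- y0
  y$values[250] <- NA
  rec <- reconstruct(y, covs)
  expect_identical(rec$method[250], "GAM")
  expect_true(all(rec$method[-250] == "OBSERVED"))
  expect_true(is.finite(rec$lower95[250]) && is.finite(rec$upper95[250]))
  expect_true(rec$lower95[250] <= rec$value[250] &&
                rec$value[250] <= rec$upper95[250])
  # the point prediction follows the surrounding data closely
  expect_lt(abs(rec$value[250] - y0$values[250]), 1.5)
  # observed values never altered
  expect_identical(rec$value[-250], y0$values[-250])
})

test_that("a covariate-free gap is one ARIMA run with widening intervals", {
  g <- make_grid(2000)
  covs <- make_covariates(g)
  y <- make_response(g, covs)
  gap <- 1001:1672  # 672 steps = one week
  y$values[gap] <- NA
  for (v in names(covs)) covs[[v]]$values[gap] <- NA
  rec <- reconstruct(y, covs, recon_control(strict = TRUE))
  expect_true(all(rec$method[gap] == "ARIMA"))
  expect_identical(nrow(rec$runs), 1L)
  expect_identical(rec$runs$start, 1001L)
  expect_identical(rec$runs$length, 672L)
  expect_identical(rec$runs$history, 500L)
  hw <- (rec$upper95[gap] - rec$lower95[gap]) / 2
  expect_true(all(diff(hw) >= -1e-8))
  expect_gt(hw[672], hw[1])
})

test_that("a leading gap shorter than min_history stays UNFILLED", {
  g <- make_grid(600)
  covs <- make_covariates(g)
  y <- make_response(g, covs)
  y$values[1:30] <- NA
  for (v in names(covs)) covs[[v]]$values[1:30] <- NA
  expect_warning(rec <- reconstruct(y, covs, recon_control(strict = TRUE)),
                 "UNFILLED")
  expect_true(all(rec$method[1:30] == "UNFILLED"))
  expect_true(all(is.na(rec$value[1:30])))
  expect_true(all(is.na(rec$lower95[1:30])))
  expect_true(all(rec$method[31:600] == "OBSERVED"))
})

test_that("every originally missing timestamp gets a terminal label", {
  synth <- generate_synthetic(synth_control(n_days = 20, n_events = 2),
                              seed = 3)
  y <- synth$series$nitrate
  rec <- suppressWarnings(reconstruct(y, synth$series[-1]))
  miss <- which(is.na(y$values))
  expect_true(all(rec$method[miss] %in% c("GAM", "ARIMA", "UNFILLED")))
  expect_true(all(rec$method[-miss] == "OBSERVED"))
  expect_identical(rec$value[-miss], y$values[-miss])
  filled <- rec$method %in% c("GAM", "ARIMA")
  expect_true(all(is.finite(rec$value[filled])))
  expect_true(all(rec$lower95[filled] <= rec$value[filled] &
                    rec$value[filled] <= rec$upper95[filled]))
})

test_that("method attribution matches covariate availability row-by-row", {
  g <- make_grid(1500)
  covs <- make_covariates(g)
  y <- make_response(g, covs)
  set.seed(31)
  miss <- sort(sample(600:1400, 120))
  y$values[miss] <- NA
  covgap <- 900:1000
  covs$dissolved_oxygen$values[covgap] <- NA
  rec <- reconstruct(y, covs, recon_control(strict = TRUE))
  d <- build_design(y, covs)
  for (t in miss) {
    expected <- if (all(!is.na(as.data.frame(d)[t, setdiff(gam_candidates(),
                                                           c("lag1", "lag2"))])))
      NULL else "ARIMA"
    if (!is.null(expected)) expect_identical(rec$method[t], expected)
  }
  # points with all covariates present and observed/filled lags must be GAM
  iso <- setdiff(miss, c(covgap, covgap + 1, covgap + 2))
  expect_true(all(rec$method[iso] == "GAM"))
})

test_that("without feedback, lag-dependent points fall back to ARIMA", {
  g <- make_grid(800)
  covs <- make_covariates(g)
  y <- make_response(g, covs)
  y$values[600:601] <- NA
  rec_fb <- reconstruct(y, covs, recon_control(strict = TRUE))
  expect_identical(rec_fb$method[600:601], c("GAM", "GAM"))
  rec_nofb <- reconstruct(y, covs,
                          recon_control(strict = TRUE, feedback = FALSE))
  expect_identical(rec_nofb$method[600], "GAM")
  expect_identical(rec_nofb$method[601], "ARIMA")
})

test_that("GAM reconstructions beat ARIMA over the same gap when covariates drive the truth", {
  g <- make_grid(2500)
  covs <- make_covariates(g)
  y <- make_response(g, covs, noise_sd = 0.1, phi = 0.3)
  truth <- y$values
  gap <- 1501:1692  # two days
  y_gam <- y; y_gam$values[gap] <- NA
  rec_gam <- reconstruct(y_gam, covs)
  covs_blank <- covs
  for (v in names(covs_blank)) covs_blank[[v]]$values[gap] <- NA
  y_ari <- y; y_ari$values[gap] <- NA
  rec_ari <- reconstruct(y_ari, covs_blank, recon_control(strict = TRUE))
  expect_true(all(rec_ari$method[gap] == "ARIMA"))
  expect_true(all(rec_gam$method[gap] == "GAM"))
  expect_lt(rmse(truth[gap], rec_gam$value[gap]),
            rmse(truth[gap], rec_ari$value[gap]))
})

test_that("arima_history truncates, shrinks past unfilled entries, and errors out", {
  w <- as.numeric(1:1000)
  expect_identical(arima_history(w, 601, 500), w[101:600])
  expect_identical(arima_history(w, 301, 500, min_history = 50), w[1:300])
  expect_null(arima_history(w, 31, 500, min_history = 50))
  w2 <- w; w2[550] <- NA
  expect_identical(arima_history(w2, 601, 500), w[551:600])
  w3 <- w; w3[598] <- NA
  expect_null(arima_history(w3, 601, 500, min_history = 50))
})

test_that("summary, print and as.data.frame expose the reconstruction", {
  g <- make_grid(400)
  covs <- make_covariates(g)
  y <- make_response(g, covs)
  y$values[c(200, 300)] <- NA
  rec <- reconstruct(y, covs)
  expect_output(print(rec), "GAM 2")
  s <- summary(rec)
  expect_s3_class(s, "summary.reconstruction")
  expect_identical(unname(s$counts["GAM"]), 2L)
  df <- as.data.frame(rec)
  expect_identical(nrow(df), 400L)
  expect_named(df, c("timestamp", "value", "lower95", "upper95", "method"))
})
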