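test_that("a noiseless linear signal is recovered exactly (OLS oracle)", {
  set.seed(1)
  n <- 200
  d <- data.frame(temperature = runif(n, 0, 10))
  y <- 2 + 3 * d$temperature
  fit <- fit_gam(d, y, terms = "temperature", engine = "gam")
  ols <- lm(y ~ temperature, data = d)
  expect_lt(max(abs(fitted(fit) - fitted(ols))), 1e-6)
})

test_that("constant response gives the constant intercept and ~zero variance", {
  d <- data.frame(x = 1:50)
  fit <- fit_gam(d, rep(5, 50), terms = character())
  expect_equal(unname(coef(fit)[1]), 5)
  expect_lt(fit$sigma2, 1e-20)
})

test_that("a smooth nonlinear signal is recovered within noise level", {
  set.seed(7)
  n <- 1000
  d <- data.frame(x = sort(runif(n, 0, 2 * pi)))
  y <- sin(d$x) + rnorm(n, 0, 0.1)
  names(d) <- "temperature"
  fit <- fit_gam(d, y, terms = "temperature", engine = "gam")
  expect_lt(max(abs(fitted(fit) - sin(d$temperature))), 0.1)
  # independent penalized-spline oracle: smooth.spline with GCV
  oracle <- smooth.spline(d$temperature, y)
  expect_lt(max(abs(fitted(fit) - fitted(oracle))), 0.1)
})

test_that("AIC of an unpenalized linear fit equals the textbook closed form", {
  set.seed(3)
  n <- 120
  # three distinct values force a parametric (pure linear) term
  d <- data.frame(temperature = sample(c(1, 2, 3), n, replace = TRUE))
  y <- 1 + 0.5 * d$temperature + rnorm(n, 0, 0.3)
  fit <- fit_gam(d, y, terms = "temperature")
  ols <- lm(y ~ temperature, data = d)
  rss <- sum(resid(ols)^2)
  closed_form <- n * log(2 * pi * rss / n) + n + 2 * (2 + 1)
  expect_equal(gam_aic(fit), closed_form, tolerance = 1e-8)
  expect_equal(gam_aic(fit), AIC(ols), tolerance = 1e-8)
  # identical fits give identical AIC
  expect_identical(gam_aic(fit), gam_aic(fit_gam(d, y, terms = "temperature")))
})

test_that("adding a pure-noise smooth usually increases the AIC", {
  worse <- 0
  for (s in 1:20) {
    set.seed(s)
    n <- 2000
    d <- data.frame(x1 = runif(n), x2 = runif(n))
    y <- sin(2 * pi * d$x1) + rnorm(n, 0, 0.3)
    rows <- seq_len(n)
    a1 <- gam_aic(fit_gam(d, y, terms = "x1", rows = rows))
    a2 <- gam_aic(fit_gam(d, y, terms = c("x1", "x2"), rows = rows))
    if (a2 > a1) worse <- worse + 1
  }
  expect_gte(worse, 14)  # ~84% in expectation; see the AIC penalty argument
})

test_that("huge smoothing penalty collapses each smooth to its linear null space", {
  set.seed(11)
  n <- 300
  d <- data.frame(temperature = runif(n, 0, 10), elevation = runif(n))
  y <- 1 + 0.3 * d$temperature - 2 * d$elevation + rnorm(n, 0, 0.2)
  fit <- fit_gam(d, y, terms = c("temperature", "elevation"), sp = 1e8,
                 engine = "gam")
  ols <- lm(y ~ temperature + elevation, data = d)
  expect_lt(max(abs(fitted(fit) - fitted(ols))), 1e-6)
})

test_that("fitted values are invariant to affine rescaling of a covariate", {
  set.seed(13)
  n <- 400
  d <- data.frame(temperature = runif(n, 0, 10))
  y <- sin(d$temperature) + rnorm(n, 0, 0.2)
  f1 <- fit_gam(d, y, terms = "temperature", engine = "gam")
  d2 <- data.frame(temperature = 2 * d$temperature + 5)
  f2 <- fit_gam(d2, y, terms = "temperature", engine = "gam")
  expect_lt(max(abs(fitted(f1) - fitted(f2))), 1e-5)
})

test_that("rank and training-row preconditions are enforced", {
  d <- data.frame(x = runif(8))
  y <- rnorm(8)
  expect_error(fit_gam(d, y, terms = "x", k = 10), "rank error")
  expect_error(stepwise_gam(data.frame(x = rep(NA_real_, 20)), rnorm(20),
                            candidates = "x"), "no rows complete")
})

test_that("stepwise selection finds a strong single-covariate signal", {
  set.seed(5)
  n <- 2000
  d <- data.frame(x1 = runif(n), x2 = runif(n), x3 = runif(n))
  y <- 3 * sin(2 * pi * d$x1) + rnorm(n, 0, 0.3)
  fit <- stepwise_gam(d, y, candidates = c("x1", "x2", "x3"))
  expect_true("x1" %in% fit$selected)
  # selection optimality over the visited models
  rows <- fit$rows
  expect_lte(fit$aic, gam_aic(fit_gam(d, y, terms = character(), rows = rows)))
  expect_lte(fit$aic,
             gam_aic(fit_gam(d, y, terms = c("x1", "x2", "x3"), rows = rows)))
})

test_that("empty candidate list yields the intercept-only model", {
  d <- data.frame(x = runif(60))
  fit <- stepwise_gam(d, rnorm(60), candidates = character())
  expect_identical(fit$selected, character(0))
})

test_that("prediction intervals obey their closed forms", {
  set.seed(9)
  n <- 150
  d <- data.frame(temperature = runif(n, 0, 10))
  y <- 2 + sin(d$temperature) + rnorm(n, 0, 0.3)
  fit <- fit_gam(d, y, terms = "temperature", engine = "gam")
  pr <- predict_gam(fit, d)
  # training-row prediction equals the fitted value
  expect_equal(pr$fit, fitted(fit), tolerance = 1e-8)
  # halfwidth can never undercut the residual noise floor
  expect_true(all(pr$upper - pr$fit >= qnorm(0.975) * sqrt(fit$sigma2) - 1e-10))
  # intercept-only closed form: 1.96 * sqrt(sigma2 * (1 + 1/n))
  fit0 <- fit_gam(d, y, terms = character())
  pr0 <- predict_gam(fit0, d[1:3, , drop = FALSE])
  expect_equal(pr0$fit, rep(mean(y), 3), tolerance = 1e-8)
  expect_equal(pr0$upper - pr0$fit,
               rep(qnorm(0.975) * sqrt(fit0$sigma2 * (1 + 1 / n)), 3),
               tolerance = 1e-8)
  # rows missing a required column are refused
  d_na <- d[1:2, , drop = FALSE]
  d_na$temperature[2] <- NA
  pr_na <- predict_gam(fit, d_na)
  expect_false(is.na(pr_na$fit[1]))
  expect_true(is.na(pr_na$fit[2]))
})

test_that("the fast row predictor agrees with predict_gam", {
  g <- make_grid(800)
  covs <- make_covariates(g)
  y <- make_response(g, covs)
  d <- build_design(y, covs)
  fit <- stepwise_gam(d, y)
  rowpred <- streamfill:::make_row_predictor(fit, d)
  skip_if(is.null(rowpred))
  dd <- as.data.frame(d)
  set.seed(21)
  for (t in sample(3:800, 25)) {
    ref <- predict_gam(fit, dd[t, , drop = FALSE])
    got <- rowpred(t, dd$lag1[t], dd$lag2[t])
    expect_equal(got[1], ref$fit, tolerance = 1e-8)
    expect_equal(got[2], ref$lower, tolerance = 1e-8)
    expect_equal(got[3], ref$upper, tolerance = 1e-8)
    # and with perturbed lag values
    got2 <- rowpred(t, dd$lag1[t] + 1, dd$lag2[t] - 1)
    nd <- dd[t, , drop = FALSE]
    nd$lag1 <- nd$lag1 + 1; nd$lag2 <- nd$lag2 - 1
    ref2 <- predict_gam(fit, nd)
    expect_equal(got2[1], ref2$fit, tolerance = 1e-8)
    expect_equal(got2[3], ref2$upper, tolerance = 1e-8)
  }
})
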