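test_that("differencing follows first-difference arithmetic", {
  x <- c(1, 3, 6, 10)
  expect_equal(difference(x, 0), x)
  expect_equal(difference(x, 1), c(2, 3, 4))
  expect_equal(difference(difference(x, 1), 1), difference(x, 2))
  expect_error(difference(x, 4), "length")

  grid <- seq(as.Date("2006-01-01"), by = 7, length.out = 4)
  ws <- weekly_series(grid, x)
  d1 <- difference(ws, 1)
  expect_equal(d1$value, c(2, 3, 4))
  expect_equal(d1$week_start, grid[-1])
})

test_that("CSS minimiser matches a brute-force grid search to 3 decimals", {
  set.seed(7)
  w_ar <- sim_ar1(20, 0.5)
  grid <- seq(-0.998, 0.998, by = 0.001)
  oracle_ar <- grid[which.min(vapply(grid, css_brute_ar1, numeric(1),
                                     w = w_ar))]
  fit_ar <- css_fit(w_ar, arima_spec(1, 0, 0, include_mean = FALSE))
  expect_lt(abs(fit_ar$phi - oracle_ar), 1e-3)

  w_ma <- diff(sim_ima11(21, 0.4))
  oracle_ma <- grid[which.min(vapply(grid, css_brute_ma1, numeric(1),
                                     w = w_ma))]
  fit_ma <- css_fit(w_ma, arima_spec(0, 0, 1, include_mean = FALSE))
  expect_lt(abs(fit_ma$theta - oracle_ma), 1e-3)
})

test_that("CSS estimates agree with the reference CSS implementation", {
  set.seed(31)
  for (r in 1:50) {
    y <- sim_ar1(400, runif(1, -0.7, 0.7)) + 5
    mine <- css_fit(y, arima_spec(1, 0, 0))
    ref <- stats::arima(y, order = c(1, 0, 0), method = "CSS")
    expect_lt(abs(mine$phi - unname(coef(ref)["ar1"])), 0.01)

    x <- sim_ima11(400, runif(1, -0.7, 0.7))
    mine2 <- css_fit(x, arima_spec(0, 1, 1))
    ref2 <- stats::arima(x, order = c(0, 1, 1), method = "CSS")
    # reference uses the (1 + theta B) sign convention
    expect_lt(abs(mine2$theta - (-unname(coef(ref2)["ma1"]))), 0.01)
  }
})

test_that("standard errors and T-ratios are internally consistent", {
  set.seed(5)
  y <- sim_ar1(500, 0.4) + 10
  fit <- css_fit(y, arima_spec(1, 0, 0))
  expect_equal(unname(fit$t_ratios["ar1"]), unname(fit$phi / fit$se["ar1"]))
  # asymptotic SE for an AR(1) is sqrt((1 - phi^2)/n)
  expect_equal(unname(fit$se["ar1"]),
               sqrt((1 - fit$phi^2) / fit$n_used), tolerance = 0.25)
  expect_equal(fit$sigma2, fit$css / fit$n_used)
  expect_equal(fit$n_used, 499)
})

test_that("estimator bias shrinks as the series grows", {
  set.seed(88)
  sizes <- c(200, 1000, 5000)
  bias_phi <- bias_theta <- numeric(length(sizes))
  for (i in seq_along(sizes)) {
    n <- sizes[i]
    err_p <- err_t <- numeric(200)
    for (r in 1:200) {
      err_p[r] <- css_fit(sim_ar1(n, 0.33),
                          arima_spec(1, 0, 0, FALSE))$phi - 0.33
      err_t[r] <- css_fit(sim_ima11(n + 1, 0.4),
                          arima_spec(0, 1, 1))$theta - 0.4
    }
    bias_phi[i] <- abs(mean(err_p))
    bias_theta[i] <- abs(mean(err_t))
  }
  mono <- c(diff(bias_phi) < 0, diff(bias_theta) < 0)
  expect_gte(mean(mono), 2 / 3)
  expect_lt(bias_phi[3], bias_phi[1])
  expect_lt(bias_theta[3], bias_theta[1])
})

test_that("sample ACF and PACF behave like their textbook definitions", {
  set.seed(2)
  wn <- rnorm(2000)
  a <- sample_acf(wn, 40)
  expect_equal(a[1], 1)                       # lag 0
  expect_lt(mean(abs(a[-1]) > 2 / sqrt(2000)), 0.12)  # ~5% exceed the band

  ar <- sim_ar1(20000, 0.5)
  expect_equal(sample_acf(ar, 5)[-1], 0.5^(1:5), tolerance = 0.05)

  # PACF via Durbin-Levinson against the reference implementation
  x <- sim_ar1(500, 0.6)
  expect_equal(sample_pacf(x, 10),
               as.numeric(stats::pacf(x, lag.max = 10, plot = FALSE)$acf),
               tolerance = 1e-8)
  expect_error(sample_acf(rep(3, 50), 5), "constant")
})

test_that("one-step forecasts reduce to their closed forms", {
  y <- c(10, 11, 9, 12, 13)
  rw <- structure(list(spec = arima_spec(0, 1, 1), phi = numeric(0),
                       theta = 0, mu = 0, sigma2 = 4), class = "arima_fit")
  expect_equal(one_step_forecast(rw, y)$point, 13)  # random walk limit
  expect_equal(one_step_forecast(rw, y)$se, 2)

  ar <- structure(list(spec = arima_spec(1, 0, 0), phi = 0.6,
                       theta = numeric(0), mu = 10, sigma2 = 1),
                  class = "arima_fit")
  expect_equal(one_step_forecast(ar, y)$point, 10 + 0.6 * (13 - 10))
})

test_that("IMA(1,1) forecast equals the hand-rolled recursion", {
  y <- c(5, 6, 5.5, 7, 6.5, 8)
  theta <- 0.4
  fit <- structure(list(spec = arima_spec(0, 1, 1), phi = numeric(0),
                        theta = theta, mu = 0, sigma2 = 1),
                   class = "arima_fit")
  # by hand: w_t = diff(y), eps_t = w_t + theta * eps_{t-1}, eps_0 = 0,
  # forecast = y_n - theta * eps_n
  w <- diff(y)
  eps <- 0
  for (t in seq_along(w)) eps <- w[t] + theta * eps
  expect_equal(one_step_forecast(fit, y)$point, y[6] - theta * eps)
})

test_that("residuals of a correctly specified fit are white", {
  set.seed(17)
  x <- sim_ima11(3000, 0.4)
  fit <- css_fit(x, arima_spec(0, 1, 1))
  r <- sample_acf(residuals(fit), 19)[-1]
  expect_gte(mean(abs(r) < 2 / sqrt(fit$n_used)), 0.9)
})

test_that("one-step 95% intervals at true parameters cover ~95%", {
  set.seed(23)
  theta <- 0.4
  y <- sim_ima11(2200, theta)
  fit <- structure(list(spec = arima_spec(0, 1, 1), phi = numeric(0),
                        theta = theta, mu = 0, sigma2 = 1),
                   class = "arima_fit")
  z <- qnorm(0.975)
  covered <- vapply(200:2199, function(t) {
    fc <- one_step_forecast(fit, y[1:t])
    abs(y[t + 1] - fc$point) <= z * fc$se
  }, logical(1))
  expect_gte(mean(covered), 0.93)
  expect_lte(mean(covered), 0.97)
})

test_that("degenerate constant input is flagged, not silently fitted", {
  y <- rep(4, 50)
  expect_warning(fit <- css_fit(y, arima_spec(0, 1, 1)), "constant")
  expect_equal(fit$theta, 0)
  expect_equal(fit$sigma2, 0)
})
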