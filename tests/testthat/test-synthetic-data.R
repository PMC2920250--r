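test_that("generator configuration validates its invariants", {
  expect_error(generator_config(start_date = "2003-06-30"), "Sunday")
  expect_error(generator_config(n_weeks = 5), "at least 10")
  expect_error(generator_config(sales_theta = 1.2), "sales_theta")
  expect_error(generator_config(case_phi = -1), "case_phi")
  expect_error(generator_config(sales_level = 1.5), "sales_level")
  expect_error(generator_config(outbreak_rate = -1), "outbreak_rate")
})

test_that("identical seeds give byte-identical output, any call order", {
  cfg <- quick_config()
  a <- simulate_study(cfg, daily = TRUE)
  # different generation order must not change any sub-stream
  set.seed(999)
  invisible(generate_outbreaks(cfg))
  b <- simulate_study(cfg, daily = TRUE)
  expect_identical(a$sales$daily, b$sales$daily)
  expect_identical(a$cases$records, b$cases$records)
  expect_identical(a$outbreaks, b$outbreaks)
  expect_identical(a$truth, b$truth)
})

test_that("zero-noise sales collapse to the configured level", {
  cfg <- quick_config(sales_sigma = 0, effect_per_case = 0)
  s <- generate_sales(cfg, daily = FALSE)
  expect_equal(s$latent$value, rep(cfg$sales_level, cfg$n_weeks))
  # achieved proportions only differ by integer rounding of unit counts
  expect_lt(max(abs(s$weekly$value - cfg$sales_level)), 1e-4)
})

test_that("zero-noise cases collapse to the configured mean", {
  cfg <- quick_config(case_sigma = 0)
  cc <- generate_cases(cfg)
  expect_equal(cc$weekly$value, rep(cfg$case_mean, cfg$n_weeks))
})

test_that("phi = 0 cases are white noise", {
  cfg <- generator_config(n_weeks = 2000, case_phi = 0, seed = 7)
  cc <- generate_cases(cfg, records = FALSE)
  expect_lt(abs(sample_acf(cc$weekly, 1)[2]), 2 / sqrt(2000))
})

test_that("downstream fits recover the generating parameters", {
  # AR(1) case model
  cfg <- generator_config(n_weeks = 2000, seed = 11)
  fit_c <- css_fit(generate_cases(cfg, records = FALSE)$weekly, arima_spec(1, 0, 0))
  expect_lt(abs(fit_c$phi - cfg$case_phi), 3 * fit_c$se[["ar1"]])
  # IMA(1,1) sales model (central level leaves headroom for a long walk)
  cfg2 <- generator_config(n_weeks = 2000, sales_level = 0.5, seed = 12)
  fit_s <- css_fit(generate_sales(cfg2, daily = FALSE)$weekly,
                   arima_spec(0, 1, 1))
  expect_lt(abs(fit_s$theta - cfg2$sales_theta), 3 * fit_s$se[["ma1"]])
})

test_that("closed loop at study scale: theta recovered within sampling error", {
  cfg <- generator_config(n_weeks = 234, seed = 3)
  s <- generate_sales(cfg, daily = FALSE)
  fit <- css_fit(s$weekly, arima_spec(0, 1, 1))
  expect_lt(abs(fit$theta - cfg$sales_theta), 3 * fit$se[["ma1"]])
})

test_that("parameter recovery is within 3 SE in at least 95% of replicates", {
  set.seed(202)
  n_rep <- 200
  ok_phi <- ok_theta <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- generator_config(n_weeks = 2000, sales_level = 0.5,
                            seed = 5000 + r)
    fc <- css_fit(generate_cases(cfg, records = FALSE)$weekly, arima_spec(1, 0, 0))
    ok_phi[r] <- abs(fc$phi - cfg$case_phi) < 3 * fc$se[["ar1"]]
    fs <- css_fit(generate_sales(cfg, daily = FALSE)$weekly,
                  arima_spec(0, 1, 1))
    ok_theta[r] <- abs(fs$theta - cfg$sales_theta) < 3 * fs$se[["ma1"]]
  }
  expect_gte(mean(ok_phi), 0.95)
  expect_gte(mean(ok_theta), 0.95)
})

test_that("outbreak process matches its Poisson intensity", {
  expect_equal(nrow(generate_outbreaks(quick_config(outbreak_rate = 0))), 0)

  cfg <- generator_config(n_weeks = 234, outbreak_rate = 0.7, seed = 9)
  n_ob <- nrow(generate_outbreaks(cfg))
  mu <- 0.7 * 234
  expect_gt(n_ob, mu - 3 * sqrt(mu))
  expect_lt(n_ob, mu + 3 * sqrt(mu))

  fixed <- generate_outbreaks(quick_config(
    outbreak_size_dist = list(dist = "fixed", value = 153)))
  expect_true(all(fixed$cases == 153))
})

test_that("outbreak records are well-formed", {
  ob <- generate_outbreaks(generator_config(seed = 21))
  expect_true(all(ob$cases >= 1))
  has_last <- !is.na(ob$last_onset)
  expect_true(all(ob$last_onset[has_last] >= ob$first_onset[has_last]))
  expect_gt(mean(is.na(ob$last_onset)), 0.5)  # most last onsets blank
})

test_that("inject_effect is the identity at zero effect and exact otherwise", {
  cfg <- quick_config()
  clean <- generate_sales(cfg, daily = FALSE)
  ob1 <- data.frame(first_onset = clean$units$week_start[10] + 3,
                    last_onset = as.Date(NA), cases = 100L,
                    etiology = "norovirus", institutional = 0L)

  same <- inject_effect(clean, ob1, effect_per_case = 0)
  expect_equal(same$weekly$value, clean$weekly$value)

  bumped <- inject_effect(clean, ob1, effect_per_case = 5)
  du <- bumped$units$diarrhea_units - clean$units$diarrhea_units
  expect_equal(du[10], 500)
  expect_equal(sum(du != 0), 1)          # exactly one week changed
  expect_equal(bumped$units$injected_units[10], 500)
})

test_that("injected and clean series differ only on active weeks plus lag", {
  cfg <- quick_config(outbreak_rate = 0.15)
  clean <- generate_sales(cfg, daily = FALSE)
  ob <- generate_outbreaks(cfg)
  lag <- 2L
  bumped <- inject_effect(clean, ob, effect_per_case = 5,
                          effect_lag_weeks = lag)
  changed <- which(bumped$weekly$value != clean$weekly$value)
  grid <- clean$units$week_start
  active <- which(otcsurv:::outbreak_active_cases(ob, grid) > 0)
  expected <- intersect(active + lag, seq_along(grid))
  expect_true(all(changed %in% expected))
})

test_that("a lag pushing the effect off the grid warns and truncates", {
  cfg <- quick_config()
  clean <- generate_sales(cfg, daily = FALSE)
  last_wk <- clean$units$week_start[cfg$n_weeks]
  ob <- data.frame(first_onset = last_wk + 1, last_onset = as.Date(NA),
                   cases = 50L, etiology = "x", institutional = 0L)
  expect_warning(out <- inject_effect(clean, ob, 5, effect_lag_weeks = 4L),
                 "truncated")
  expect_equal(out$weekly$value, clean$weekly$value)
})

test_that("study CSV artefacts round-trip through the aggregators", {
  dir <- withr::local_tempdir()
  cfg <- quick_config()
  st <- simulate_study(cfg, out_dir = dir, daily = TRUE)
  expect_true(all(file.exists(file.path(dir, c(
    "sales_daily.csv", "cases.csv", "outbreaks.csv", "truth.csv")))))
  daily <- read.csv(file.path(dir, "sales_daily.csv"))
  daily$date <- as.Date(daily$date)
  expect_equal(aggregate_sales(daily)$value, st$sales$weekly$value,
               tolerance = 1e-12)
  cases <- read.csv(file.path(dir, "cases.csv"))
  cases$report_date <- as.Date(cases$report_date)
  agg <- aggregate_cases(cases, date_floor = cfg$start_date,
                         grid = st$truth$week_start)
  expect_equal(agg$value, st$truth$case_count)
})
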