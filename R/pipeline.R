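#' Run the full sales-surveillance analysis
#'
#' Convenience wrapper chaining the whole evaluation: aggregate (or accept
#' pre-aggregated) weekly sales and case series, fit the univariate ARIMA
#' models on the model-building period, compute the pre-whitened
#' cross-correlation between sales and cases, regress model-period sales
#' residuals on weekly outbreak covariates, roll one-week-ahead forecasts
#' with weekly refits across the forecasting period, turn upper-limit
#' exceedances into signals, and score them against outbreak weeks and a
#' random-signal baseline.
#'
#' @param sales daily sales records (data frame) or a sales-proportion
#'   [weekly_series()].
#' @param cases case records (data frame) or a case-count
#'   [weekly_series()].
#' @param outbreaks outbreak records data frame.
#' @param split a [period_split()]; default is the package's reference
#'   study layout.
#' @param sales_spec,case_spec model orders; defaults IMA(1,1) and AR(1).
#' @param ccf_mode pre-whitening mode for the cross-correlation.
#' @param min_cases vector of inclusive outbreak-size strata to evaluate.
#' @param n_random random signal sets per stratum.
#' @param date_floor earliest case-report date used.
#' @param level forecast interval confidence level.
#' @param seed seed for the random baseline draws.
#' @return list with components `weekly` (the input series), `fits`,
#'   `ccf`, `regression` (outbreak counts and outbreak-case covariates),
#'   `forecasts`, `signals`, and `evaluation` (per stratum: the model
#'   `eval_result` plus the random-baseline results).
#' @export
run_surveillance <- function(sales, cases, outbreaks,
                             split = default_period_split(),
                             sales_spec = arima_spec(0, 1, 1),
                             case_spec = arima_spec(1, 0, 0),
                             ccf_mode = "double_prewhiten",
                             min_cases = c(1L, 50L, 100L),
                             n_random = 3L,
                             date_floor = as.Date("2004-01-04"),
                             level = 0.95,
                             seed = NULL) {
  sales_weekly <- if (inherits(sales, "weekly_series")) sales else
    aggregate_sales(sales)
  cases_weekly <- if (inherits(cases, "weekly_series")) cases else
    aggregate_cases(cases, date_floor = date_floor)

  parts <- split_periods(sales_weekly, split)
  model_end <- split$model[2L]

  sales_fit <- css_fit(window_weeks(sales_weekly, to = model_end),
                       sales_spec)
  case_model <- window_weeks(cases_weekly, to = min(model_end,
                                                    max(cases_weekly$week_start)))
  case_fit <- css_fit(case_model, case_spec)

  pw <- prewhiten_pair(sales_weekly, cases_weekly, mode = ccf_mode,
                       x_spec = sales_spec, y_spec = case_spec)
  ccf_res <- cross_correlation(pw$x, pw$y, max_lag = 19L)

  ob_weekly <- aggregate_outbreaks(outbreaks, min_cases = 1L,
                                   grid = sales_weekly$week_start)
  model_resid <- window_weeks(sales_fit$residuals, to = model_end)
  regression <- list(
    outbreak_count = residual_regression(model_resid, ob_weekly$outbreaks),
    outbreak_cases = residual_regression(model_resid, ob_weekly$cases))

  fc_grid <- week_seq(split$forecasting[1L], split$forecasting[2L])
  forecasts <- rolling_forecast(sales_weekly, sales_spec, fc_grid,
                                level = level)
  signals <- generate_signals(forecasts)

  if (!is.null(seed)) set.seed(seed)
  evaluation <- lapply(min_cases, function(mc) {
    ow <- outbreak_weeks(outbreaks, fc_grid, min_cases = mc)
    model_eval <- sensitivity_specificity(signals$signal_weeks, ow,
                                          fc_grid, min_cases = mc)
    rand <- random_signal_baseline(fc_grid,
                                   k = max(1L, length(signals$signal_weeks)),
                                   outbreak_week_set = ow,
                                   n_sets = n_random, min_cases = mc)
    list(model = model_eval, random = rand)
  })
  names(evaluation) <- paste0("min_cases_", min_cases)

  list(weekly = list(sales = sales_weekly, cases = cases_weekly),
       fits = list(sales = sales_fit, cases = case_fit),
       ccf = ccf_res,
       regression = regression,
       forecasts = forecasts,
       signals = signals,
       evaluation = evaluation)
}
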