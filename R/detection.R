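#' Rolling one-week-ahead forecasts with weekly model updating
#'
#' For each week in the forecast range, the ARIMA model (orders fixed) is
#' re-estimated by conditional least squares on all data strictly before
#' that week, a one-step forecast is issued, and a forecast interval
#' `point +/- z * sqrt(sigma2)` is recorded.  The default `z` is the
#' two-sided 95% normal quantile (1.959964); a one-sided variant is
#' available.  Forecasts are strictly causal: the forecast for week `w`
#' never sees data from week `w` onward.
#'
#' @param series full [weekly_series()] of observations (model-building
#'   history plus the forecast range).
#' @param spec an [arima_spec()]; orders are held fixed across refits.
#' @param forecast_range `Date` vector of Sundays to forecast, or a
#'   length-2 `c(from, to)` range; must lie inside the series and leave
#'   enough history before the first forecast week.
#' @param level confidence level of the forecast interval (default 0.95).
#' @param tail `"two_sided"` (default, z = 1.96 at 95%) or `"one_sided"`
#'   (z = 1.645 at 95%) interval construction.
#' @param refit re-estimate parameters every week (default) or fit once on
#'   the history before the first forecast week and keep the parameters.
#' @param sigma2_tol innovation variances below this are flagged as
#'   degenerate rather than silently producing a zero-width interval.
#' @return object of class `forecast_points`: data frame with columns
#'   `week`, `observed`, `point`, `lower`, `upper`, `sigma2`, `degenerate`,
#'   `refit_ok`, plus a `params` attribute (matrix of the per-week
#'   coefficient snapshots) and `level`/`tail` attributes.
#' @export
rolling_forecast <- function(series, spec, forecast_range,
                             level = 0.95,
                             tail = c("two_sided", "one_sided"),
                             refit = TRUE, sigma2_tol = 1e-18) {
  tail <- match.arg(tail)
  stopifnot(inherits(series, "weekly_series"), inherits(spec, "arima_spec"))
  forecast_range <- as.Date(forecast_range)
  if (length(forecast_range) == 2L)
    forecast_range <- week_seq(forecast_range[1L], forecast_range[2L])
  if (!all(forecast_range %in% series$week_start))
    stop("forecast_range must lie inside the series")
  z <- if (tail == "two_sided") stats::qnorm((1 + level) / 2) else
    stats::qnorm(level)

  m <- length(forecast_range)
  out <- data.frame(week = forecast_range,
                    observed = NA_real_, point = NA_real_,
                    lower = NA_real_, upper = NA_real_,
                    sigma2 = NA_real_, degenerate = FALSE,
                    refit_ok = TRUE)
  params <- NULL
  fit <- NULL
  for (i in seq_len(m)) {
    w <- forecast_range[i]
    hist <- window_weeks(series, to = w - 7L)
    if (refit || is.null(fit)) {
      new_fit <- try(css_fit(hist, spec), silent = TRUE)
      if (inherits(new_fit, "try-error")) {
        if (is.null(fit)) stop("initial model fit failed: ", new_fit)
        warning("refit failed for week ", format(w),
                "; carrying previous parameters")
        out$refit_ok[i] <- FALSE
      } else fit <- new_fit
    }
    fc <- one_step_forecast(fit, hist)
    obs <- series$value[series$week_start == w]
    coefs <- c(fit$phi, fit$theta,
               if (fit$spec$include_mean) fit$mu)
    if (is.null(params))
      params <- matrix(NA_real_, m, length(coefs),
                       dimnames = list(NULL, names(fit$se)))
    if (length(coefs)) params[i, ] <- coefs
    out$observed[i] <- obs
    out$point[i] <- fc$point
    out$sigma2[i] <- fit$sigma2
    if (fit$sigma2 < sigma2_tol) out$degenerate[i] <- TRUE
    out$lower[i] <- fc$point - z * fc$se
    out$upper[i] <- fc$point + z * fc$se
  }
  if (any(out$degenerate))
    warning("degenerate (near-zero) innovation variance in ",
            sum(out$degenerate), " week(s); intervals unreliable there")
  structure(out, params = params, level = level, tail = tail,
            class = c("forecast_points", "data.frame"))
}

#' Surveillance signals from forecast exceedances
#'
#' A week is a signal when its observed value strictly exceeds the upper
#' forecast limit; an observation exactly on the limit is not a signal.
#'
#' @param points a `forecast_points` object from [rolling_forecast()].
#' @return object of class `signal_set`: list with `signal_weeks`
#'   (Sunday `Date`s), `points`, and `level`.
#' @export
generate_signals <- function(points) {
  stopifnot(inherits(points, "forecast_points"))
  sig <- points$week[points$observed > points$upper]
  structure(list(signal_weeks = sig, points = points,
                 level = attr(points, "level")),
            class = "signal_set")
}

#' @export
print.signal_set <- function(x, ...) {
  cat(sprintf("%d signal week(s) out of %d forecast weeks (level %.2f)\n",
              length(x$signal_weeks), nrow(x$points), x$level))
  if (length(x$signal_weeks))
    cat(paste(format(x$signal_weeks), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.forecast_points <- function(x, ...) {
  graphics::plot(x$week, x$observed, type = "l",
                 xlab = "week", ylab = "value",
                 ylim = range(c(x$observed, x$lower, x$upper)), ...)
  graphics::lines(x$week, x$point, lty = 2)
  graphics::lines(x$week, x$upper, col = "grey50")
  graphics::lines(x$week, x$lower, col = "grey50")
  sig <- x$observed > x$upper
  if (any(sig)) graphics::points(x$week[sig], x$observed[sig], pch = 19)
  invisible(x)
}
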