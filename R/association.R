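#' Pre-whiten a pair of weekly series
#'
#' Autocorrelated series cross-correlate spuriously, so both series are
#' filtered through fitted ARIMA models before the cross-correlation
#' function is computed.  Two schemes are offered:
#'
#' * `"prewhiten"`: fit `x`'s univariate model and pass *both* series
#'   through `x`'s differencing and inverse ARMA filter (the classical
#'   pre-whitening of the input series);
#' * `"double_prewhiten"`: filter each series through its *own* fitted
#'   model, so both outputs are that model's residuals.
#'
#' @param x_series,y_series [weekly_series()] objects; they are aligned on
#'   their common weeks first.
#' @param mode `"double_prewhiten"` (default) or `"prewhiten"`.
#' @param x_spec,y_spec [arima_spec()]s for the two univariate models;
#'   defaults are the package's reference forms, IMA(1,1) for `x` (a sales
#'   proportion) and AR(1) with mean for `y` (a case count).
#' @return list with `x` and `y` (residual-scale [weekly_series()] on a
#'   common week grid), `mode`, and `fits` (the underlying `arima_fit`s).
#' @export
prewhiten_pair <- function(x_series, y_series,
                           mode = c("double_prewhiten", "prewhiten"),
                           x_spec = arima_spec(0, 1, 1),
                           y_spec = arima_spec(1, 0, 0)) {
  mode <- match.arg(mode)
  al <- align_weeks(x_series, y_series)
  fit_x <- css_fit(al$a, x_spec)
  if (mode == "prewhiten") {
    fits <- list(x = fit_x)
    xw <- fit_x$residuals
    yw <- arma_inverse_filter(al$b, fit_x)
  } else {
    fit_y <- css_fit(al$b, y_spec)
    fits <- list(x = fit_x, y = fit_y)
    xw <- fit_x$residuals
    yw <- fit_y$residuals
  }
  al2 <- align_weeks(xw, yw)
  list(x = al2$a, y = al2$b, mode = mode, fits = fits)
}

# Pass an arbitrary series through a fitted model's differencing and
# inverse ARMA filter; the filtered series is centred on its own mean
# after differencing (the fitted mu belongs to the model's own series).
arma_inverse_filter <- function(series, fit) {
  d <- fit$spec$d
  w <- difference(series, d)
  eps <- css_innovations(w$value, fit$phi, fit$theta, mu = mean(w$value))
  weekly_series(w$week_start[(nrow(w) - length(eps) + 1L):nrow(w)], eps,
                label = paste0(ws_label(series), "_filtered"))
}

#' Lagged cross-correlation with significance band
#'
#' Sample cross-correlations
#' \deqn{r(k) = \frac{\sum_t (a_t - \bar a)(b_{t+k} - \bar b)}{n\, s_a s_b}}
#' at lags `-max_lag..max_lag`, using full-sample means and standard
#' deviations (denominator `n`).  Positive lags mean `b` trails `a`.  The
#' constant significance band is `2 / sqrt(n)`; lags whose `|r|` exceed it
#' are flagged.
#'
#' @param a,b equal-length numeric vectors or [weekly_series()] (aligned
#'   on common weeks first).
#' @param max_lag largest lag in weeks (default 19).
#' @return object of class `ccf_result`: data frame of `lag`,
#'   `correlation`, `flagged`, with attributes `band`, `n`, `mode`.
#' @export
cross_correlation <- function(a, b, max_lag = 19L) {
  if (inherits(a, "weekly_series") && inherits(b, "weekly_series")) {
    al <- align_weeks(a, b)
    a <- al$a; b <- al$b
  }
  av <- ws_values(a); bv <- ws_values(b)
  n <- length(av)
  if (length(bv) != n) stop("series must have equal length")
  if (max_lag >= n) stop("max_lag must be below the series length")
  am <- mean(av); bm <- mean(bv)
  sa <- sqrt(sum((av - am)^2) / n)
  sb <- sqrt(sum((bv - bm)^2) / n)
  if (sa == 0 || sb == 0) stop("constant series has no cross-correlation")
  lags <- (-max_lag):max_lag
  r <- vapply(lags, function(k) {
    if (k >= 0) {
      t <- seq_len(n - k)
      sum((av[t] - am) * (bv[t + k] - bm))
    } else {
      t <- seq_len(n + k)
      sum((av[t - k] - am) * (bv[t] - bm))
    }
  }, numeric(1)) / (n * sa * sb)
  band <- 2 / sqrt(n)
  structure(data.frame(lag = lags, correlation = r,
                       flagged = abs(r) > band),
            band = band, n = n,
            class = c("ccf_result", "data.frame"))
}

#' @export
print.ccf_result <- function(x, ...) {
  cat(sprintf("Cross-correlations, lags %d..%d, n = %d, band = +/-%.4f\n",
              min(x$lag), max(x$lag), attr(x, "n"), attr(x, "band")))
  fl <- x[x$flagged, , drop = FALSE]
  if (nrow(fl)) {
    cat("flagged lags:\n")
    print.data.frame(fl, row.names = FALSE)
  } else cat("no lag exceeds the band\n")
  invisible(x)
}

#' @export
plot.ccf_result <- function(x, ...) {
  band <- attr(x, "band")
  graphics::plot(x$lag, x$correlation, type = "h",
                 xlab = "lag (weeks)", ylab = "cross-correlation",
                 ylim = range(c(x$correlation, band, -band)), ...)
  graphics::abline(h = c(-band, 0, band), lty = c(2, 1, 2))
  invisible(x)
}

#' Regress model residuals on an outbreak covariate
#'
#' Simple ordinary-least-squares regression of sales-model residuals on a
#' weekly outbreak covariate (outbreak counts or outbreak-associated
#' cases), with closed-form slope, intercept and slope standard error, and
#' a two-sided t test on the slope with `n - 2` degrees of freedom.
#'
#' @param residuals,covariate numeric vectors or [weekly_series()]
#'   (aligned on common weeks first); at least 3 common weeks.
#' @return object of class `residual_regression`: list with `slope`,
#'   `intercept`, `slope_se`, `t_stat`, `p_value`, `n`.
#' @export
residual_regression <- function(residuals, covariate) {
  if (inherits(residuals, "weekly_series") &&
      inherits(covariate, "weekly_series")) {
    al <- align_weeks(residuals, covariate)
    residuals <- al$a; covariate <- al$b
  }
  y <- ws_values(residuals); x <- ws_values(covariate)
  n <- length(y)
  if (length(x) != n) stop("series must have equal length")
  if (n < 3L) stop("need at least 3 observations")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("covariate has zero variance")
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  rss <- sum((y - intercept - slope * x)^2)
  s2 <- rss / (n - 2L)
  slope_se <- sqrt(s2 / sxx)
  if (slope_se > 0) {
    t_stat <- slope / slope_se
    p_value <- max(2 * stats::pt(-abs(t_stat), df = n - 2L),
                   .Machine$double.xmin)  # keep p in (0, 1]
  } else if (slope == 0) {       # degenerate: no residual variation at all
    t_stat <- 0
    p_value <- 1
  } else {                       # exact fit: evidence is overwhelming
    t_stat <- sign(slope) * Inf
    p_value <- .Machine$double.xmin
  }
  structure(list(slope = slope, intercept = intercept,
                 slope_se = slope_se, t_stat = t_stat,
                 p_value = p_value, n = n),
            class = "residual_regression")
}

#' @export
print.residual_regression <- function(x, ...) {
  cat(sprintf(
    "slope %.5g (se %.5g), intercept %.5g, t = %.3f, p = %.4g, n = %d\n",
    x$slope, x$slope_se, x$intercept, x$t_stat, x$p_value, x$n))
  invisible(x)
}
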