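#' ARIMA model order specification
#'
#' @param p autoregressive order (>= 0).
#' @param d order of first differencing (>= 0).
#' @param q moving-average order (>= 0).
#' @param include_mean should a mean term be estimated?  Defaults to `TRUE`
#'   for undifferenced models and `FALSE` once the series is differenced
#'   (no drift constant), which is the classical Box-Jenkins default.
#' @return object of class `arima_spec`.
#' @examples
#' arima_spec(0, 1, 1)  # integrated first-order moving average, IMA(1,1)
#' arima_spec(1, 0, 0)  # AR(1) with mean
#' @export
arima_spec <- function(p, d, q, include_mean = NULL) {
  p <- as.integer(p); d <- as.integer(d); q <- as.integer(q)
  if (any(c(p, d, q) < 0L)) stop("orders must be non-negative")
  if (p + q < 1L && d < 1L) stop("model must have at least one of p, d, q positive")
  if (is.null(include_mean)) include_mean <- d == 0L
  structure(list(p = p, d = d, q = q, include_mean = isTRUE(include_mean)),
            class = "arima_spec")
}

#' @export
print.arima_spec <- function(x, ...) {
  cat(sprintf("ARIMA(%d,%d,%d)%s\n", x$p, x$d, x$q,
              if (x$include_mean) " with mean" else ""))
  invisible(x)
}

#' Difference a series
#'
#' Applies `d`-fold first differencing (the "I" step of ARIMA modelling).
#' Weekly series keep their week labels, dropping the first `d` weeks.
#'
#' @param x numeric vector or [weekly_series()].
#' @param d number of differences (>= 0).
#' @return same type as `x`, shortened by `d`.
#' @export
difference <- function(x, d = 1L) {
  d <- as.integer(d)
  if (d < 0L) stop("d must be non-negative")
  v <- ws_values(x)
  if (d >= length(v)) stop("d must be smaller than the series length")
  out <- if (d == 0L) v else diff(v, differences = d)
  if (inherits(x, "weekly_series")) {
    weekly_series(x$week_start[(d + 1L):nrow(x)], out,
                  label = paste0("diff", d, "_", ws_label(x)))
  } else out
}

# Conditional innovations of an ARMA(p,q) model on the (already differenced)
# series w.  Sign convention: (1 - phi_1 B - ...)(w_t - mu) = (1 - theta_1 B
# - ...) eps_t, so eps_t = (w_t - mu) - sum phi_i (w_{t-i} - mu)
#                          + sum theta_j eps_{t-j},
# with pre-sample innovations fixed at zero and t running from p+1.
css_innovations <- function(w, phi, theta, mu = 0) {
  p <- length(phi); q <- length(theta)
  wc <- w - mu
  n <- length(wc)
  if (n <= p) stop("series too short for the AR order")
  z <- wc[(p + 1L):n]
  if (p > 0L)
    for (i in seq_len(p)) z <- z - phi[i] * wc[(p + 1L - i):(n - i)]
  if (q > 0L) z <- as.numeric(stats::filter(z, theta, method = "recursive"))
  z
}

# Pack/unpack the free-parameter vector: AR coefs, MA coefs, then mean.
css_objective <- function(par, w, p, q, include_mean) {
  phi <- if (p > 0L) par[seq_len(p)] else numeric(0)
  theta <- if (q > 0L) par[p + seq_len(q)] else numeric(0)
  coefs <- c(phi, theta)
  if (length(coefs) && max(abs(coefs)) >= 0.999)
    return(1e12 * (1 + max(abs(coefs))))
  mu <- if (include_mean) par[p + q + 1L] else 0
  sum(css_innovations(w, phi, theta, mu)^2)
}

#' Fit an ARIMA model by conditional least squares
#'
#' Box-Jenkins estimation from first principles: the series is differenced
#' `d` times, and the ARMA coefficients (plus a mean for undifferenced
#' models) are chosen to minimise the conditional sum of squares (CSS)
#' \deqn{S = \sum_{t=p+1}^{n} \varepsilon_t^2,}
#' where the innovations are computed recursively with pre-sample
#' innovations set to zero.  The moving-average polynomial uses the
#' \eqn{(1 - \theta B)} sign convention, so an IMA(1,1) with positive
#' smoothing has a positive `theta`.
#'
#' Optimisation is derivative-free: a coarse grid plus golden-section
#' refinement for a single coefficient, and multi-start Nelder-Mead (starts
#' at -0.5, 0, +0.5 per coefficient) inside the invertibility/stationarity
#' box otherwise.  Standard errors come from the numerically differenced
#' Hessian of the CSS surface at the optimum,
#' \eqn{\widehat{Cov} = 2\hat\sigma^2 H^{-1}}.
#'
#' @param series numeric vector or [weekly_series()].
#' @param spec an [arima_spec()].
#' @param tol convergence tolerance on the objective.
#' @return object of class `arima_fit` with elements `spec`, `phi`,
#'   `theta`, `mu`, `sigma2` (innovation variance, CSS / n_used), `se`,
#'   `t_ratios`, `residuals` (a `weekly_series` when the input was one),
#'   `n_used`, `css`, and logical flags `converged` and `boundary`.
#' @examples
#' set.seed(1)
#' y <- as.numeric(arima.sim(list(ar = 0.5), n = 300))
#' css_fit(y, arima_spec(1, 0, 0))
#' @export
css_fit <- function(series, spec, tol = 1e-8) {
  stopifnot(inherits(spec, "arima_spec"))
  y <- ws_values(series)
  p <- spec$p; d <- spec$d; q <- spec$q
  if (length(y) < 10L * (p + q + 1L))
    stop("series too short to estimate this model reliably")
  w <- if (d > 0L) diff(y, differences = d) else y
  degenerate_input <- stats::sd(w) == 0 && (p + q) > 0L
  if (degenerate_input)
    warning("differenced series is constant; ARMA coefficients are ",
            "unidentified and set to zero, sigma2 is zero")
  include_mean <- spec$include_mean
  npar <- p + q + as.integer(include_mean)
  boundary <- FALSE
  converged <- TRUE
  obj <- function(pp) css_objective(pp, w, p, q, include_mean)

  if (degenerate_input) {
    par <- c(rep(0, p + q), if (include_mean) mean(w))
  } else if (p + q == 0L) {
    # pure random walk / mean model: the CSS minimiser is closed form
    par <- if (include_mean) mean(w) else numeric(0)
  } else if (npar == 1L && !include_mean) {
    # single ARMA coefficient: coarse scan then golden-section refinement
    grid <- seq(-0.95, 0.95, by = 0.05)
    vals <- vapply(grid, obj, numeric(1))
    g0 <- grid[which.min(vals)]
    opt <- stats::optimize(obj,
                           lower = max(-0.9989, g0 - 0.1),
                           upper = min(0.9989, g0 + 0.1),
                           tol = tol)
    par <- opt$minimum
  } else {
    arma_starts <- list(c(-0.5, 0, 0.5))[rep(1L, p + q)]
    starts <- as.matrix(do.call(expand.grid, arma_starts))
    best <- NULL
    for (s in seq_len(nrow(starts))) {
      init <- as.numeric(starts[s, ])
      if (include_mean) init <- c(init, mean(w))
      res <- stats::optim(init, obj, method = "Nelder-Mead",
                          control = list(reltol = tol, maxit = 2000L))
      if (is.null(best) || res$value < best$value) best <- res
    }
    par <- best$par
    if (best$convergence != 0L) converged <- FALSE
  }

  phi <- if (p > 0L) par[seq_len(p)] else numeric(0)
  theta <- if (q > 0L) par[p + seq_len(q)] else numeric(0)
  mu <- if (include_mean) par[p + q + 1L] else 0
  if (length(c(phi, theta)) && max(abs(c(phi, theta))) > 0.995) {
    boundary <- TRUE
    warning("estimate at the stationarity/invertibility boundary")
  }

  eps <- css_innovations(w, phi, theta, mu)
  n_used <- length(eps)
  css <- sum(eps^2)
  sigma2 <- css / n_used

  se <- rep(NA_real_, npar)
  if (npar > 0L && sigma2 > 0) {
    H <- num_hessian(obj, par, h = 1e-4)
    V <- try(2 * sigma2 * solve(H), silent = TRUE)
    if (!inherits(V, "try-error")) {
      dv <- diag(V)
      se[dv > 0] <- sqrt(dv[dv > 0])
    }
  }
  est <- par
  t_ratios <- est / se

  resid <- eps
  if (inherits(series, "weekly_series")) {
    wk <- series$week_start[(length(y) - n_used + 1L):length(y)]
    resid <- weekly_series(wk, eps,
                           label = paste0(ws_label(series), "_residuals"))
  }

  nm <- c(if (p > 0L) paste0("ar", seq_len(p)),
          if (q > 0L) paste0("ma", seq_len(q)),
          if (include_mean) "mean")
  names(se) <- names(t_ratios) <- nm
  structure(list(spec = spec, phi = phi, theta = theta, mu = mu,
                 sigma2 = sigma2, se = se, t_ratios = t_ratios,
                 residuals = resid, n_used = n_used, css = css,
                 converged = converged, boundary = boundary),
            class = "arima_fit")
}

# Central-difference Hessian, fixed step (objective is smooth inside the box).
num_hessian <- function(f, x, h = 1e-4) {
  k <- length(x)
  H <- matrix(NA_real_, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    ei <- replace(numeric(k), i, h)
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h^2
    if (i < k) for (j in (i + 1L):k) {
      ej <- replace(numeric(k), j, h)
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h^2)
    }
  }
  H
}

#' @export
print.arima_fit <- function(x, ...) {
  print(x$spec)
  est <- c(x$phi, x$theta, if (x$spec$include_mean) x$mu)
  if (length(est)) {
    tab <- data.frame(estimate = est, se = x$se, t_ratio = x$t_ratios)
    rownames(tab) <- names(x$se)
    print(round(tab, 4))
  }
  cat(sprintf("sigma2 = %.6g  (CSS %.6g on %d obs)\n",
              x$sigma2, x$css, x$n_used))
  if (!x$converged) cat("warning: optimizer did not report convergence\n")
  if (x$boundary) cat("warning: boundary estimate\n")
  invisible(x)
}

#' @export
residuals.arima_fit <- function(object, ...) object$residuals

#' Sample autocorrelation function
#'
#' Mean-corrected sample autocorrelations with denominator `n` (the
#' Box-Jenkins convention, matching the `2/sqrt(n)` significance band used
#' throughout the package).
#'
#' @param x numeric vector or [weekly_series()].
#' @param max_lag largest lag; must be below half the series length.
#' @return numeric vector of correlations at lags `0..max_lag`.
#' @export
sample_acf <- function(x, max_lag) {
  v <- ws_values(x)
  n <- length(v)
  if (max_lag >= n / 2) stop("max_lag must be below half the series length")
  vc <- v - mean(v)
  c0 <- sum(vc^2) / n
  if (c0 == 0) stop("constant series has no autocorrelation")
  vapply(0:max_lag, function(k) {
    sum(vc[seq_len(n - k)] * vc[(1L + k):n]) / n / c0
  }, numeric(1))
}

#' Sample partial autocorrelation function
#'
#' Computed from [sample_acf()] by the Durbin-Levinson recursion.
#'
#' @inheritParams sample_acf
#' @return numeric vector of partial autocorrelations at lags `1..max_lag`.
#' @export
sample_pacf <- function(x, max_lag) {
  r <- sample_acf(x, max_lag)[-1L]
  pacf_out <- numeric(max_lag)
  phi_prev <- numeric(0)
  for (k in seq_len(max_lag)) {
    if (k == 1L) {
      phi_k <- r[1L]
    } else {
      num <- r[k] - sum(phi_prev * r[(k - 1L):1L])
      den <- 1 - sum(phi_prev * r[seq_len(k - 1L)])
      phi_k <- num / den
      phi_prev <- phi_prev - phi_k * rev(phi_prev)
    }
    pacf_out[k] <- phi_k
    phi_prev <- c(phi_prev, phi_k)
  }
  pacf_out
}

#' One-step-ahead forecast from a fitted ARIMA model
#'
#' Conditional expectation of the next observation given the history and
#' the fitted parameters, with the one-step forecast standard error
#' `sqrt(sigma2)`.  For an IMA(1,1) this reduces to the familiar
#' exponential-smoothing update `y_t - theta * eps_t`.
#'
#' @param fit an `arima_fit`.
#' @param history numeric vector or [weekly_series()] of past observations
#'   (the most recent last); must be longer than `p + d`.
#' @return list with `point` and `se`.
#' @export
one_step_forecast <- function(fit, history) {
  y <- ws_values(history)
  p <- fit$spec$p; d <- fit$spec$d; q <- fit$spec$q
  if (length(y) <= p + d) stop("history shorter than p + d")
  w <- if (d > 0L) diff(y, differences = d) else y
  eps <- css_innovations(w, fit$phi, fit$theta, fit$mu)
  nw <- length(w)
  what <- fit$mu
  if (p > 0L)
    for (i in seq_len(p)) what <- what + fit$phi[i] * (w[nw + 1L - i] - fit$mu)
  if (q > 0L)
    for (j in seq_len(q)) {
      ej <- if (length(eps) + 1L - j >= 1L) eps[length(eps) + 1L - j] else 0
      what <- what - fit$theta[j] * ej
    }
  point <- what
  if (d > 0L) {
    # undo differencing: add back the last value of each difference level
    for (k in seq(d - 1L, 0L)) {
      xk <- if (k == 0L) y else diff(y, differences = k)
      point <- point + xk[length(xk)]
    }
  }
  list(point = point, se = sqrt(fit$sigma2))
}
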