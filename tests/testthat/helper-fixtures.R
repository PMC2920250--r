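# Shared fixtures and independent oracles used across the test files.

# Small, fast generator configuration for plumbing tests.
quick_config <- function(seed = 101L, ...) {
  generator_config(n_weeks = 60L, seed = seed, ...)
}

# Brute-force conditional sum of squares, written as plain loops so it is
# independent of the package's vectorised implementation.
css_brute_ar1 <- function(w, phi) {
  s <- 0
  for (t in 2:length(w)) s <- s + (w[t] - phi * w[t - 1])^2
  s
}

css_brute_ma1 <- function(w, theta) {
  e_prev <- 0
  s <- 0
  for (t in seq_along(w)) {
    e <- w[t] + theta * e_prev
    s <- s + e^2
    e_prev <- e
  }
  s
}

# Simulate with R's generator but the package's (1 - theta B) convention.
sim_ar1 <- function(n, phi, sd = 1) {
  as.numeric(stats::arima.sim(list(ar = phi), n = n, sd = sd))
}
sim_ima11 <- function(n, theta, sd = 1, start = 0) {
  w <- as.numeric(stats::arima.sim(list(ma = -theta), n = n, sd = sd))
  start + cumsum(w)
}

# Twenty large synthetic outbreaks (all >= 50 cases, three >= 100), with a
# mix of blank and multi-week last-onset dates.
large_outbreak_fixture <- function() {
  data.frame(
    first_onset = as.Date(c(
      "2006-01-25", "2006-04-18", "2006-04-24", "2006-04-25", "2006-04-26",
      "2006-05-08", "2006-10-26", "2006-11-23", "2006-11-30", "2006-11-30",
      "2006-12-07", "2006-12-07", "2007-01-03", "2007-01-08", "2007-07-13",
      "2007-08-03", "2007-09-15", "2007-12-20", "2007-12-22", "2007-12-22")),
    last_onset = as.Date(c(
      NA, NA, NA, "2006-05-02", NA, NA, NA, NA, NA, NA, NA, NA, NA, NA,
      "2007-07-17", "2007-08-17", "2007-09-19", "2008-01-01", NA,
      "2008-01-15")),
    cases = c(101L, 60L, 62L, 107L, 55L, 50L, 81L, 86L, 72L, 63L, 80L,
              61L, 76L, 60L, 92L, 153L, 51L, 52L, 52L, 76L),
    etiology = "norovirus",
    institutional = 0L)
}
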