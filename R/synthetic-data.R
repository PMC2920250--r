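#' Configuration for the synthetic surveillance-data generator
#'
#' Builds the parameter set describing a synthetic study: an IMA(1,1)
#' weekly sales-proportion series converted to daily unit-sales records, an
#' AR(1) weekly case-count series expanded into individual case reports, a
#' sparse Poisson outbreak process, and an optional injected effect of
#' outbreak-associated cases on remedy sales.  Defaults reproduce the
#' surveillance setting the package models: a 236-week study grid starting
#' Sunday 2003-06-29, a sales proportion averaging 0.044 with an overall
#' standard deviation near 0.014, MA(1) coefficient 0.4 on the differenced
#' proportion, weekly case counts around 55 with AR(1) coefficient 0.33,
#' and roughly one outbreak per week with sizes of median ~19 and maxima
#' near 150 cases.
#'
#' @param n_weeks number of weeks (>= 10).
#' @param start_date first Sunday of the study grid.
#' @param sales_theta MA(1) coefficient of the differenced proportion
#'   series, `(1 - theta B)` convention, `|theta| < 1`.
#' @param sales_sigma innovation SD of the proportion series (> 0 unless a
#'   deterministic series is wanted).
#' @param sales_level starting proportion level, in (0, 1).
#' @param total_units_mean mean weekly all-category non-promotional unit
#'   sales (weekly totals are Poisson around this).
#' @param promo_frac expected promotional units as a fraction of
#'   non-promotional units; promotional records are emitted and flagged but
#'   never enter the analysis proportion.
#' @param case_phi AR(1) coefficient of the weekly case counts, `|phi| < 1`.
#' @param case_mean,case_sigma mean and innovation SD of weekly case counts.
#' @param outbreak_rate expected outbreaks per week (Poisson).
#' @param outbreak_size_dist distribution spec for outbreak case counts:
#'   `list(dist = "nbinom1", mu =, size =)` (1 + negative binomial),
#'   `list(dist = "fixed", value =)`, or `list(dist = "geometric1", mean =)`.
#' @param outbreak_duration_dist distribution spec for whole weeks from
#'   first to last onset (same forms; default geometric with mean 1).
#' @param missing_last_prob probability an outbreak's last-onset date is
#'   blanked out in the emitted records.
#' @param report_outbreak_cases fraction of outbreak-associated cases that
#'   also appear as individual case reports in the outbreak's onset week.
#' @param effect_per_case extra diarrheal units sold per concurrent
#'   outbreak-associated case (0 = sales independent of outbreaks).
#' @param effect_lag_weeks lag, in weeks, of that effect on sales.
#' @param seed integer random seed; every generated artefact is a
#'   deterministic function of the configuration including the seed.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_weeks = 236L,
                             start_date = as.Date("2003-06-29"),
                             sales_theta = 0.4,
                             sales_sigma = 0.0026,
                             sales_level = 0.044,
                             total_units_mean = 55000,
                             promo_frac = 0.1,
                             case_phi = 0.33,
                             case_mean = 55,
                             case_sigma = 12,
                             outbreak_rate = 1.0,
                             outbreak_size_dist = list(dist = "nbinom1",
                                                       mu = 24, size = 2),
                             outbreak_duration_dist = list(dist = "geometric1",
                                                           mean = 1) ,
                             missing_last_prob = 0.7,
                             report_outbreak_cases = 1.0,
                             effect_per_case = 0,
                             effect_lag_weeks = 0L,
                             seed = 20100720L) {
  start_date <- as.Date(start_date)
  if (weekday_num(start_date) != 0L) stop("start_date must be a Sunday")
  n_weeks <- as.integer(n_weeks)
  if (n_weeks < 10L) stop("n_weeks must be at least 10")
  if (abs(sales_theta) >= 1) stop("|sales_theta| must be < 1")
  if (abs(case_phi) >= 1) stop("|case_phi| must be < 1")
  if (sales_sigma < 0) stop("sales_sigma must be non-negative")
  if (sales_level <= 0 || sales_level >= 1)
    stop("sales_level must be inside (0, 1)")
  if (outbreak_rate < 0) stop("outbreak_rate must be non-negative")
  if (missing_last_prob < 0 || missing_last_prob > 1)
    stop("missing_last_prob must be a probability")
  structure(list(n_weeks = n_weeks, start_date = start_date,
                 sales_theta = sales_theta, sales_sigma = sales_sigma,
                 sales_level = sales_level,
                 total_units_mean = total_units_mean,
                 promo_frac = promo_frac,
                 case_phi = case_phi, case_mean = case_mean,
                 case_sigma = case_sigma,
                 outbreak_rate = outbreak_rate,
                 outbreak_size_dist = outbreak_size_dist,
                 outbreak_duration_dist = outbreak_duration_dist,
                 missing_last_prob = missing_last_prob,
                 report_outbreak_cases = report_outbreak_cases,
                 effect_per_case = effect_per_case,
                 effect_lag_weeks = as.integer(effect_lag_weeks),
                 seed = as.integer(seed)),
            class = "generator_config")
}

config_weeks <- function(config) {
  seq(config$start_date, by = 7L, length.out = config$n_weeks)
}

# One seeded generator; each artefact draws from its own deterministic
# sub-stream so generation order never matters.
substream_seed <- function(config, stream) {
  streams <- c(sales = 1L, cases = 2L, outbreaks = 3L, daily = 4L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  sub <- sample.int(.Machine$integer.max - 1L, length(streams))
  sub[[streams[[stream]]]]
}

draw_dist <- function(spec, n) {
  switch(spec$dist,
    nbinom1 = 1L + stats::rnbinom(n, mu = spec$mu, size = spec$size),
    fixed = rep(as.numeric(spec$value), n),
    geometric1 = stats::rgeom(n, prob = 1 / (1 + spec$mean)),
    stop("unknown distribution spec: ", spec$dist))
}

# NRDM-style sales categories; first is the analysis category.
.sales_categories <- c("diarrhea_remedies", "anti_fever_adult",
                       "cold_relief_adult_tablet", "cough_syrup_adult_liquid",
                       "throat_lozenges", "thermometers")
.other_category_weights <- c(0.25, 0.30, 0.20, 0.15, 0.10)

.case_etiologies <- c("campylobacteriosis", "cryptosporidiosis",
                      "salmonellosis", "giardiasis", "shigellosis",
                      "amoebiasis", "other")
.case_etiology_weights <- c(0.29, 0.19, 0.19, 0.15, 0.09, 0.04, 0.05)

.outbreak_etiologies <- c("norovirus", "unknown", "salmonellosis", "other")
.outbreak_etiology_weights <- c(0.62, 0.18, 0.07, 0.13)

#' Generate synthetic over-the-counter sales data
#'
#' Simulates the weekly diarrheal-remedy sales proportion as an IMA(1,1),
#' \deqn{p_t = p_{t-1} + \varepsilon_t - \theta\,\varepsilon_{t-1},}
#' clipped to (0, 1), converts it to integer diarrheal and total unit
#' counts (weekly totals Poisson around `total_units_mean`), optionally
#' injects an outbreak-driven sales effect, and expands the weekly units
#' into daily per-category records with promotional sales flagged.
#' The daily records re-aggregate exactly to the returned weekly series.
#'
#' @param config a [generator_config()].
#' @param outbreaks optional outbreak records (from [generate_outbreaks()]);
#'   when supplied and `effect_per_case > 0` the effect is injected before
#'   daily records are emitted.
#' @param daily emit daily records?  Set `FALSE` for weekly-only studies
#'   (e.g. large simulation sweeps).
#' @return object of class `sales_sim`: list with `weekly` (achieved
#'   proportion [weekly_series()]), `latent` (pre-rounding proportion),
#'   `units` (data frame week_start / diarrhea_units / total_units /
#'   injected_units) and `daily` (data frame date / category /
#'   promotional / units, or `NULL`).
#' @export
generate_sales <- function(config, outbreaks = NULL, daily = TRUE) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(substream_seed(config, "sales"))
  n <- config$n_weeks
  weeks <- config_weeks(config)
  eps <- stats::rnorm(n, 0, config$sales_sigma)
  theta <- config$sales_theta

  incr <- eps - theta * c(0, eps[-n])
  p <- config$sales_level + cumsum(incr)
  lo <- 1e-6; hi <- 1 - 1e-6
  if (any(p <= lo | p >= hi)) {
    # sequential clip so the walk continues from the clipped level
    p <- numeric(n)
    prev <- config$sales_level
    for (t in seq_len(n)) {
      prev <- min(max(prev + incr[t], lo), hi)
      p[t] <- prev
    }
    warning("proportion series hit the (0,1) clip boundary; ",
            "consider a smaller sales_sigma or a more central sales_level")
  }

  total <- stats::rpois(n, config$total_units_mean)
  diarrhea <- pmin(round(p * total), total)
  units <- data.frame(week_start = weeks,
                      diarrhea_units = as.numeric(diarrhea),
                      total_units = as.numeric(total),
                      injected_units = 0)
  sim <- structure(list(weekly = weekly_series(weeks, diarrhea / total,
                                               label = "sales_proportion"),
                        latent = weekly_series(weeks, p,
                                               label = "latent_proportion"),
                        units = units, daily = NULL),
                   class = "sales_sim")
  if (!is.null(outbreaks) && config$effect_per_case != 0)
    sim <- inject_effect(sim, outbreaks, config$effect_per_case,
                         config$effect_lag_weeks)
  if (daily) sim$daily <- emit_daily_sales(sim, config)
  sim
}

# Split weekly units into 7 daily chunks and a handful of categories;
# multinomial splits keep the weekly totals exact so aggregation closes.
emit_daily_sales <- function(sim, config) {
  set.seed(substream_seed(config, "daily"))
  weeks <- sim$units$week_start
  n <- length(weeks)
  out <- vector("list", n)
  n_other <- length(.sales_categories) - 1L
  for (i in seq_len(n)) {
    dvec <- stats::rmultinom(1L, sim$units$diarrhea_units[i], rep(1, 7))[, 1L]
    other_total <- sim$units$total_units[i] - sim$units$diarrhea_units[i]
    ovec <- stats::rmultinom(1L, other_total,
                             rep(.other_category_weights, each = 7) / 7)[, 1L]
    dates <- weeks[i] + 0:6
    rec <- data.frame(
      date = c(dates, rep(dates, n_other)),
      category = rep(.sales_categories, each = 7L),
      promotional = 0L,
      units = c(dvec, ovec))
    promo_units <- stats::rpois(nrow(rec), config$promo_frac * rec$units)
    promo <- rec
    promo$promotional <- 1L
    promo$units <- promo_units
    rec <- rbind(rec, promo)
    out[[i]] <- rec[rec$units > 0L, ]
  }
  daily <- do.call(rbind, out)
  rownames(daily) <- NULL
  daily
}

#' Inject an outbreak-driven effect into simulated sales
#'
#' For every outbreak-active week `w` (first-onset week through last-onset
#' week, single week when the last onset is missing), diarrheal units in
#' week `w + lag` are increased by `effect_per_case` times the
#' outbreak-associated cases active that week; the totals and the achieved
#' proportion are recomputed.  Effects that the lag pushes past the end of
#' the grid are truncated with a warning.
#'
#' @param sales a `sales_sim` from [generate_sales()].
#' @param outbreaks outbreak records (data frame with `first_onset`,
#'   `last_onset`, `cases`).
#' @param effect_per_case extra units per active case.
#' @param effect_lag_weeks integer lag in weeks.
#' @return the modified `sales_sim` (daily records, if any, are dropped:
#'   regenerate them via [generate_sales()] with `outbreaks` supplied).
#' @export
inject_effect <- function(sales, outbreaks, effect_per_case,
                          effect_lag_weeks = 0L) {
  stopifnot(inherits(sales, "sales_sim"))
  units <- sales$units
  units$injected_units <- 0
  weeks <- units$week_start
  if (effect_per_case != 0 && nrow(outbreaks) > 0L) {
    active <- outbreak_active_cases(outbreaks, weeks)
    lag <- as.integer(effect_lag_weeks)
    add <- round(effect_per_case * active)
    idx <- seq_along(weeks) + lag
    keep <- idx >= 1L & idx <= length(weeks)
    if (any(add[!keep] > 0))
      warning("injected effect truncated at the edge of the week grid")
    bump <- numeric(length(weeks))
    bump[idx[keep]] <- add[keep]
    units$diarrhea_units <- units$diarrhea_units + bump
    units$total_units <- units$total_units + bump
    units$injected_units <- bump
  }
  sales$units <- units
  sales$weekly <- weekly_series(weeks,
                                units$diarrhea_units / units$total_units,
                                label = "sales_proportion")
  sales$daily <- NULL
  sales
}

# Outbreak-associated cases active in each grid week: an outbreak
# contributes its full case count to every week from its first-onset week
# to its last-onset week (missing last onset = active one week).
outbreak_active_cases <- function(outbreaks, weeks) {
  active <- numeric(length(weeks))
  if (nrow(outbreaks) == 0L) return(active)
  ws <- week_start(outbreaks$first_onset)
  we <- ifelse(is.na(outbreaks$last_onset), as.integer(ws),
               as.integer(week_start(outbreaks$last_onset)))
  we <- as.Date(we, origin = "1970-01-01")
  for (i in seq_len(nrow(outbreaks))) {
    hit <- weeks >= ws[i] & weeks <= we[i]
    active[hit] <- active[hit] + outbreaks$cases[i]
  }
  active
}

#' Generate synthetic gastrointestinal case reports
#'
#' Weekly counts follow a latent AR(1),
#' \deqn{c_t = \mu + \phi (c_{t-1} - \mu) + \varepsilon_t,}
#' rounded to non-negative integers; each counted case becomes one report
#' record with a report date inside its week, an etiology and a county.
#'
#' @param config a [generator_config()].
#' @param records expand the weekly counts into individual report records?
#'   Set `FALSE` for weekly-only simulation sweeps (the weekly series is
#'   unchanged either way).
#' @return list with `records` (data frame report_date / etiology /
#'   county, or `NULL`), `weekly` (integer-count [weekly_series()]) and
#'   `latent` (pre-rounding counts).
#' @export
generate_cases <- function(config, records = TRUE) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(substream_seed(config, "cases"))
  n <- config$n_weeks
  weeks <- config_weeks(config)
  phi <- config$case_phi
  eps <- stats::rnorm(n, 0, config$case_sigma)
  c_lat <- numeric(n)
  prev <- config$case_mean +
    if (config$case_sigma > 0)
      stats::rnorm(1, 0, config$case_sigma / sqrt(1 - phi^2)) else 0
  for (t in seq_len(n)) {
    prev <- config$case_mean + phi * (prev - config$case_mean) + eps[t]
    c_lat[t] <- prev
  }
  counts <- pmax(0L, as.integer(round(c_lat)))
  total <- sum(counts)
  rec <- NULL
  if (records)
    rec <- data.frame(
      report_date = rep(weeks, counts) +
        sample(0:6, total, replace = TRUE),
      etiology = sample(.case_etiologies, total, replace = TRUE,
                        prob = .case_etiology_weights),
      county = sample(paste0("county_", 1:3), total, replace = TRUE))
  list(records = rec,
       weekly = weekly_series(weeks, counts, label = "case_count"),
       latent = weekly_series(weeks, c_lat, label = "latent_cases"))
}

#' Generate synthetic outbreak records
#'
#' Outbreak first onsets arrive as a Poisson process at `outbreak_rate`
#' per week (uniform day within the week); sizes and whole-week durations
#' come from the configured distributions, and a configurable fraction of
#' last-onset dates are blanked to mimic incomplete surveillance records.
#'
#' @param config a [generator_config()].
#' @return data frame with columns `first_onset`, `last_onset` (`NA` when
#'   missing), `cases`, `etiology`, `institutional`.
#' @export
generate_outbreaks <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(substream_seed(config, "outbreaks"))
  weeks <- config_weeks(config)
  k <- stats::rpois(config$n_weeks, config$outbreak_rate)
  m <- sum(k)
  empty <- data.frame(first_onset = as.Date(character()),
                      last_onset = as.Date(character()),
                      cases = integer(), etiology = character(),
                      institutional = integer())
  if (m == 0L) return(empty)
  first_onset <- rep(weeks, k) + sample(0:6, m, replace = TRUE)
  cases <- as.integer(round(draw_dist(config$outbreak_size_dist, m)))
  cases <- pmax(1L, cases)
  dur_weeks <- as.integer(round(draw_dist(config$outbreak_duration_dist, m)))
  last_onset <- first_onset + 7L * pmax(0L, dur_weeks)
  last_onset[stats::runif(m) < config$missing_last_prob] <- NA
  out <- data.frame(
    first_onset = first_onset,
    last_onset = last_onset,
    cases = cases,
    etiology = sample(.outbreak_etiologies, m, replace = TRUE,
                      prob = .outbreak_etiology_weights),
    institutional = stats::rbinom(m, 1L, 0.3))
  out[order(out$first_onset), , drop = FALSE]
}

#' Simulate a full synthetic surveillance study
#'
#' Orchestrates the three generators with consistent sub-streams of the
#' configured seed: outbreaks first, then case reports (optionally
#' augmented with reported outbreak-associated cases in the outbreak's
#' onset week), then sales with any configured outbreak effect injected
#' before daily records are emitted.  Optionally writes the four CSV
#' artefacts (`sales_daily.csv`, `cases.csv`, `outbreaks.csv`,
#' `truth.csv`) to a directory.
#'
#' @param config a [generator_config()].
#' @param out_dir directory to write CSV files to (created if needed);
#'   `NULL` skips writing.
#' @param daily emit daily sales records?
#' @return list with `sales` (a `sales_sim`), `cases`, `outbreaks`, and
#'   `truth` (weekly data frame of all latent quantities).
#' @export
simulate_study <- function(config, out_dir = NULL, daily = TRUE) {
  stopifnot(inherits(config, "generator_config"))
  outbreaks <- generate_outbreaks(config)
  cases <- generate_cases(config)
  weeks <- config_weeks(config)

  if (config$report_outbreak_cases > 0 && nrow(outbreaks) > 0L) {
    rep_n <- as.integer(round(config$report_outbreak_cases * outbreaks$cases))
    keep <- rep_n > 0L
    if (any(keep)) {
      ob_records <- data.frame(
        report_date = rep(outbreaks$first_onset[keep], rep_n[keep]),
        etiology = rep(outbreaks$etiology[keep], rep_n[keep]),
        county = "county_1")
      cases$records <- rbind(cases$records, ob_records)
      extra <- tabulate(match(week_start(ob_records$report_date), weeks),
                        nbins = length(weeks))
      cases$weekly <- weekly_series(weeks, cases$weekly$value + extra,
                                    label = "case_count")
    }
  }

  sales <- generate_sales(config, outbreaks = outbreaks, daily = daily)
  truth <- data.frame(week_start = weeks,
                      latent_proportion = sales$latent$value,
                      proportion = sales$weekly$value,
                      diarrhea_units = sales$units$diarrhea_units,
                      total_units = sales$units$total_units,
                      injected_units = sales$units$injected_units,
                      latent_cases = cases$latent$value,
                      case_count = cases$weekly$value)
  study <- list(sales = sales, cases = cases, outbreaks = outbreaks,
                truth = truth)
  if (!is.null(out_dir)) write_study(study, out_dir)
  study
}

write_study <- function(study, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(study$sales$daily))
    utils::write.csv(study$sales$daily,
                     file.path(out_dir, "sales_daily.csv"), row.names = FALSE)
  utils::write.csv(study$cases$records,
                   file.path(out_dir, "cases.csv"), row.names = FALSE)
  ob <- study$outbreaks
  ob$last_onset <- ifelse(is.na(ob$last_onset), "",
                          format(ob$last_onset))
  utils::write.csv(ob, file.path(out_dir, "outbreaks.csv"),
                   row.names = FALSE)
  utils::write.csv(study$truth, file.path(out_dir, "truth.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}
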