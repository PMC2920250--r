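#' Identify outbreak weeks on a week grid
#'
#' A week is an outbreak week when at least one outbreak (of at least
#' `min_cases` cases) is active in it: the outbreak started that week or
#' earlier and ended that week or later.  Outbreaks with a missing
#' last-onset date are taken to be active only in their first-onset week.
#'
#' @param outbreaks data frame with `first_onset`, `last_onset` (may be
#'   `NA`) and `cases`.
#' @param week_grid `Date` vector of consecutive Sundays (the evaluation
#'   grid, typically the forecasting period).
#' @param min_cases inclusive minimum outbreak size.
#' @return sorted `Date` vector of outbreak weeks (subset of `week_grid`).
#' @export
outbreak_weeks <- function(outbreaks, week_grid, min_cases = 1L) {
  week_grid <- as.Date(week_grid)
  if (length(week_grid) > 1L && any(diff(as.integer(week_grid)) != 7L))
    stop("week_grid must be consecutive Sundays")
  if (any(weekday_num(week_grid) != 0L))
    stop("week_grid must contain Sundays")
  keep <- outbreaks[outbreaks$cases >= min_cases, , drop = FALSE]
  if (!nrow(keep)) return(as.Date(character()))
  ws <- week_start(keep$first_onset)
  we <- as.Date(ifelse(is.na(keep$last_onset), as.integer(ws),
                       as.integer(week_start(keep$last_onset))),
                origin = "1970-01-01")
  hit <- rep(FALSE, length(week_grid))
  for (i in seq_len(nrow(keep)))
    hit <- hit | (week_grid >= ws[i] & week_grid <= we[i])
  week_grid[hit]
}

#' Sensitivity and specificity of signals against outbreak weeks
#'
#' Sensitivity is the number of outbreak weeks carrying a signal divided
#' by the total number of outbreak weeks; specificity is the number of
#' non-outbreak weeks without a signal divided by the total number of
#' non-outbreak weeks.  Signals and outbreak weeks outside the evaluation
#' grid are ignored; outbreak weeks and non-outbreak weeks always
#' partition the grid.
#'
#' @param signal_weeks `Date` vector of signal weeks.
#' @param outbreak_week_set `Date` vector of outbreak weeks (e.g. from
#'   [outbreak_weeks()]).
#' @param week_grid `Date` vector of Sundays: the evaluation grid.
#' @param min_cases the size filter used to build `outbreak_week_set`
#'   (carried along for reporting).
#' @return object of class `eval_result`: list with `sensitivity`,
#'   `specificity` (NA when the denominator is empty),
#'   `outbreak_weeks_with_signal`, `total_outbreak_weeks`,
#'   `nonoutbreak_weeks_without_signal`, `total_nonoutbreak_weeks`,
#'   `min_cases`, `signal_weeks`.
#' @export
sensitivity_specificity <- function(signal_weeks, outbreak_week_set,
                                    week_grid, min_cases = 1L) {
  week_grid <- as.Date(week_grid)
  if (!length(week_grid)) stop("empty evaluation grid")
  signal_weeks <- as.Date(signal_weeks)
  signal_weeks <- signal_weeks[signal_weeks %in% week_grid]
  ow <- as.Date(outbreak_week_set)
  ow <- ow[ow %in% week_grid]
  now <- week_grid[!week_grid %in% ow]
  hit <- sum(ow %in% signal_weeks)
  clean <- sum(!now %in% signal_weeks)
  structure(list(
    sensitivity = if (length(ow)) hit / length(ow) else NA_real_,
    specificity = if (length(now)) clean / length(now) else NA_real_,
    outbreak_weeks_with_signal = hit,
    total_outbreak_weeks = length(ow),
    nonoutbreak_weeks_without_signal = clean,
    total_nonoutbreak_weeks = length(now),
    min_cases = min_cases,
    signal_weeks = sort(signal_weeks)),
    class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  pct <- function(num, den) {
    if (!den) return("undefined (0 denominator)")
    sprintf("%d%% (%d/%d)", round(100 * num / den), num, den)
  }
  cat(sprintf("outbreak size filter: >= %d cases\n", x$min_cases))
  cat("sensitivity:",
      pct(x$outbreak_weeks_with_signal, x$total_outbreak_weeks), "\n")
  cat("specificity:",
      pct(x$nonoutbreak_weeks_without_signal, x$total_nonoutbreak_weeks),
      "\n")
  invisible(x)
}

#' Randomly placed signals as a null baseline
#'
#' Scores sets of `k` signal weeks drawn uniformly without replacement
#' from the evaluation grid, giving the null distribution against which a
#' model's signals are judged: a useful alarm must locate outbreak weeks
#' better than the same number of alarms placed at random.
#'
#' @param week_grid `Date` vector of Sundays.
#' @param k signals per random set (`k <= length(week_grid)`).
#' @param outbreak_week_set outbreak weeks to score against.
#' @param n_sets number of random sets.
#' @param seed optional integer seed for reproducibility.
#' @param min_cases carried through to the results, for reporting.
#' @return list of `n_sets` [sensitivity_specificity()] results.
#' @export
random_signal_baseline <- function(week_grid, k, outbreak_week_set,
                                   n_sets = 3L, seed = NULL,
                                   min_cases = 1L) {
  week_grid <- as.Date(week_grid)
  if (k > length(week_grid)) stop("k exceeds the grid size")
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_sets), function(s) {
    sig <- sample(week_grid, k)
    sensitivity_specificity(sig, outbreak_week_set, week_grid,
                            min_cases = min_cases)
  })
}

#' Rank a model's sensitivity within its random baseline
#'
#' Normalised rank of the model sensitivity among `n_sets` random signal
#' sets of the same size, with randomised tie-breaking, so the rank is
#' exactly uniform on (0, 1) when model signals are no better than random.
#'
#' @param model_eval an `eval_result` for the model's signals.
#' @param week_grid,outbreak_week_set as in [random_signal_baseline()].
#' @param n_sets number of random comparison sets.
#' @param seed optional integer seed.
#' @return number in (0, 1): the fraction of the null distribution lying
#'   below the model's sensitivity.
#' @export
baseline_rank <- function(model_eval, week_grid, outbreak_week_set,
                          n_sets = 1000L, seed = NULL) {
  stopifnot(inherits(model_eval, "eval_result"))
  if (!is.null(seed)) set.seed(seed)
  week_grid <- as.Date(week_grid)
  ow <- as.Date(outbreak_week_set)
  ow <- ow[ow %in% week_grid]
  k <- length(model_eval$signal_weeks)
  if (!length(ow)) return(stats::runif(1))  # no outbreak weeks: pure tie
  sens <- if (k > 0L)
    vapply(seq_len(n_sets), function(s)
      sum(sample(week_grid, k) %in% ow) / length(ow), numeric(1))
  else rep(0, n_sets)
  ms <- model_eval$sensitivity
  (sum(sens < ms) + stats::runif(1) * (sum(sens == ms) + 1L)) / (n_sets + 1L)
}
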