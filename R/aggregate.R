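#' Weekly sales-proportion aggregation
#'
#' Computes the analysis variable: per Sunday-anchored week, the proportion
#' of non-promotional diarrheal-remedy units to non-promotional units over
#' all categories combined.  Promotional records are excluded from both
#' numerator and denominator.
#'
#' @param daily data frame with columns `date`, `category`, `promotional`
#'   (0/1) and `units`.
#' @param diarrhea_category category name forming the numerator.
#' @param fill what to do with a week whose denominator is zero:
#'   `"error"` (default) or `"carry"` (carry the previous week's
#'   proportion forward).
#' @return a [weekly_series()] of proportions over the full week range of
#'   the data.
#' @export
aggregate_sales <- function(daily,
                            diarrhea_category = "diarrhea_remedies",
                            fill = c("error", "carry")) {
  fill <- match.arg(fill)
  need <- c("date", "category", "promotional", "units")
  if (!all(need %in% names(daily)))
    stop("daily sales records need columns: ", paste(need, collapse = ", "))
  np <- daily[daily$promotional == 0L, , drop = FALSE]
  wk <- week_start(np$date)
  grid <- week_seq(min(wk), max(wk))
  idx <- match(wk, grid)
  denom <- as.numeric(tapply_sum(np$units, idx, length(grid)))
  is_d <- np$category == diarrhea_category
  numer <- as.numeric(tapply_sum(np$units[is_d], idx[is_d], length(grid)))
  if (any(denom == 0)) {
    if (fill == "error")
      stop("week(s) with zero non-promotional units: ",
           paste(format(grid[denom == 0]), collapse = ", "))
    prop <- numer / denom
    for (i in which(denom == 0)) {
      if (i == 1L) stop("cannot carry forward into the first week")
      prop[i] <- prop[i - 1L]
    }
  } else prop <- numer / denom
  weekly_series(grid, prop, label = "sales_proportion")
}

tapply_sum <- function(x, idx, nbins) {
  out <- numeric(nbins)
  if (length(x)) {
    s <- tapply(x, factor(idx, levels = seq_len(nbins)), sum)
    out[!is.na(s)] <- s[!is.na(s)]
  }
  out
}

#' Weekly case-count aggregation
#'
#' Counts case reports per week of report, restricted to reports on or
#' after `date_floor` (early records are dropped to avoid known shifts in
#' reporting practice), with interior weeks zero-filled.
#'
#' @param records data frame with a `report_date` column.
#' @param date_floor earliest report date kept; defaults to the first
#'   Sunday of 2004.
#' @param grid optional `Date` vector of Sundays fixing the output range
#'   (required when `records` is empty).
#' @return a [weekly_series()] of counts.
#' @export
aggregate_cases <- function(records, date_floor = as.Date("2004-01-04"),
                            grid = NULL) {
  dates <- as.Date(records$report_date)
  dates <- dates[dates >= as.Date(date_floor)]
  if (is.null(grid)) {
    if (!length(dates))
      stop("no records on/after date_floor and no grid supplied")
    grid <- week_seq(min(dates), max(dates))
  } else {
    grid <- as.Date(grid)
    dates <- dates[week_start(dates) >= grid[1L] &
                     week_start(dates) <= grid[length(grid)]]
  }
  counts <- tabulate(match(week_start(dates), grid), nbins = length(grid))
  weekly_series(grid, counts, label = "case_count")
}

#' Weekly outbreak aggregation
#'
#' Filters outbreaks to `cases >= min_cases` (inclusive, matching the
#' "50 or more / 100 or more" strata) and assigns both the outbreak count
#' and the outbreak-associated case total to the week of first onset.
#'
#' @param outbreaks data frame with `first_onset` and `cases` columns.
#' @param min_cases inclusive minimum outbreak size.
#' @param grid optional `Date` vector of Sundays fixing the output range
#'   (required when no outbreak survives the filter).
#' @return list of two [weekly_series()]: `outbreaks` (counts) and
#'   `cases` (outbreak-associated case totals).
#' @export
aggregate_outbreaks <- function(outbreaks, min_cases = 1L, grid = NULL) {
  keep <- outbreaks[outbreaks$cases >= min_cases, , drop = FALSE]
  wk <- week_start(keep$first_onset)
  if (is.null(grid)) {
    if (!nrow(keep)) stop("no outbreaks pass the filter and no grid supplied")
    grid <- week_seq(min(wk), max(wk))
  } else grid <- as.Date(grid)
  idx <- match(wk, grid)
  ok <- !is.na(idx)
  n_ob <- tabulate(idx[ok], nbins = length(grid))
  n_cases <- tapply_sum(keep$cases[ok], idx[ok], length(grid))
  list(outbreaks = weekly_series(grid, n_ob, label = "outbreak_count"),
       cases = weekly_series(grid, n_cases, label = "outbreak_cases"))
}

#' Study-period split definition
#'
#' The study timeline is divided into contiguous model-building,
#' validation and forecasting date ranges.  The default reproduces the
#' package's reference layout: model 2003-06-29 to 2005-07-02, validation
#' 2005-07-03 to 2005-12-31, forecasting 2006-01-01 to 2007-12-30
#' (105 + 26 + 105 Sunday-anchored weeks).
#'
#' @param model,forecasting length-2 `Date` vectors `c(start, end)`.
#' @param validation length-2 `Date` vector, or `NULL` for a degenerate
#'   split with no validation period.
#' @return object of class `period_split`.
#' @export
period_split <- function(model, validation, forecasting) {
  as_range <- function(r) {
    r <- as.Date(r)
    if (length(r) != 2L || r[2L] < r[1L]) stop("range must be c(start, end)")
    r
  }
  model <- as_range(model)
  forecasting <- as_range(forecasting)
  if (!is.null(validation)) validation <- as_range(validation)
  ranges <- Filter(Negate(is.null),
                   list(model = model, validation = validation,
                        forecasting = forecasting))
  for (i in seq_len(length(ranges) - 1L))
    if (ranges[[i + 1L]][1L] != ranges[[i]][2L] + 1L)
      stop("periods must be contiguous and in order (model, validation, forecasting)")
  structure(list(model = model, validation = validation,
                 forecasting = forecasting),
            class = "period_split")
}

#' @rdname period_split
#' @export
default_period_split <- function() {
  period_split(model = c("2003-06-29", "2005-07-02"),
               validation = c("2005-07-03", "2005-12-31"),
               forecasting = c("2006-01-01", "2007-12-30"))
}

#' Split a weekly series into model / validation / forecasting parts
#'
#' Each week is assigned to the period whose date range contains its
#' Sunday.  The three parts partition the input: concatenating them
#' reproduces the series exactly; weeks falling outside every range are an
#' error.
#'
#' @param series a [weekly_series()].
#' @param split a [period_split()].
#' @return list of [weekly_series()] (`model`, `validation`,
#'   `forecasting`; `validation` is `NULL` for a degenerate split).
#' @export
split_periods <- function(series, split = default_period_split()) {
  stopifnot(inherits(split, "period_split"))
  part <- function(r) {
    if (is.null(r)) return(NULL)
    keep <- series$week_start >= r[1L] & series$week_start <= r[2L]
    if (!any(keep)) return(NULL)
    weekly_series(series$week_start[keep], series$value[keep],
                  label = ws_label(series))
  }
  out <- list(model = part(split$model),
              validation = part(split$validation),
              forecasting = part(split$forecasting))
  covered <- sum(vapply(out, function(p) if (is.null(p)) 0L else nrow(p),
                        integer(1)))
  if (covered != nrow(series))
    stop("split ranges do not cover the series (", nrow(series) - covered,
         " weeks uncovered)")
  out
}
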