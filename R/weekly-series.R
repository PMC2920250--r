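#' Sunday-anchored weekly time series
#'
#' The whole pipeline works on weekly series labelled by the Sunday that
#' starts the week (weeks run Sunday through Saturday).  A `weekly_series`
#' is a data frame with columns `week_start` (consecutive Sundays, no gaps)
#' and `value`, plus a `label` attribute naming the series.
#'
#' @param week_start vector of dates, all Sundays, strictly increasing by
#'   exactly seven days.
#' @param values numeric values, one per week.
#' @param label short series name used in printing and plots.
#' @return An object of class `weekly_series` (also a `data.frame`).
#' @examples
#' weekly_series(seq(as.Date("2006-01-01"), by = 7, length.out = 4),
#'               c(0.04, 0.05, 0.045, 0.042), label = "sales_proportion")
#' @export
weekly_series <- function(week_start, values, label = "series") {
  week_start <- as.Date(week_start)
  values <- as.numeric(values)
  if (length(week_start) != length(values))
    stop("week_start and values must have the same length")
  if (length(values) < 1L) stop("a weekly series needs at least one week")
  o <- order(week_start)
  week_start <- week_start[o]
  values <- values[o]
  if (any(weekday_num(week_start) != 0L))
    stop("all week_start dates must be Sundays")
  if (length(week_start) > 1L &&
      any(diff(as.integer(week_start)) != 7L))
    stop("weeks must be consecutive Sundays with no gaps")
  structure(data.frame(week_start = week_start, value = values),
            label = label,
            class = c("weekly_series", "data.frame"))
}

#' @export
print.weekly_series <- function(x, ...) {
  cat(sprintf("Weekly series '%s': %d weeks, %s to %s\n",
              ws_label(x), nrow(x),
              format(x$week_start[1L]),
              format(x$week_start[nrow(x)])))
  print.data.frame(utils::head(as.data.frame(x), 6L), row.names = FALSE)
  if (nrow(x) > 6L) cat(sprintf("... %d more weeks\n", nrow(x) - 6L))
  invisible(x)
}

ws_label <- function(x) {
  lb <- attr(x, "label")
  if (is.null(lb)) "series" else lb
}

weekday_num <- function(d) as.POSIXlt(as.Date(d))$wday

#' Sunday starting the week of a date
#'
#' Maps any calendar date to the Sunday on or before it, the anchor used to
#' label weeks throughout the package.
#'
#' @param date a `Date` vector (or anything `as.Date` understands).
#' @return `Date` vector of Sundays.
#' @examples
#' week_start(as.Date("2006-01-25"))  # Wednesday -> 2006-01-22
#' @export
week_start <- function(date) {
  d <- as.Date(date)
  d - weekday_num(d)
}

#' Sequence of consecutive week-start Sundays
#'
#' @param from,to dates; both are snapped to their week's Sunday.
#' @return `Date` vector of Sundays from `week_start(from)` to
#'   `week_start(to)` inclusive.
#' @export
week_seq <- function(from, to) {
  a <- week_start(from)
  b <- week_start(to)
  if (b < a) stop("'to' precedes 'from'")
  seq(a, b, by = 7L)
}

#' Restrict a weekly series to a date window
#'
#' @param series a [weekly_series()].
#' @param from,to inclusive date bounds (snapped to Sundays); `NULL` keeps
#'   the corresponding end.
#' @return the restricted `weekly_series`.
#' @export
window_weeks <- function(series, from = NULL, to = NULL) {
  keep <- rep(TRUE, nrow(series))
  if (!is.null(from)) keep <- keep & series$week_start >= week_start(from)
  if (!is.null(to))   keep <- keep & series$week_start <= week_start(to)
  if (!any(keep)) stop("window contains no weeks of the series")
  weekly_series(series$week_start[keep], series$value[keep],
                label = ws_label(series))
}

#' Align two weekly series on their common weeks
#'
#' @param a,b [weekly_series()] objects.
#' @return list with elements `a` and `b`, both restricted to the shared
#'   (necessarily contiguous) week range.
#' @export
align_weeks <- function(a, b) {
  from <- max(a$week_start[1L], b$week_start[1L])
  to <- min(a$week_start[nrow(a)], b$week_start[nrow(b)])
  if (to < from) stop("series share no weeks")
  list(a = window_weeks(a, from, to), b = window_weeks(b, from, to))
}

ws_values <- function(x) {
  if (inherits(x, "weekly_series")) x$value else as.numeric(x)
}
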