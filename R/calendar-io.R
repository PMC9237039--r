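#' Fixed 365-day calendar helpers
#'
#' The package works on a fixed 365-day calendar: every year has DOY 1-365
#' and leap days (Feb 29) are dropped when real dates are ingested. These
#' helpers convert between (year, doy) pairs and calendar `Date`s under
#' that convention.
#'
#' @param year integer calendar year(s).
#' @param doy integer day-of-year in 1-365 on the fixed calendar.
#' @return `doy_to_date()` returns a `Date`; `date_to_doy()` returns a
#'   data.frame with columns `year` and `doy` (`NA` for Feb 29).
#' @examples
#' doy_to_date(2001, 60)          # "2001-03-01"
#' doy_to_date(2000, 60)          # also March 1: Feb 29 is skipped
#' date_to_doy(as.Date("2000-03-01"))
#' @export
doy_to_date <- function(year, doy) {
  stopifnot(all(doy >= 1L & doy <= DAYS_PER_YEAR))
  d <- as.Date(paste0(year, "-01-01")) + (doy - 1L)
  # in leap years, dates on/after Mar 1 (doy >= 60 in the 365-day count)
  # must skip Feb 29
  leap <- is_leap(year)
  d[leap & doy >= 60L] <- d[leap & doy >= 60L] + 1L
  d
}

#' @param date a `Date` vector.
#' @rdname doy_to_date
#' @export
date_to_doy <- function(date) {
  date <- as.Date(date)
  year <- as.integer(format(date, "%Y"))
  doy <- as.integer(format(date, "%j"))
  leap <- is_leap(year)
  feb29 <- leap & doy == 60L
  doy[leap & doy > 60L] <- doy[leap & doy > 60L] - 1L
  doy[feb29] <- NA_integer_
  data.frame(year = year, doy = doy)
}

is_leap <- function(year) {
  (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
}

#' Construct a daily series table
#'
#' The package's working representation of one site's time series of a
#' single variable: a data.frame with columns `site_id`, `year`, `doy`,
#' `value`, one row per (year, doy) on the fixed 365-day calendar.
#'
#' @param site_id site identifier (scalar character).
#' @param year,doy,value parallel vectors.
#' @return a `daily_series` data.frame.
#' @export
daily_series <- function(site_id, year, doy, value) {
  if (length(year) == 1L) year <- rep(year, length(doy))
  stopifnot(length(year) == length(doy), length(doy) == length(value))
  out <- data.frame(site_id = site_id, year = as.integer(year),
                    doy = as.integer(doy), value = as.numeric(value))
  class(out) <- c("daily_series", "data.frame")
  out
}

#' Read and write daily series in the long CSV layout
#'
#' The on-disk interchange layout is a long CSV with columns
#' `site_id, date, variable, value` and ISO-8601 dates. On read, leap days
#' are dropped and dates converted to (year, doy) on the 365-day calendar.
#'
#' @param path CSV file path.
#' @param variable which variable to extract (`NULL` = all, keeping the
#'   `variable` column).
#' @return a data.frame with columns `site_id`, `year`, `doy`, `value`
#'   (plus `variable` when `variable = NULL`).
#' @export
read_daily_series <- function(path, variable = NULL) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("site_id", "date", "variable", "value") %in% names(x)))
  if (!is.null(variable)) x <- x[x$variable %in% variable, , drop = FALSE]
  yd <- date_to_doy(as.Date(x$date))
  x$year <- yd$year
  x$doy <- yd$doy
  x <- x[!is.na(x$doy), , drop = FALSE]  # drop Feb 29
  keep <- c("site_id", if (is.null(variable)) "variable", "year", "doy", "value")
  x[, keep, drop = FALSE]
}

#' @param series a data.frame with columns `site_id`, `year`, `doy`,
#'   `value` (and optionally `variable`).
#' @param variable_name label written to the `variable` column when the
#'   input has none.
#' @rdname read_daily_series
#' @export
write_daily_series <- function(series, path, variable_name = "value") {
  v <- if ("variable" %in% names(series)) series$variable else variable_name
  out <- data.frame(site_id = series$site_id,
                    date = format(doy_to_date(series$year, series$doy)),
                    variable = v,
                    value = series$value)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# subset one year of a series as a plain (doy, value) frame, ordered
year_slice <- function(series, year) {
  s <- series[series$year == year, , drop = FALSE]
  s[order(s$doy), , drop = FALSE]
}
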