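# Simulation calendar.
#
# The clock counts days from 1 January 2015 (day index 0) on a 365-day
# calendar: month lengths are Gregorian but no 29 February ever occurs, so
# every year is identical.  Simulations default to 5475 days = 15 years,
# ending 31 December 2029.

MONTH_LENGTHS <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
MONTH_STARTS <- c(0L, cumsum(MONTH_LENGTHS))  # year-day before each month

#' Day of the year
#'
#' @param day_index Integer vector of day indices (0 = 1 Jan 2015).
#' @return Integer vector in 1..365.
#' @export
day_of_year <- function(day_index) {
  if (any(day_index < 0)) stop("day_index must be >= 0")
  (as.integer(day_index) %% 365L) + 1L
}

#' Calendar date of a day index
#'
#' @param day_index Integer vector.
#' @return data.frame with columns year, month, day, year_day.
#' @export
calendar_date <- function(day_index) {
  yd <- day_of_year(day_index)
  month <- findInterval(yd - 1L, MONTH_STARTS[-13L])
  data.frame(year = 2015L + as.integer(day_index) %/% 365L,
             month = month,
             day = yd - MONTH_STARTS[month],
             year_day = yd)
}

#' Day index of a calendar date
#'
#' @param year,month,day Integer scalars (no-leap calendar).
#' @return Integer day index (0 = 1 Jan 2015).
#' @export
day_index_of <- function(year, month, day) {
  (year - 2015L) * 365L + MONTH_STARTS[month] + day - 1L
}

is_month_first_day <- function(yd) yd %in% (MONTH_STARTS[1:12] + 1L)
is_month_last_day <- function(yd) yd %in% MONTH_STARTS[2:13]

# 1 Jan 2015 was a Thursday; Sundays are meat-purchase days.
is_sunday <- function(day_index) (day_index %% 7L) == 3L

#' Default festival calendar
#'
#' The village celebrates 23 festival days a year.  Their identities are a
#' documented, configurable fixture: the count and the per-day cost are what
#' matter to the dynamics.  The default list spans the major festivals of the
#' Nepali year (Maghe Sankranti through Dashain and Tihar).
#'
#' @return Sorted integer vector of 23 year-days.
#' @export
default_festival_days <- function() {
  sort(c(15L, 35L, 48L, 75L, 95L, 104L, 124L, 228L, 229L, 236L, 250L, 260L,
         285L, 286L, 287L, 288L, 289L, 306L, 307L, 308L, 309L, 310L, 315L))
}
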