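## Calendar arithmetic is done on integer day offsets from a fixed study
## epoch. Months are a fixed 30.4375-day divisor so that "months" summaries
## are reproducible from daily claims.

#' Average days per calendar month used for month-denominated summaries
#'
#' A fixed divisor (365.25 / 12) converting day counts to months, so that
#' per-patient-per-month statistics are reproducible from day-level claims.
#' @export
DAYS_PER_MONTH <- 365.25 / 12

#' Default study epoch (day 0)
#'
#' All integer day offsets in the package are relative to this date, the
#' start of the member-identification window.
#' @export
PAHLOT_EPOCH <- as.Date("2015-10-01")

#' Convert calendar dates to integer day offsets
#'
#' @param x a `Date` vector (or character coercible to `Date`).
#' @param epoch the day-0 reference date.
#' @return integer vector of day offsets (negative for dates before the
#'   epoch).
#' @export
#' @examples
#' date_to_day(as.Date("2015-10-31"))
date_to_day <- function(x, epoch = PAHLOT_EPOCH) {
  as.integer(as.Date(x) - as.Date(epoch))
}

#' Convert integer day offsets back to calendar dates
#'
#' @param day integer day offsets.
#' @inheritParams date_to_day
#' @return a `Date` vector.
#' @export
day_to_date <- function(day, epoch = PAHLOT_EPOCH) {
  as.Date(epoch) + as.integer(day)
}

#' Calendar year of a day offset
#'
#' Used to pick the inflation multiplier for a claim.
#' @inheritParams day_to_date
#' @return integer calendar years.
#' @export
day_to_year <- function(day, epoch = PAHLOT_EPOCH) {
  as.integer(format(day_to_date(day, epoch), "%Y"))
}

#' Convert a day count to months
#'
#' @param days numeric day counts.
#' @return `days / 30.4375`.
#' @export
days_to_months <- function(days) {
  days / DAYS_PER_MONTH
}
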