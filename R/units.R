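#' @keywords internal
"_PACKAGE"

# Model clock constants. The engine runs on a weekly grid; calendar
# conversions use the average Gregorian year (365.25 days).
WEEKS_PER_YEAR <- 365.25 / 7     # 52.17857...
WEEKS_PER_MONTH <- 4.348125      # 1/12 of a 365.2425-day Gregorian year

#' Convert months to weeks
#'
#' Durations are held internally in weeks (the cycle clock). Medians
#' reported in months are converted with 1 month = 4.348125 weeks (one
#' twelfth of the 365.2425-day Gregorian calendar year).
#'
#' @param x numeric vector of durations in months.
#' @return durations in weeks.
#' @export
#' @examples
#' months_to_weeks(12)  # one year, 52.17857 weeks
months_to_weeks <- function(x) x * WEEKS_PER_MONTH

#' Convert years to weeks
#' @param x numeric vector of durations in years.
#' @return durations in weeks.
#' @export
years_to_weeks <- function(x) x * WEEKS_PER_YEAR

#' Convert weeks to years
#' @param x numeric vector of durations in weeks.
#' @return durations in years.
#' @export
weeks_to_years <- function(x) x / WEEKS_PER_YEAR
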