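#' Time-unit conversions
#'
#' All internal computation in adtimesave is carried out in years; trial
#' summaries arrive on a study clock in weeks and some published delays are
#' quoted in months. These helpers fix the conversion constants used
#' throughout the package: 1 year = 52.1786 weeks = 12 months.
#'
#' @param weeks,months,years Numeric vectors of durations.
#' @return A numeric vector in the target unit.
#' @examples
#' weeks_to_years(52.1786)
#' years_to_months(1.5)
#' @name units
NULL

WEEKS_PER_YEAR <- 52.1786
MONTHS_PER_YEAR <- 12

#' @rdname units
#' @export
weeks_to_years <- function(weeks) weeks / WEEKS_PER_YEAR

#' @rdname units
#' @export
years_to_weeks <- function(years) years * WEEKS_PER_YEAR

#' @rdname units
#' @export
months_to_years <- function(months) months / MONTHS_PER_YEAR

#' @rdname units
#' @export
years_to_months <- function(years) years * MONTHS_PER_YEAR
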