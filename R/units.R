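# Unit conversions used throughout the package.  All model arithmetic is
# done in femtograms of carbon, millilitres (treated as identical to cm^3)
# and days; user-facing timespans are years.

#: molar mass of carbon, g mol^-1
.CARBON_MOLAR_MASS <- 12.011

#' Convert micrograms to femtograms
#'
#' Exact decimal scaling (1 ug = 1e9 fg); the single place where the
#' microgram-to-femtogram step happens so that unit audits are local.
#'
#' @param x quantity in micrograms.
#' @return quantity in femtograms.
#' @export
ugToFg <- function(x) x * 1e9

#' Convert grams to femtograms
#' @param x quantity in grams.
#' @return quantity in femtograms.
#' @export
gToFg <- function(x) x * 1e15

#' Convert years to days and back
#'
#' @param x time in years (`yearsToDays`) or days (`daysToYears`).
#' @param days_per_year calendar convention; the default 365.25 reproduces
#'   all published three-significant-figure results (365 does as well).
#' @return converted time.
#' @export
yearsToDays <- function(x, days_per_year = 365.25) x * days_per_year

#' @rdname yearsToDays
#' @export
daysToYears <- function(x, days_per_year = 365.25) x / days_per_year
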