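#' Money amounts, currency conversion and inflation adjustment
#'
#' Cost ledgers collected alongside a trial typically mix currencies and
#' expenditure years. The costing convention implemented here is the standard
#' one for ingredients-based costing in low-income settings: convert each
#' amount to the base currency at the expenditure year's annual-average
#' exchange rate, then inflate to base-year prices with a consumer price
#' index. The pipeline always converts first and inflates second; tests pin
#' this order because the two operations do not commute.
#'
#' @name money
NULL

MONEY_YEAR_MIN <- 2000L
MONEY_YEAR_MAX <- 2030L

#' Create a money amount
#'
#' @param value non-negative amount in `currency` units.
#' @param currency ISO-4217 currency code, e.g. `"USD"`, `"UGX"`.
#' @param year calendar year of expenditure (2000-2030).
#' @return an object of class `money`.
#' @export
#' @examples
#' money(5550, "UGX", 2013)
money <- function(value, currency, year) {
  assert_scalar_number(value, "value", min = 0)
  if (!is.character(currency) || length(currency) != 1L || !nzchar(currency)) {
    stop_cea("`currency` must be a single ISO-4217 code")
  }
  assert_scalar_number(year, "year", min = MONEY_YEAR_MIN, max = MONEY_YEAR_MAX)
  structure(
    list(value = as.numeric(value), currency = toupper(currency), year = as.integer(year)),
    class = "money"
  )
}

#' @export
format.money <- function(x, ...) {
  sprintf("%s %.2f (%d)", x$currency, x$value, x$year)
}

#' @export
print.money <- function(x, ...) {
  cat("<money>", format(x), "\n")
  invisible(x)
}

#' Convert a money amount to the base currency
#'
#' Rates are quoted as local-currency units per unit of base currency for a
#' given year (e.g. UGX per USD), matching how central banks publish
#' annual-average rates. Conversion divides by the rate and preserves the
#' expenditure year.
#'
#' @param amount a [money] object.
#' @param rate_table named list: `rate_table[[currency]][[as.character(year)]]`
#'   gives units of `currency` per unit of `base_currency`.
#' @param base_currency ISO-4217 code of the analysis currency.
#' @return a [money] object in `base_currency`, same year.
#' @export
#' @examples
#' rt <- list(UGX = c("2013" = 3700))
#' convert_currency(money(5550, "UGX", 2013), rt, "USD") # 1.50 USD
convert_currency <- function(amount, rate_table, base_currency) {
  stopifnot(inherits(amount, "money"))
  base_currency <- toupper(base_currency)
  if (amount$currency == base_currency) {
    return(amount)
  }
  rate <- lookup_year(rate_table[[amount$currency]], amount$year)
  if (is.null(rate) || is.na(rate)) {
    stop_cea("unknown exchange rate for %s in %d", amount$currency, amount$year,
             class = "trialcea_missing_rate")
  }
  money(amount$value / rate, base_currency, amount$year)
}

#' Inflate a base-currency amount to base-year prices
#'
#' Scales by `cpi[base_year] / cpi[year]` and relabels the year. The CPI
#' series must be the one for the base currency's economy (the conversion
#' happens before inflation, so the amount is already in base currency).
#'
#' @param amount a [money] object already in base currency.
#' @param cpi_table named numeric vector or list, indexed by year as character.
#' @param base_year target price year.
#' @return a [money] object at `base_year` prices.
#' @export
#' @examples
#' inflate_to_base_year(money(250, "USD", 2010), c("2010" = 92, "2015" = 115), 2015)
inflate_to_base_year <- function(amount, cpi_table, base_year) {
  stopifnot(inherits(amount, "money"))
  assert_scalar_number(base_year, "base_year", MONEY_YEAR_MIN, MONEY_YEAR_MAX)
  if (amount$year == base_year) {
    return(amount)
  }
  cpi_from <- lookup_year(cpi_table, amount$year)
  cpi_to <- lookup_year(cpi_table, base_year)
  if (is.null(cpi_from) || is.na(cpi_from)) {
    stop_cea("no CPI entry for year %d", amount$year, class = "trialcea_missing_cpi")
  }
  if (is.null(cpi_to) || is.na(cpi_to)) {
    stop_cea("no CPI entry for base year %d", as.integer(base_year),
             class = "trialcea_missing_cpi")
  }
  money(amount$value * cpi_to / cpi_from, amount$currency, base_year)
}
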