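#' Capital annualisation: annuity factors and equivalent annual cost
#'
#' One-off investments (programme development, office equipment) are spread
#' over their useful life as a constant annual charge. With principal P,
#' useful life n years, discount rate r and end-of-life resale value S, the
#' equivalent annual cost is
#'
#'   EAC = (P - S (1+r)^-n) / A(r, n),   A(r, n) = sum_{t=1..n} (1+r)^-t.
#'
#' When the resale value equals the full principal (S = P) this reduces
#' analytically to EAC = P r: only the opportunity cost of tying up the
#' capital is charged. That identity is exercised heavily in the tests.
#'
#' @name capital
NULL

#' Present-value-of-annuity factor
#'
#' @param rate annual effective discount rate, `>= 0`.
#' @param n useful life in whole years, `>= 1`.
#' @return `sum((1 + rate)^-(1:n))`; equals `n` when `rate = 0`.
#' @export
#' @examples
#' annuity_factor(0.0926, 7) # about 4.99
annuity_factor <- function(rate, n) {
  assert_scalar_number(rate, "rate", min = 0)
  assert_scalar_number(n, "n", min = 1)
  if (n != floor(n)) stop_cea("`n` must be a whole number of years (got %g)", n)
  if (rate == 0) {
    return(as.numeric(n))
  }
  (1 - (1 + rate)^(-n)) / rate
}

#' Create a capital asset
#'
#' @param label free-text description.
#' @param principal a [money] object: the original investment.
#' @param useful_life_years whole years of useful life, `>= 1`.
#' @param resale_fraction fraction of the principal recovered at end of life;
#'   usually in `[0, 1]`, values above 1 are permitted only so sensitivity
#'   sweeps can scale a full-resale assumption upwards.
#' @param discount_rate annual effective discount rate, `>= 0`.
#' @param phase,category ledger classification used when the asset's annual
#'   charge enters cost aggregation.
#' @param allocation_fraction share of the asset attributable to the
#'   intervention, in `[0, 1]`.
#' @return an object of class `capital_asset`.
#' @export
capital_asset <- function(label, principal, useful_life_years, resale_fraction,
                          discount_rate, phase = "development",
                          category = "capital", allocation_fraction = 1) {
  stopifnot(inherits(principal, "money"))
  assert_scalar_number(useful_life_years, "useful_life_years", min = 1)
  if (useful_life_years != floor(useful_life_years)) {
    stop_cea("`useful_life_years` must be a whole number (got %g)", useful_life_years)
  }
  assert_scalar_number(resale_fraction, "resale_fraction", min = 0)
  assert_scalar_number(discount_rate, "discount_rate", min = 0)
  assert_choice(phase, "phase", LEDGER_PHASES)
  assert_choice(category, "category", LEDGER_CATEGORIES)
  assert_scalar_number(allocation_fraction, "allocation_fraction", min = 0, max = 1)
  structure(
    list(
      label = as.character(label),
      principal = principal,
      useful_life_years = as.integer(useful_life_years),
      resale_fraction = as.numeric(resale_fraction),
      discount_rate = as.numeric(discount_rate),
      phase = phase,
      category = category,
      allocation_fraction = as.numeric(allocation_fraction)
    ),
    class = "capital_asset"
  )
}

#' Equivalent annual cost of a capital asset
#'
#' @param asset a [capital_asset] whose principal is already expressed in
#'   base-year base-currency terms.
#' @return annual charge in base-currency units per year.
#' @export
#' @examples
#' a <- capital_asset("toolkit", money(446940, "USD", 2015), 7, 1, 0.0926)
#' equivalent_annual_cost(a) # 446940 * 0.0926 = 41386.64
equivalent_annual_cost <- function(asset) {
  stopifnot(inherits(asset, "capital_asset"))
  eac_value(asset$principal$value, asset$resale_fraction,
            asset$discount_rate, asset$useful_life_years)
}

# Scalar EAC kernel; exported for direct numeric use in sensitivity sweeps.
#' @rdname equivalent_annual_cost
#' @param principal_value,resale_fraction,rate,n scalar inputs to the EAC
#'   formula, for use without constructing a `capital_asset`.
#' @export
eac_value <- function(principal_value, resale_fraction, rate, n) {
  assert_scalar_number(principal_value, "principal_value", min = 0)
  salvage <- resale_fraction * principal_value
  (principal_value - salvage * (1 + rate)^(-n)) / annuity_factor(rate, n)
}
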