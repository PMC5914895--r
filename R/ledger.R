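#' Cost ledgers: line items, loading, allocation and aggregation
#'
#' A cost ledger is the ingredients-based record of everything the provider
#' spent to develop, set up and run the programme: recurrent line items
#' (staff time, materials, transport, overheads) plus capital assets that are
#' annualised over their useful life. Every line carries a phase, a category,
#' a financial/economic flag and an allocation fraction (the share of the
#' resource attributable to the intervention, for resources shared with other
#' activities).
#'
#' @name ledger
NULL

#' Closed vocabularies for ledger classification
#' @export
LEDGER_PHASES <- c("development", "start_up", "implementation", "monitoring_evaluation")

#' @rdname LEDGER_PHASES
#' @export
LEDGER_CATEGORIES <- c("staff", "capital", "recurrent")

#' @rdname LEDGER_PHASES
#' @export
COST_BASES <- c("financial", "economic")

#' Create a cost line item
#'
#' @param label free-text description.
#' @param phase one of [LEDGER_PHASES].
#' @param category one of [LEDGER_CATEGORIES].
#' @param cost_basis `"financial"` (actual expenditure) or `"economic"`
#'   (includes opportunity/donated costs).
#' @param amount a [money] object.
#' @param allocation_fraction share attributable to the intervention, `[0, 1]`.
#' @return an object of class `cost_item`.
#' @export
cost_item <- function(label, phase, category, cost_basis, amount,
                      allocation_fraction = 1) {
  assert_choice(phase, "phase", LEDGER_PHASES)
  assert_choice(category, "category", LEDGER_CATEGORIES)
  assert_choice(cost_basis, "cost_basis", COST_BASES)
  stopifnot(inherits(amount, "money"))
  assert_scalar_number(allocation_fraction, "allocation_fraction", min = 0, max = 1)
  structure(
    list(
      label = as.character(label), phase = phase, category = category,
      cost_basis = cost_basis, amount = amount,
      allocation_fraction = as.numeric(allocation_fraction)
    ),
    class = "cost_item"
  )
}

#' Allocated value of a converted, inflated item
#'
#' @param item a [cost_item] whose amount is already in base-year,
#'   base-currency terms.
#' @return `amount$value * allocation_fraction`.
#' @export
allocate <- function(item) {
  stopifnot(inherits(item, "cost_item"))
  item$amount$value * item$allocation_fraction
}

#' Create a cost ledger
#'
#' @param items list of [cost_item].
#' @param capital_assets list of [capital_asset].
#' @param base_year price year of the analysis.
#' @param base_currency ISO-4217 code of the analysis currency.
#' @param horizon_years analysis horizon in years (1.5 for an 18-month trial);
#'   annualised capital charges are multiplied by this before aggregation.
#' @return an object of class `cost_ledger`.
#' @export
cost_ledger <- function(items, capital_assets = list(), base_year,
                        base_currency, horizon_years) {
  stopifnot(is.list(items), is.list(capital_assets))
  for (it in items) stopifnot(inherits(it, "cost_item"))
  for (ca in capital_assets) stopifnot(inherits(ca, "capital_asset"))
  assert_scalar_number(base_year, "base_year", MONEY_YEAR_MIN, MONEY_YEAR_MAX)
  assert_scalar_number(horizon_years, "horizon_years")
  if (horizon_years <= 0) stop_cea("`horizon_years` must be positive")
  structure(
    list(
      items = items, capital_assets = capital_assets,
      base_year = as.integer(base_year),
      base_currency = toupper(base_currency),
      horizon_years = as.numeric(horizon_years)
    ),
    class = "cost_ledger"
  )
}

#' Read an analysis configuration from JSON
#'
#' Expected keys: `base_year`, `base_currency`, `discount_rate`,
#' `horizon_years`, `exchange_rates` (currency -> year -> units per base),
#' `cpi` (year -> index), and optionally `denominators` (label -> count).
#' Rate and CPI tables are user-supplied, not bundled constants: published
#' evaluations rarely print the series they used, so they are part of the
#' stated configuration of each analysis.
#'
#' @param path path to a JSON file.
#' @return a named list with validated fields.
#' @export
read_analysis_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("base_year", "base_currency", "discount_rate", "horizon_years")
  missing <- setdiff(required, names(cfg))
  if (length(missing)) {
    stop_cea("config is missing required keys: %s", paste(missing, collapse = ", "))
  }
  assert_scalar_number(cfg$base_year, "base_year", MONEY_YEAR_MIN, MONEY_YEAR_MAX)
  assert_scalar_number(cfg$discount_rate, "discount_rate", min = 0)
  assert_scalar_number(cfg$horizon_years, "horizon_years")
  cfg$exchange_rates <- cfg$exchange_rates %||% list()
  cfg$cpi <- cfg$cpi %||% list()
  cfg
}

#' Read a cost ledger from CSV
#'
#' Required columns: `label, phase, category, cost_basis, value, currency,
#' year, allocation_fraction, is_capital, useful_life_years, resale_fraction`
#' (UTF-8, header required). Rows with `is_capital` true become capital
#' assets discounted at `config$discount_rate`; degenerate rows (zero or
#' missing value, missing category) are rejected with row-numbered errors
#' rather than silently dropped.
#'
#' @param path path to the ledger CSV.
#' @param config a list as returned by [read_analysis_config()].
#' @return a [cost_ledger].
#' @export
read_cost_ledger <- function(path, config) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  required <- c("label", "phase", "category", "cost_basis", "value", "currency",
                "year", "allocation_fraction", "is_capital")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_cea("ledger CSV is missing columns: %s", paste(missing, collapse = ", "))
  }
  items <- list()
  assets <- list()
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    if (is.na(row$value) || row$value <= 0) {
      stop_cea("ledger row %d (%s): value must be a positive number", i, row$label)
    }
    if (is.na(row$category) || !nzchar(row$category)) {
      stop_cea("ledger row %d (%s): missing category", i, row$label)
    }
    amt <- tryCatch(
      money(row$value, row$currency, row$year),
      error = function(e) stop_cea("ledger row %d (%s): %s", i, row$label, conditionMessage(e))
    )
    is_cap <- isTRUE(row$is_capital) || identical(tolower(as.character(row$is_capital)), "true") ||
      identical(as.character(row$is_capital), "1")
    if (is_cap) {
      assets[[length(assets) + 1L]] <- tryCatch(
        capital_asset(
          label = row$label, principal = amt,
          useful_life_years = row$useful_life_years,
          resale_fraction = row$resale_fraction,
          discount_rate = config$discount_rate,
          phase = row$phase, category = row$category,
          allocation_fraction = row$allocation_fraction
        ),
        error = function(e) stop_cea("ledger row %d (%s): %s", i, row$label, conditionMessage(e))
      )
    } else {
      items[[length(items) + 1L]] <- tryCatch(
        cost_item(row$label, row$phase, row$category, row$cost_basis, amt,
                  row$allocation_fraction),
        error = function(e) stop_cea("ledger row %d (%s): %s", i, row$label, conditionMessage(e))
      )
    }
  }
  cost_ledger(items, assets, config$base_year, config$base_currency,
              config$horizon_years)
}

#' Resolve a ledger to base-year base-currency line values
#'
#' Applies, in this fixed order: currency conversion at the expenditure
#' year's rate, CPI inflation to the base year, allocation by proportion of
#' use. Capital assets are annualised (equivalent annual cost) and charged
#' for `horizon_years`, then allocated.
#'
#' @param ledger a [cost_ledger].
#' @param exchange_rates rate table as in [convert_currency()].
#' @param cpi CPI table as in [inflate_to_base_year()].
#' @return data.frame with columns `label, phase, category, source, value`.
#' @export
resolve_ledger <- function(ledger, exchange_rates, cpi) {
  stopifnot(inherits(ledger, "cost_ledger"))
  n_lines <- length(ledger$items) + length(ledger$capital_assets)
  if (n_lines == 0L) {
    return(data.frame(label = character(), phase = character(),
                      category = character(), source = character(),
                      value = numeric(), stringsAsFactors = FALSE))
  }
  rows <- vector("list", n_lines)
  k <- 0L
  for (it in ledger$items) {
    conv <- convert_currency(it$amount, exchange_rates, ledger$base_currency)
    infl <- inflate_to_base_year(conv, cpi, ledger$base_year)
    resolved <- it
    resolved$amount <- infl
    k <- k + 1L
    rows[[k]] <- data.frame(
      label = it$label, phase = it$phase, category = it$category,
      source = "item", value = allocate(resolved), stringsAsFactors = FALSE
    )
  }
  for (ca in ledger$capital_assets) {
    conv <- convert_currency(ca$principal, exchange_rates, ledger$base_currency)
    infl <- inflate_to_base_year(conv, cpi, ledger$base_year)
    asset <- ca
    asset$principal <- infl
    annual <- equivalent_annual_cost(asset)
    k <- k + 1L
    rows[[k]] <- data.frame(
      label = ca$label, phase = ca$phase, category = ca$category,
      source = "capital_asset",
      value = annual * ledger$horizon_years * ca$allocation_fraction,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Aggregate a ledger by phase or category
#'
#' @param ledger a [cost_ledger].
#' @param exchange_rates,cpi tables passed to [resolve_ledger()].
#' @param group_by `"phase"` or `"category"`.
#' @param include_me include `monitoring_evaluation` lines? Published cost
#'   tables are conventionally reported excluding M&E, which exists only
#'   because of the trial.
#' @return data.frame `group, total, percent` with attribute `grand_total`;
#'   percents are of the selected scope's grand total, rounded half-up to
#'   integers for reporting.
#' @export
aggregate_costs <- function(ledger, exchange_rates, cpi,
                            group_by = c("phase", "category"),
                            include_me = FALSE) {
  group_by <- match.arg(group_by)
  resolved <- resolve_ledger(ledger, exchange_rates, cpi)
  if (is.null(resolved) || nrow(resolved) == 0L) {
    stop_cea("cannot aggregate an empty ledger")
  }
  if (!include_me) {
    resolved <- resolved[resolved$phase != "monitoring_evaluation", , drop = FALSE]
    if (nrow(resolved) == 0L) stop_cea("ledger contains only monitoring_evaluation lines")
  }
  grand <- sum(resolved$value)
  totals <- tapply(resolved$value, resolved[[group_by]], sum)
  levels <- if (group_by == "phase") LEDGER_PHASES else LEDGER_CATEGORIES
  present <- levels[levels %in% names(totals)]
  out <- data.frame(
    group = present,
    total = as.numeric(totals[present]),
    percent = round_half_up(100 * as.numeric(totals[present]) / grand),
    stringsAsFactors = FALSE
  )
  attr(out, "grand_total") <- grand
  out
}

#' Unit cost
#'
#' @param total cost in base-currency units.
#' @param denominator positive count (schools, pupils, ...).
#' @param label optional label attached to the result.
#' @return `total / denominator`, with attributes `label` and `reported`
#'   (half-up rounded to the whole currency unit).
#' @export
#' @examples
#' unit_cost(157343, 21, "per school per year") # 7492.52..., reported 7493
unit_cost <- function(total, denominator, label = NULL) {
  assert_scalar_number(total, "total", min = 0)
  assert_scalar_number(denominator, "denominator")
  if (denominator <= 0) stop_cea("`denominator` must be positive (got %g)", denominator)
  out <- total / denominator
  attr(out, "label") <- label
  attr(out, "reported") <- round_half_up(as.numeric(out))
  out
}
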