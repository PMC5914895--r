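#' Cost-effectiveness ratios and univariate sensitivity analysis
#'
#' The comparator throughout is "do nothing": zero incremental cost, zero
#' cases averted. The cost-effectiveness ratio is therefore a simple
#' quotient, programme cost divided by cases averted, not a full incremental
#' table. Sensitivity analysis re-runs the whole cost-to-effect pipeline
#' with exactly one parameter perturbed, so interactions with capital
#' annualisation are honoured rather than approximated by scaling outputs.
#'
#' @name cea
NULL

#' Cost per case averted against a do-nothing comparator
#'
#' @param total_cost programme cost over the analysis horizon.
#' @param annual_cost annual programme running cost.
#' @param counts a [counterfactual_cases()] result (or any list with
#'   `averted_cases`).
#' @param unit_costs optional named list of unit costs to carry along.
#' @return object of class `cea_result` with full-precision ratios and
#'   half-up rounded `*_reported` versions.
#' @export
#' @examples
#' cc <- counterfactual_cases(9000, 0.49, 0.31)
#' cost_effectiveness(397233, 157343, cc) # 245 and 97 per case (reported)
cost_effectiveness <- function(total_cost, annual_cost, counts,
                               unit_costs = list()) {
  assert_scalar_number(total_cost, "total_cost", min = 0)
  assert_scalar_number(annual_cost, "annual_cost", min = 0)
  averted <- counts$averted_cases
  if (is.null(averted) || !is.finite(averted) || averted <= 0) {
    stop_cea("not cost-effective vs do-nothing; ratio undefined (cases averted = %s)",
             format(averted), class = "trialcea_undefined_ratio")
  }
  structure(
    list(
      total_cost = total_cost,
      annual_cost = annual_cost,
      averted_cases = averted,
      cost_per_case_total = total_cost / averted,
      cost_per_case_annual = annual_cost / averted,
      cost_per_case_total_reported = round_half_up(total_cost / averted),
      cost_per_case_annual_reported = round_half_up(annual_cost / averted),
      unit_costs = unit_costs
    ),
    class = "cea_result"
  )
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("Total cost: %s   Annual cost: %s\n",
              format(round_half_up(x$total_cost), big.mark = ","),
              format(round_half_up(x$annual_cost), big.mark = ",")))
  cat(sprintf("Cases averted: %g\n", round_half_up(x$averted_cases)))
  cat(sprintf("Cost per case averted: %g (total), %g (annual)\n",
              x$cost_per_case_total_reported, x$cost_per_case_annual_reported))
  invisible(x)
}

#' Run the full cost-to-effect pipeline for one configuration
#'
#' The configuration is a plain list:
#' \describe{
#'   \item{ledger}{a [cost_ledger]}
#'   \item{exchange_rates, cpi}{rate tables for [resolve_ledger()]}
#'   \item{counts}{a [counterfactual_cases()] result, or instead
#'     `n_pupils` + `expected_prevalence` + `observed_prevalence`, or
#'     `n_pupils` + `observed_prevalence` + `effect` (an `effect_estimate`,
#'     from which the counterfactual prevalence is `observed + RD`)}
#'   \item{annual_cost}{optional override; the default convention divides the
#'     implementation-phase total by `horizon_years`}
#'   \item{denominators}{optional named list (e.g. `schools`, `pupils`) used
#'     for annual unit costs}
#'   \item{override_averted}{internal hook used by [tornado()] to set cases
#'     averted to a confidence bound}
#' }
#'
#' @param config list as described above.
#' @return a `cea_result` with `table_phase` / `table_category` attached as
#'   attributes.
#' @export
cea_pipeline <- function(config) {
  by_phase <- aggregate_costs(config$ledger, config$exchange_rates, config$cpi,
                              group_by = "phase",
                              include_me = isTRUE(config$include_me))
  by_category <- aggregate_costs(config$ledger, config$exchange_rates, config$cpi,
                                 group_by = "category",
                                 include_me = isTRUE(config$include_me))
  total_cost <- attr(by_phase, "grand_total")

  annual_cost <- config$annual_cost
  if (is.null(annual_cost)) {
    impl <- by_phase$total[by_phase$group == "implementation"]
    annual_cost <- if (length(impl)) impl / config$ledger$horizon_years else
      total_cost / config$ledger$horizon_years
  }

  counts <- config$counts
  if (is.null(counts)) {
    if (!is.null(config$effect)) {
      expected <- config$observed_prevalence + config$effect$risk_difference
    } else {
      expected <- config$expected_prevalence
    }
    counts <- counterfactual_cases(config$n_pupils, expected,
                                   config$observed_prevalence)
  }
  if (!is.null(config$override_averted)) {
    counts$averted_cases <- config$override_averted
    counts$averted_reported <- round_half_up(config$override_averted)
  }

  unit_costs <- list()
  for (nm in names(config$denominators %||% list())) {
    unit_costs[[paste0("annual_per_", nm)]] <-
      unit_cost(annual_cost, config$denominators[[nm]], paste0("annual per ", nm))
  }

  out <- cost_effectiveness(total_cost, annual_cost, counts, unit_costs)
  out$counts <- counts
  attr(out, "table_phase") <- by_phase
  attr(out, "table_category") <- by_category
  out
}

# Registry of perturbable parameters. Each entry rewrites one field of the
# pipeline configuration; `value` is a multiplier for the scale kinds and an
# absolute cases-averted figure for `cases_averted`. The dev_cost and
# resale_value sweeps act on the ledger's capital assets — all of them by
# default, or the subset named in `config$dev_asset_labels`.
tornado_parameters <- function() {
  targeted <- function(config, ca) {
    is.null(config$dev_asset_labels) || ca$label %in% config$dev_asset_labels
  }
  list(
    dev_cost = list(
      kind = "scale",
      apply = function(config, value) {
        config$ledger$capital_assets <- lapply(
          config$ledger$capital_assets,
          function(ca) {
            if (targeted(config, ca)) {
              ca$principal$value <- ca$principal$value * value
            }
            ca
          }
        )
        config
      }
    ),
    resale_value = list(
      kind = "scale",
      apply = function(config, value) {
        config$ledger$capital_assets <- lapply(
          config$ledger$capital_assets,
          function(ca) {
            if (targeted(config, ca)) {
              ca$resale_fraction <- ca$resale_fraction * value
            }
            ca
          }
        )
        config
      }
    ),
    cases_averted = list(
      kind = "absolute",
      apply = function(config, value) {
        config$override_averted <- value
        config
      }
    )
  )
}

#' Univariate (tornado) sensitivity analysis
#'
#' Each perturbation re-runs the entire pipeline with exactly one parameter
#' changed. Recognised parameters: `dev_cost` (scales development-phase
#' capital principal), `resale_value` (scales the development asset's resale
#' fraction), `cases_averted` (sets cases averted to an absolute value, e.g.
#' a confidence bound). For the scale parameters `low`/`high` are
#' multipliers (0.5 and 1.5 for a +/-50% sweep); for `cases_averted` they
#' are absolute counts.
#'
#' @param config pipeline configuration, as for [cea_pipeline()].
#' @param perturbations list of `list(parameter =, low =, high =)`.
#' @param result_kinds which results to tabulate per row.
#' @return data.frame of sensitivity rows (`parameter`, `perturbation`,
#'   `result_kind`, `low_result`, `base_result`, `high_result`) with the
#'   unperturbed `cea_result` attached as attribute `base`. Every row
#'   brackets the base case; a violation is an internal error.
#' @export
tornado <- function(config, perturbations,
                    result_kinds = c("total_cost", "cost_per_case")) {
  registry <- tornado_parameters()
  result_kinds <- match.arg(result_kinds, several.ok = TRUE)
  base <- cea_pipeline(config)
  extract <- function(res, kind) {
    switch(kind,
           total_cost = res$total_cost,
           cost_per_case = res$cost_per_case_total)
  }
  rows <- list()
  for (p in perturbations) {
    entry <- registry[[p$parameter]]
    if (is.null(entry)) {
      stop_cea("unknown sensitivity parameter %s; valid names: %s",
               sQuote(p$parameter), paste(names(registry), collapse = ", "))
    }
    res_low <- cea_pipeline(entry$apply(config, p$low))
    res_high <- cea_pipeline(entry$apply(config, p$high))
    for (kind in result_kinds) {
      lo <- extract(res_low, kind)
      hi <- extract(res_high, kind)
      ba <- extract(base, kind)
      if (!(min(lo, hi) <= ba && ba <= max(lo, hi))) {
        stop_cea("sensitivity row for %s does not bracket the base case (%g not in [%g, %g])",
                 p$parameter, ba, min(lo, hi), max(lo, hi))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = p$parameter,
        perturbation = sprintf(
          if (entry$kind == "scale") "x%g / x%g" else "%g to %g", p$low, p$high),
        result_kind = kind,
        low_result = lo, base_result = ba, high_result = hi,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(parameter = character(), perturbation = character(),
               result_kind = character(), low_result = numeric(),
               base_result = numeric(), high_result = numeric(),
               stringsAsFactors = FALSE)
  attr(out, "base") <- base
  out
}
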