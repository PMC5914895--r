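# trialcea

Trial-based economic evaluation for cluster-randomised public-health
interventions: ingredients-based costing with capital annualisation,
cluster-robust risk-difference estimation, cases-averted arithmetic,
cost-per-case ratios against a do-nothing comparator, and univariate
(tornado) sensitivity analysis.

The package is written for health economists and trial statisticians who
need to cost a programme delivered alongside a cluster-randomised trial and
turn the trial's effect estimate into a cost-effectiveness statement. It was
built around a published evaluation of a school violence-prevention
programme delivered in 21 intervention schools in Uganda over an 18-month
trial, and ships that analysis as a built-in, fully recomputed worked
example.

## The model

**Costing.** Every ledger line is converted to the base currency at the
expenditure year's annual-average exchange rate, inflated to base-year
prices with a CPI series, and allocated by proportion of use:

    value_base = (value / rate(currency, year)) * CPI(base) / CPI(year) * f_alloc

One-off investments are annualised as an equivalent annual cost over a
useful life of `n` years at discount rate `r`, with end-of-life resale `S`:

    EAC = (P - S (1+r)^-n) / A(r, n),   A(r, n) = (1 - (1+r)^-n) / r

With full resale (`S = P`) this collapses to `EAC = P r` — only the
opportunity cost of capital is charged. Annual charges are multiplied by the
analysis horizon (1.5 years for an 18-month trial) before aggregation.

**Effect.** The risk difference `RD = p_control - p_intervention` (positive
= protective) is estimated by an identity-link binomial GLM of the binary
outcome on arm (linear-probability fallback when identity-link ML leaves
[0,1]), with a CR1 cluster-robust sandwich variance over schools:

    V = (X'X)^-1 [ sum_g X_g' e_g e_g' X_g ] (X'X)^-1 * G/(G-1)

**Cost-effectiveness.** Cases averted among `n` intervention pupils are
`n * p_expected - n * p_observed`, where `p_expected = p_observed + RD` is
the counterfactual prevalence absent the intervention; cost per case averted
is programme cost divided by cases averted (do-nothing comparator: zero
cost, zero effect). The risk-difference CI gives bounds on cases averted,
and the tornado re-runs the entire pipeline perturbing one parameter at a
time (development cost, resale value, cases averted).

## Worked example

```r
library(trialcea)
b <- run_worked_example()
print(b)
```

```
Report bundle
  grand total: 397,233
  total_cost                   397,233
  annual_cost                  157,343
  expected_cases               4,410
  observed_cases               2,790
  cases_averted                1,620
  cost_per_case_total          245
  cost_per_case_annual         97
  annual_cost_per_school       7,493
  annual_cost_per_pupil        17
  dev_staff_share_pct          55
  teacher_time_cost_midpoint   2,185
  relative_reduction           0.37
```

Reading: setting up and running the programme for 18 months cost US$397,233
(2015 US$, provider perspective, excluding M&E). Among ~9,000 intervention
pupils, 49% would have reported past-week physical violence absent the
intervention (4,410 expected cases) versus 31% observed (2,790 cases), so
1,620 cases were averted — US$245 per case averted overall, or US$97 per
case on annual implementation cost (US$157,343/year, US$7,493 per school).
Every figure carries a provenance string (`b$headline$<name>$provenance`)
recording the arithmetic that produced it; `b$sensitivity` holds the
univariate sensitivity rows.

The generic entry points behind the example: `read_cost_ledger()` /
`aggregate_costs()` for costing, `fit_risk_difference()` /
`counterfactual_cases()` for effects, `cea_pipeline()` / `tornado()` for
ratios and sensitivity, `simulate_trial()` / `simulate_ledger()` for
synthetic data with known ground truth, and a CLI
(`inst/cli/cea.R`; subcommands `simulate`, `run`, `tornado`,
`worked-example`).

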