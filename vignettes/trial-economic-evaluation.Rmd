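---
title: "Methods: trial-based cost-effectiveness with cluster-robust effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trial-based cost-effectiveness with cluster-robust effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialcea)
```

## Scope and model

`trialcea` implements the standard pipeline for an economic evaluation run
alongside a cluster-randomised trial, from the provider's perspective:
ingredients-based costing, an adjusted risk difference on a binary outcome,
counterfactual cases averted, cost per case averted against a do-nothing
comparator, and univariate sensitivity analysis. The built-in worked example
is an 18-month trial of a school violence-prevention programme in 21
intervention schools in Uganda; all of its inputs are published constants
shipped in `extdata/worked_example.json`.

## Costing

Each ledger line carries a phase (`development`, `start_up`,
`implementation`, `monitoring_evaluation`), a category (`staff`, `capital`,
`recurrent`), a financial/economic flag, a money amount (value, currency,
expenditure year) and an allocation fraction in [0, 1] — the proportion of a
shared resource attributable to the intervention.

**Order of operations.** Amounts are converted to the base currency at the
expenditure year's annual-average rate *first*, then inflated to base-year
prices with the base economy's CPI, then allocated. Conversion and inflation
do not commute when exchange rates move relative to prices, so the order is
hard-coded and pinned by a test. Rate and CPI tables are user-supplied
configuration, not bundled constants: published evaluations rarely print the
series they used.

**Capital annualisation.** A one-off investment with principal $P$, useful
life $n$ years, discount rate $r$ and end-of-life resale $S$ is charged as
the equivalent annual cost

$$\mathrm{EAC} = \frac{P - S\,(1+r)^{-n}}{A(r,n)}, \qquad
A(r,n) = \sum_{t=1}^{n}(1+r)^{-t} = \frac{1-(1+r)^{-n}}{r},$$

the textbook convention in which paying the EAC for $n$ years and recovering
the salvage has the same present value as the principal. Two limits anchor
the tests: $r=0, S=0$ gives straight-line depreciation $P/n$, and $S=P$
gives $\mathrm{EAC}=Pr$ exactly, for any $n$. The source evaluation never
prints its annualisation formula; this convention is adopted because it
reproduces that evaluation's qualitative treatment (a development investment
with "resale value equal to the original investment" charged at principal
times rate) and is the field's default. Annual charges are multiplied by the
analysis horizon — 1.5 years for an 18-month implementation period — before
entering aggregation.

**Placement of the development charge.** The worked example's published cost
table reports only start-up and implementation phases, yet its sensitivity
table moves the grand total when development cost changes, so the
development charge (446{,}940 × 0.0926 × 1.5 ≈ 62{,}080) must sit inside
those margins. The source describes the development investment as "collected
as a start-up cost" and "treated as a capital item"; we therefore place it
in the start-up phase, capital category. The worked example carves that
charge out of the published margins and re-adds it as an explicit
`capital_asset`, so the published table reproduces exactly *and* the
sensitivity sweeps can perturb a real asset rather than scale an output.

**Reporting conventions.** Full precision is kept internally; reports round
money half-up to whole currency units and percents half-up to integers
(base R's `round()` rounds half to even, which disagrees with published
tables — 157{,}343/21 = 7{,}492.5 must report as 7{,}493). Degenerate
ledger rows (zero value, missing category) are rejected at load with
row-numbered errors rather than silently dropped.

**Annual cost convention (open design point).** The worked example's source
prints an "annual average" implementation cost (157{,}343) that is not
implementation total / 1.5 (= 186{,}189), presumably reflecting
calendar-year accounting it does not describe. The pipeline's default
convention is implementation-phase total divided by `horizon_years`; an
explicit `annual_cost` input overrides it, and the worked example supplies
the published figure as that input. Similarly, the published per-pupil cost
(US\$15) is not 157{,}343/9{,}000 (= 17.48); the pupil denominator behind it
is never stated, so the package reports the transparent quotient with its
provenance and does not target the printed value.

## Effect estimation

The estimand is the risk difference $RD = p_{\text{control}} -
p_{\text{intervention}}$, oriented so protective effects are positive. The
point estimate comes from an identity-link binomial GLM of outcome on arm
(plus covariates when requested, passed through as-is — no automatic
selection, since the source pre-specifies but does not list a covariate
procedure). Identity-link ML can fail when fitted probabilities leave
[0, 1]; the fit then falls back to an ordinary linear-probability model and
flags `fallback_lpm` in the output.

Variance uses a CR1 cluster-robust sandwich over schools,

$$\widehat V = (X'X)^{-1}\Big[\textstyle\sum_g X_g'e_g\,e_g'X_g\Big](X'X)^{-1}\cdot\frac{G}{G-1},$$

with response residuals $e$ and $G$ clusters. The OLS "bread" $(X'X)^{-1}$
is used for both fitting routes: it is the working-independence
estimating-equation sandwich, it makes the estimator identical to its
independent brute-force oracle in the tests, and in the arm-only design the
identity-link ML and OLS fits coincide anyway (both are the arm means). With
one record per cluster the estimator reduces to the ordinary HC-type robust
variance. Confidence bounds use a 1.96 normal multiplier (configurable; the
source's convention is unknown, and at 42 clusters a t-quantile would widen
bounds by ~4%).

Cases averted among $n$ intervention pupils are $n\,p_{\text{expected}} -
n\,p_{\text{observed}}$ with $p_{\text{expected}} = p_{\text{observed}} +
RD$; the CI bounds on $RD$ scale to bounds on cases averted. A negative
result (harm) warns rather than errors, but cost-per-case ratios are
*undefined* at zero or negative cases averted and raise a typed error — a
programme that averts nothing has no finite cost-effectiveness against
doing nothing. The descriptive `relative_reduction = averted/expected` is
clearly labelled as such: it is not the source trial's covariate-adjusted
42% relative risk reduction, which requires the real pupil-level data and is
out of scope.

## Sensitivity analysis

The tornado re-runs the *entire* pipeline with exactly one parameter
perturbed — development cost (scaled), resale fraction (scaled), or cases
averted (set to a CI bound) — rather than scaling outputs, so interactions
with annualisation are honoured. Every row must bracket the base case; a
violation is an internal error, and the invariant is property-tested on
random configurations. Running the machinery with an empty perturbation list
reproduces the base result bit-identically.

The worked example's source prints sensitivity bounds (total cost
366{,}945–435{,}816 for development ±50%; 332{,}509–696{,}808 for resale
±50%; 162–548 per case) that cannot be reproduced from any standard EAC
convention plus its printed inputs — they are asymmetric in ways a ±50%
univariate perturbation of the printed base cannot produce, and the
underlying unrounded intermediates are not published. The package reproduces
the *procedure* (its bounds: 366{,}193–428{,}273, 361{,}089–433{,}377,
163.5–551.7) and documents the discrepancy rather than tuning toward the
printed numbers.

## Synthetic data

`simulate_trial()` emulates the stated trial world: 21 clusters per arm,
430 pupils per cluster (9{,}000 intervention pupils / 21 schools), control
prevalence 0.49, protective risk difference 0.18, ICC 0.1. The source
reports neither per-school enrolment nor the outcome ICC; 430 and 0.1 are
fixture conventions — 0.1 is a typical school-level ICC for behavioural
outcomes — fixed once and not revisited. Clustering is beta-binomial:
cluster prevalences are Beta with mean equal to the arm prevalence and
$a+b = 1/\rho - 1$, chosen over logit-normal because mean and ICC are exact
in closed form, so desk-scale checks need no integration. Covariates, when
requested, are standard-normal school- and pupil-level terms with linear
effects on the probability, clipped to [0.01, 0.99]. A single integer seed
drives everything, with fixed per-component stream offsets (prevalences,
covariates, outcomes, ledger split) so adding a component never perturbs
earlier draws; identical seeds give byte-identical datasets.

What a green simulation test does establish: the estimator recovers the
generating risk difference at the stated design (200 replicates, mean within
3 Monte-Carlo SEs, CI coverage in [90%, 99%]) and the ledger pipeline
conserves totals. What it does not: real pupil data have covariate
imbalance, nonresponse, unequal cluster sizes and non-beta cluster
heterogeneity, none of which are simulated; the worked example's published
effect came from a covariate-adjusted model we cannot re-run.

`simulate_ledger()` constructs multi-currency, multi-year ledgers whose
resolved totals hit requested phase and category margins exactly: cell
totals are the rank-one product of the margins (which satisfies both margin
constraints), raw item values are back-computed through the same rate/CPI
tables the pipeline will apply, and allocation fractions are drawn in
[0.5, 1] and divided out. Totals are exact to floating-point, well within
the 1-unit conservation tolerance.

## Numerical choices and edge cases

- `annuity_factor(0, n) = n` is handled as an explicit limit (the closed
  form is 0/0).
- Rounding is half-away-from-zero throughout reporting; internal arithmetic
  is double precision with no intermediate rounding.
- Missing exchange-rate or CPI entries raise typed errors naming the
  currency and year; unknown tornado parameters list the valid names.
- Ledger aggregation refuses empty ledgers and (by default) excludes
  monitoring-and-evaluation lines, matching the convention of reporting
  programme costs "excluding M&E".
- The identity-link fit starts at the pooled mean with zero slopes; the
  fallback is reported, never silent.

## Known limitations

- No probabilistic sensitivity analysis (CEACs), discounting of benefit
  streams, or budget-impact projection — none are part of this design.
- Referral/health-system cost offsets and monetised future spillovers are
  out of scope, as in the source evaluation.
- The cluster-robust variance uses the CR1 small-sample factor only;
  CR2/CR3 adjustments and wild-cluster bootstrap are not implemented.
- Covariate adjustment assumes covariates enter linearly on the probability
  scale.
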