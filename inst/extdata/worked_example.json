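{
  "comment": "Published inputs for the built-in worked example: an 18-month cluster-randomised trial of a school violence-prevention programme in 21 intervention schools in Uganda (2015 US$, provider perspective, excluding M&E). All figures are printed constants from the source evaluation, not estimates made here.",
  "base_year": 2015,
  "base_currency": "USD",
  "horizon_years": 1.5,
  "n_pupils": 9000,
  "n_intervention_schools": 21,
  "expected_prevalence": 0.49,
  "observed_prevalence": 0.31,
  "phase_totals": { "start_up": 117949, "implementation": 279284 },
  "category_totals": { "staff": 156441, "capital": 69164, "recurrent": 171628 },
  "annual_implementation_cost": 157343,
  "development": {
    "total_cost": 446940,
    "staff_cost": 244251,
    "useful_life_years": 7,
    "resale_fraction": 1.0,
    "discount_rate": 0.0926,
    "phase": "start_up",
    "category": "capital"
  },
  "teacher_time_cost": { "low": 1589, "high": 2781 },
  "risk_difference_ci": [0.08, 0.27],
  "sensitivity": {
    "dev_cost_multipliers": [0.5, 1.5],
    "resale_multipliers": [0.5, 1.5]
  }
}
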