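test_that("with no clustering structure the estimate is the difference in proportions", {
  # each pupil its own cluster: identity-link saturated case
  outcomes <- c(1, 1, 0, 1, 0, 0, 0, 1, 0, 0, 1, 0)
  arms <- c(rep("control", 6), rep("intervention", 6))
  records <- toy_records(as.list(outcomes), as.list(arms))
  records$school_id <- sprintf("p%02d", seq_len(nrow(records)))

  est <- fit_risk_difference(records)
  p0 <- mean(outcomes[arms == "control"])
  p1 <- mean(outcomes[arms == "intervention"])
  expect_equal(est$risk_difference, p0 - p1)
  expect_equal(est$n_clusters, 12)

  # one record per cluster reduces to the HC-type robust SE (oracle)
  expect_equal(est$se, oracle_arm_se(records), tolerance = 1e-10)
  expect_equal(est$ci_low, est$risk_difference - 1.96 * est$se)
  expect_equal(est$ci_high, est$risk_difference + 1.96 * est$se)
})

test_that("cluster-robust SE matches the brute-force sandwich on toy datasets", {
  toys <- list(
    toy_records(list(c(1, 1, 0), c(0, 1, 0), c(0, 0, 1), c(1, 0, 0)),
                list("control", "control", "intervention", "intervention")),
    toy_records(list(c(1, 1, 1, 0), c(0, 0, 1), c(0, 1), c(0, 0, 0, 1), c(1, 0)),
                list("control", "control", "intervention", "intervention",
                     "intervention")),
    toy_records(list(rep(1, 5), c(rep(0, 4), 1), c(0, 1, 0, 1), c(0, 0, 1, 0)),
                list("control", "control", "intervention", "intervention")),
    toy_records(list(c(1, 0), c(1, 1), c(0, 1), c(0, 0), c(1, 0), c(0, 1)),
                list("control", "control", "control", "intervention",
                     "intervention", "intervention")),
    toy_records(rep(list(c(1, 0, 0, 1, 1, 0, 0, 0)), 5),
                list("control", "control", "intervention", "intervention",
                     "control"))
  )
  for (records in toys) {
    est <- fit_risk_difference(records)
    expect_equal(est$se, oracle_arm_se(records), tolerance = 1e-8)
  }
})

test_that("estimates are invariant to record order", {
  design <- trial_design(n_clusters_per_arm = 4, pupils_per_cluster = 25, seed = 5)
  records <- simulate_trial(design)
  est1 <- fit_risk_difference(records)
  shuffled <- records[sample(nrow(records)), ]
  est2 <- fit_risk_difference(shuffled)
  expect_equal(est1$risk_difference, est2$risk_difference)
  expect_equal(est1$se, est2$se)
})

test_that("covariate adjustment passes covariates through the model", {
  design <- trial_design(
    n_clusters_per_arm = 8, pupils_per_cluster = 60, seed = 9,
    covariate_effects = c(school_ses = 0.05, age_z = 0.03)
  )
  records <- simulate_trial(design)
  unadj <- fit_risk_difference(records, adjust = FALSE)
  adj <- fit_risk_difference(records, adjust = TRUE)
  expect_false(unadj$adjusted)
  expect_true(adj$adjusted)
  expect_false(identical(unadj$se, adj$se))
})

test_that("degenerate trial data produce descriptive errors", {
  one_arm <- toy_records(list(c(1, 0), c(0, 1)), list("control", "control"))
  expect_error(fit_risk_difference(one_arm), "both")

  few <- toy_records(list(c(1, 0), c(0, 1), c(1, 1)),
                     list("control", "control", "intervention"))
  expect_error(fit_risk_difference(few), "2 clusters per arm")

  constant <- toy_records(list(c(1, 1), c(1, 1), c(1, 1), c(1, 1)),
                          list("control", "control", "intervention",
                               "intervention"))
  expect_error(fit_risk_difference(constant), "constant")

  mixed <- toy_records(list(c(1, 0), c(0, 1), c(1, 1), c(0, 0)),
                       list("control", "control", "intervention",
                            "intervention"))
  mixed$school_id[1] <- mixed$school_id[5]  # row 5 sits in an intervention cluster
  expect_error(fit_risk_difference(mixed), "both arms")
})

test_that("simulation recovery: mean estimate near the generating risk difference", {
  # scaled-down recovery check (the full-design version runs in the
  # acceptance suite): 30 replicates, 21+21 clusters of 60 pupils
  reps <- 30
  ests <- vapply(seq_len(reps), function(i) {
    d <- trial_design(n_clusters_per_arm = 21, pupils_per_cluster = 60,
                      seed = 1000 + i)
    fit_risk_difference(simulate_trial(d))$risk_difference
  }, numeric(1))
  mc_se <- sd(ests) / sqrt(reps)
  expect_lt(abs(mean(ests) - 0.18), 3 * mc_se)
})

test_that("counterfactual case arithmetic matches the published worked numbers", {
  cc <- counterfactual_cases(9000, 0.49, 0.31)
  expect_equal(cc$expected_reported, 4410)
  expect_equal(cc$observed_reported, 2790)
  expect_equal(cc$averted_reported, 1620)
  expect_equal(cc$relative_reduction, 1620 / 4410)

  upper <- counterfactual_cases(9000, 0.49, 0.22)
  expect_equal(upper$averted_reported, 2430)

  # no effect, linearity in n, antisymmetry under swapping prevalences
  expect_equal(counterfactual_cases(500, 0.3, 0.3)$averted_cases, 0)
  a <- counterfactual_cases(1000, 0.4, 0.25)
  b <- counterfactual_cases(3000, 0.4, 0.25)
  expect_equal(3 * a$averted_cases, b$averted_cases)
  expect_warning(sw <- counterfactual_cases(1000, 0.25, 0.4), "harm")
  expect_equal(sw$averted_cases, -a$averted_cases)
})

test_that("averted-case bounds scale the confidence interval by the population", {
  eff <- effect_estimate(0.18, 0.08, 0.27)
  expect_equal(averted_bounds(9000, eff), c(low = 720, high = 2430))
  expect_equal(averted_bounds(1000, effect_estimate(0.07, 0.05, 0.10)),
               c(low = 50, high = 100))
  expect_equal(averted_bounds(9000, effect_estimate(0, 0, 0)),
               c(low = 0, high = 0))
})

test_that("effect estimates serialise to JSON with diagnostics", {
  records <- simulate_trial(trial_design(n_clusters_per_arm = 4,
                                         pupils_per_cluster = 30, seed = 2))
  est <- fit_risk_difference(records)
  parsed <- jsonlite::fromJSON(effect_to_json(est))
  expect_equal(parsed$estimate, est$risk_difference)
  expect_equal(parsed$ci, c(est$ci_low, est$ci_high))
  expect_named(parsed$diagnostics, c("converged", "fallback_lpm"))
})
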