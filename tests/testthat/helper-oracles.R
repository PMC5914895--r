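# Independent oracles and fixture builders shared across the test files.
# The oracles deliberately avoid the package's own code paths.

# Brute-force present-value-of-annuity factor: explicit discount-factor sum.
brute_annuity <- function(rate, n) {
  total <- 0
  for (t in seq_len(n)) total <- total + (1 + rate)^(-t)
  total
}

# Brute-force net-present-value check of an equivalent annual cost: paying
# `eac` each year for n years and receiving the salvage at end of life must
# have the same present value as the principal.
brute_npv_of_eac <- function(eac, salvage, rate, n) {
  pv <- 0
  for (t in seq_len(n)) pv <- pv + eac * (1 + rate)^(-t)
  pv + salvage * (1 + rate)^(-n)
}

# Brute-force CR1 cluster-robust sandwich: (X'X)^-1 [sum_g X_g'e_g e_g'X_g]
# (X'X)^-1 * G/(G-1), assembled cluster by cluster with dense loops.
brute_cluster_sandwich <- function(X, e, cluster) {
  ids <- unique(cluster)
  G <- length(ids)
  XtX_inv <- solve(t(X) %*% X)
  meat <- matrix(0, ncol(X), ncol(X))
  for (g in ids) {
    idx <- which(cluster == g)
    Xg <- X[idx, , drop = FALSE]
    eg <- e[idx]
    sg <- t(Xg) %*% eg
    meat <- meat + sg %*% t(sg)
  }
  XtX_inv %*% meat %*% XtX_inv * G / (G - 1)
}

# OLS coefficients by normal equations, for oracle fits on toy data.
brute_ols <- function(X, y) solve(t(X) %*% X, t(X) %*% y)

# Hand-built pupil records: outcomes fixed per cluster, two arms.
toy_records <- function(outcomes_by_cluster, arms_by_cluster) {
  stopifnot(length(outcomes_by_cluster) == length(arms_by_cluster))
  rows <- lapply(seq_along(outcomes_by_cluster), function(i) {
    data.frame(
      school_id = sprintf("c%02d", i),
      arm = arms_by_cluster[[i]],
      outcome = outcomes_by_cluster[[i]],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

# Oracle sandwich SE for the arm coefficient on toy records, using an OLS
# (linear-probability) fit fully independent of the package.
oracle_arm_se <- function(records) {
  X <- cbind(1, as.numeric(records$arm == "intervention"))
  fit <- brute_ols(X, records$outcome)
  e <- records$outcome - as.vector(X %*% fit)
  V <- brute_cluster_sandwich(X, e, records$school_id)
  sqrt(V[2, 2])
}

# A small hand ledger: one item per phase/category combination used.
toy_ledger <- function(base_year = 2015, horizon = 1.5) {
  items <- list(
    cost_item("training", "start_up", "staff", "financial",
              money(1000, "USD", base_year)),
    cost_item("materials", "start_up", "recurrent", "financial",
              money(500, "USD", base_year)),
    cost_item("officers", "implementation", "staff", "financial",
              money(2000, "USD", base_year)),
    cost_item("transport", "implementation", "recurrent", "economic",
              money(750, "USD", base_year), allocation_fraction = 0.8)
  )
  cost_ledger(items, list(), base_year, "USD", horizon)
}

table1_profile <- function() {
  list(
    phase = c(start_up = 117949, implementation = 279284),
    category = c(staff = 156441, capital = 69164, recurrent = 171628)
  )
}

# Minimal pipeline configuration around a toy ledger, for tornado tests:
# fixed implementation cost 100 plus a development asset with principal 100,
# full resale, 10% discount, one-year horizon (EAC = 10, charge = 10).
toy_config <- function() {
  ledger <- cost_ledger(
    list(cost_item("fixed", "implementation", "recurrent", "financial",
                   money(100, "USD", 2015))),
    list(capital_asset("dev", money(100, "USD", 2015), 7, 1, 0.10)),
    base_year = 2015, base_currency = "USD", horizon_years = 1
  )
  list(
    ledger = ledger, exchange_rates = list(), cpi = c("2015" = 100),
    counts = counterfactual_cases(1000, 0.3, 0.2)
  )
}
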