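#' Synthetic cluster-trial and cost-ledger generation
#'
#' Every pipeline stage is testable without external data. The trial
#' generator emulates a two-arm cluster-randomised design: cluster (school)
#' prevalences are drawn from a beta distribution whose mean is the arm
#' prevalence and whose dispersion is set by the intracluster correlation
#' (beta-binomial construction, chosen over logit-normal because the
#' mean/ICC relations are closed form); pupil outcomes are Bernoulli given
#' the cluster prevalence. Defaults mirror a 42-school trial: 21 clusters
#' per arm, 430 pupils per school, control prevalence 0.49, protective risk
#' difference 0.18, ICC 0.1.
#'
#' A single integer seed governs all randomness. Streams are split per
#' component (cluster prevalences, covariates, outcomes) with fixed offsets,
#' so adding covariates never perturbs the prevalence draws.
#'
#' @name synthetic
NULL

SEED_STREAM_PREVALENCE <- 0L
SEED_STREAM_COVARIATES <- 500009L
SEED_STREAM_OUTCOMES <- 1000003L
SEED_STREAM_LEDGER <- 1500007L

#' Describe a two-arm cluster-trial design
#'
#' @param n_clusters_per_arm clusters (schools) per arm.
#' @param pupils_per_cluster single count or vector recycled over clusters.
#' @param control_prevalence outcome prevalence in the control arm.
#' @param risk_difference protective risk difference, subtracted in the
#'   intervention arm; `control_prevalence - risk_difference` must lie in
#'   (0, 1).
#' @param icc intracluster correlation in `[0, 1)`.
#' @param covariate_effects optional named numeric vector of linear effects
#'   on the outcome probability; names starting `school_` generate
#'   school-level standard-normal covariates, all others pupil-level.
#' @param seed integer master seed.
#' @return object of class `trial_design`.
#' @export
trial_design <- function(n_clusters_per_arm = 21L, pupils_per_cluster = 430L,
                         control_prevalence = 0.49, risk_difference = 0.18,
                         icc = 0.1, covariate_effects = NULL, seed = 1L) {
  assert_scalar_number(n_clusters_per_arm, "n_clusters_per_arm", min = 1)
  assert_scalar_number(control_prevalence, "control_prevalence", min = 0, max = 1)
  assert_scalar_number(risk_difference, "risk_difference", min = -1, max = 1)
  p1 <- control_prevalence - risk_difference
  if (p1 <= 0 || p1 >= 1) {
    stop_cea("intervention prevalence %.3f = control_prevalence - risk_difference must be in (0, 1)", p1)
  }
  assert_scalar_number(icc, "icc", min = 0)
  if (icc >= 1) stop_cea("`icc` must be below 1")
  assert_scalar_number(seed, "seed")
  structure(
    list(
      n_clusters_per_arm = as.integer(n_clusters_per_arm),
      pupils_per_cluster = as.integer(pupils_per_cluster),
      control_prevalence = control_prevalence,
      risk_difference = risk_difference,
      icc = icc,
      covariate_effects = covariate_effects,
      seed = as.integer(seed)
    ),
    class = "trial_design"
  )
}

# Beta shapes with mean m and intracluster correlation rho:
# a + b = 1/rho - 1, a = m (1/rho - 1).
beta_shapes <- function(mean, icc) {
  s <- 1 / icc - 1
  a <- mean * s
  b <- (1 - mean) * s
  if (a <= 0 || b <= 0) {
    stop_cea("icc %.3f too large for arm prevalence %.3f: beta shapes non-positive",
             icc, mean)
  }
  c(a = a, b = b)
}

#' Simulate pupil-level records from a trial design
#'
#' @param design a [trial_design].
#' @return data.frame of pupil records (`school_id`, `arm`, `outcome`,
#'   covariate columns) with the design attached as attribute `design` and
#'   the drawn cluster prevalences as attribute `cluster_prevalence`. The
#'   same seed yields byte-identical output.
#' @export
simulate_trial <- function(design) {
  stopifnot(inherits(design, "trial_design"))
  G <- 2L * design$n_clusters_per_arm
  sizes <- rep_len(design$pupils_per_cluster, G)
  arms <- rep(c("control", "intervention"), each = design$n_clusters_per_arm)
  school_ids <- sprintf("s%02d", seq_len(G))
  arm_prev <- ifelse(arms == "control", design$control_prevalence,
                     design$control_prevalence - design$risk_difference)

  cluster_p <- with_seed(design$seed + SEED_STREAM_PREVALENCE, {
    if (design$icc == 0) {
      arm_prev
    } else {
      vapply(arm_prev, function(m) {
        sh <- beta_shapes(m, design$icc)
        stats::rbeta(1, sh["a"], sh["b"])
      }, numeric(1))
    }
  })

  n_total <- sum(sizes)
  df <- data.frame(
    school_id = rep(school_ids, sizes),
    arm = rep(arms, sizes),
    stringsAsFactors = FALSE
  )
  p <- rep(cluster_p, sizes)

  eff <- design$covariate_effects
  if (!is.null(eff) && length(eff)) {
    covs <- with_seed(design$seed + SEED_STREAM_COVARIATES, {
      out <- list()
      for (nm in names(eff)) {
        if (startsWith(nm, "school_")) {
          z <- stats::rnorm(G)
          out[[nm]] <- rep(z, sizes)
        } else {
          out[[nm]] <- stats::rnorm(n_total)
        }
      }
      out
    })
    for (nm in names(eff)) {
      df[[nm]] <- covs[[nm]]
      p <- p + eff[[nm]] * covs[[nm]]
    }
    p <- pmin(pmax(p, 0.01), 0.99)
  }

  df$outcome <- with_seed(design$seed + SEED_STREAM_OUTCOMES,
                          stats::rbinom(n_total, 1L, p))
  df <- df[, c("school_id", "arm", "outcome",
               setdiff(names(df), c("school_id", "arm", "outcome")))]
  attr(df, "design") <- design
  attr(df, "cluster_prevalence") <- stats::setNames(cluster_p, school_ids)
  df
}

#' ANOVA estimator of the intracluster correlation
#'
#' One-way random-effects ANOVA estimator on the binary outcome; used to
#' check that simulated data carry the designed ICC.
#'
#' @param records pupil records with `school_id` and `outcome`.
#' @return estimated ICC (may be slightly negative in small samples).
#' @export
estimate_icc <- function(records) {
  y <- records$outcome
  g <- factor(records$school_id)
  k <- length(levels(g))
  n_i <- as.numeric(table(g))
  N <- length(y)
  means <- tapply(y, g, mean)
  grand <- mean(y)
  msb <- sum(n_i * (means - grand)^2) / (k - 1)
  msw <- sum((y - means[g])^2) / (N - k)
  n0 <- (N - sum(n_i^2) / N) / (k - 1)
  (msb - msw) / (msb + (n0 - 1) * msw)
}

#' Simulate a cost ledger with known category and phase totals
#'
#' Builds a multi-currency, multi-year ledger whose converted, inflated and
#' allocated line values reproduce a requested set of phase and category
#' totals exactly (raw values are back-computed through the same rate and
#' CPI tables the pipeline will apply). Cell totals on the phase-by-category
#' grid are the rank-one product of the margins, so both margins are honoured.
#'
#' @param profile list with numeric named vectors `phase` (over
#'   [LEDGER_PHASES] subsets) and `category` (over [LEDGER_CATEGORIES]
#'   subsets); the two must have equal grand totals.
#' @param seed integer seed for the item-level split, currencies and years.
#' @param base_year,base_currency,horizon_years ledger configuration.
#' @return list with elements `ledger` (a [cost_ledger]), `exchange_rates`
#'   and `cpi` (the tables the ledger must be resolved with).
#' @export
simulate_ledger <- function(profile, seed = 1L, base_year = 2015L,
                            base_currency = "USD", horizon_years = 1.5) {
  phase_tot <- profile$phase
  cat_tot <- profile$category
  if (any(phase_tot < 0) || any(cat_tot < 0)) {
    stop_cea("profile totals must be non-negative")
  }
  grand_p <- sum(phase_tot)
  grand_c <- sum(cat_tot)
  if (abs(grand_p - grand_c) > 1e-6 * max(1, grand_p)) {
    stop_cea("infeasible profile: phase totals sum to %g but category totals to %g",
             grand_p, grand_c)
  }
  exchange_rates <- list(UGX = c("2012" = 2505, "2013" = 2587, "2014" = 2600))
  cpi <- c("2012" = 95.2, "2013" = 96.6, "2014" = 98.1, "2015" = 98.2)
  if (is.null(lookup_year(cpi, base_year))) cpi[as.character(base_year)] <- 100

  items <- list()
  if (grand_p > 0) {
    with_seed(seed + SEED_STREAM_LEDGER, {
      for (ph in names(phase_tot)) {
        for (ct in names(cat_tot)) {
          cell <- phase_tot[[ph]] * cat_tot[[ct]] / grand_p
          if (cell <= 0) next
          n_items <- sample(1:3, 1)
          w <- stats::runif(n_items)
          w <- w / sum(w)
          for (j in seq_len(n_items)) {
            target <- cell * w[j]
            currency <- sample(c(base_currency, "UGX"), 1)
            year <- sample(2012:2014, 1)
            f <- stats::runif(1, 0.5, 1)
            rate <- if (currency == base_currency) 1 else
              exchange_rates[[currency]][[as.character(year)]]
            # raw value such that convert -> inflate -> allocate hits `target`
            raw <- target / f * rate * cpi[[as.character(year)]] /
              cpi[[as.character(base_year)]]
            items[[length(items) + 1L]] <- cost_item(
              label = sprintf("%s/%s item %d", ph, ct, j),
              phase = ph, category = ct, cost_basis = "financial",
              amount = money(raw, currency, year),
              allocation_fraction = f
            )
          }
        }
      }
    })
  }
  ledger <- cost_ledger(items, list(), base_year, base_currency, horizon_years)
  list(ledger = ledger, exchange_rates = exchange_rates, cpi = cpi)
}
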