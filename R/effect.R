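#' Cluster-trial effect estimation on the risk-difference scale
#'
#' The effect of interest is the absolute difference in outcome prevalence
#' between arms (risk difference, RD), here oriented control minus
#' intervention so that a positive RD means the intervention is protective.
#' The point estimate comes from an identity-link binomial GLM of the binary
#' outcome on arm (plus optional covariates); when identity-link maximum
#' likelihood fails to converge (fitted probabilities leaving \[0, 1\]) the
#' fit falls back to an ordinary linear-probability model and flags this.
#' Uncertainty uses a cluster-robust sandwich variance with schools as
#' clusters:
#'
#'   V = (X'X)^-1 \[ sum_g X_g' e_g e_g' X_g \] (X'X)^-1 * G/(G-1)
#'
#' where e are response residuals and G the number of clusters. The
#' linear-estimating-equation "bread" (X'X)^-1 is used for both fitting
#' routes so the estimator has a single well-defined oracle; with one record
#' per cluster it reduces to the usual HC-type robust variance.
#'
#' @name effect
NULL

#' Read pupil-level trial records from CSV
#'
#' Required columns: `school_id`, `arm` (coded `control` / `intervention`),
#' `outcome` (0/1). Any further columns are treated as covariates.
#'
#' @param path CSV path.
#' @return data.frame of pupil records.
#' @export
read_pupil_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  required <- c("school_id", "arm", "outcome")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_cea("pupil CSV is missing columns: %s", paste(missing, collapse = ", "))
  }
  validate_pupil_records(df)
  df
}

validate_pupil_records <- function(records) {
  if (!all(records$outcome %in% c(0, 1))) {
    stop_cea("`outcome` must be binary 0/1")
  }
  if (!all(records$arm %in% c("control", "intervention"))) {
    stop_cea("`arm` must be coded control/intervention")
  }
  arms_per_school <- tapply(records$arm, records$school_id,
                            function(a) length(unique(a)))
  if (any(arms_per_school > 1L)) {
    bad <- names(arms_per_school)[arms_per_school > 1L]
    stop_cea("school(s) %s appear in both arms; cluster randomisation requires one arm per school",
             paste(bad, collapse = ", "))
  }
  invisible(records)
}

# CR1 cluster-robust sandwich variance with OLS bread.
cluster_sandwich_vcov <- function(X, resid, cluster) {
  G <- length(unique(cluster))
  bread <- solve(crossprod(X))
  scores <- rowsum(X * resid, group = cluster)  # X_g' e_g, one row per cluster
  meat <- crossprod(as.matrix(scores))
  bread %*% meat %*% bread * G / (G - 1)
}

#' Estimate the adjusted risk difference from pupil records
#'
#' @param records data.frame with `school_id`, `arm`, `outcome` and optional
#'   covariate columns.
#' @param adjust include covariates in the model? Covariates are passed
#'   through as-is; there is no automatic selection.
#' @param covariates character vector of covariate column names; default all
#'   non-design columns when `adjust = TRUE`.
#' @param ci_multiplier multiplier for the confidence bounds; default 1.96
#'   (normal approximation).
#' @return an object of class `effect_estimate`: `risk_difference` (control
#'   minus intervention, positive = protective), `se`, `ci_low`, `ci_high`,
#'   `n_clusters`, `adjusted`, `converged`, `fallback_lpm`.
#' @export
fit_risk_difference <- function(records, adjust = FALSE, covariates = NULL,
                                ci_multiplier = 1.96) {
  validate_pupil_records(records)
  cluster <- as.character(records$school_id)
  sizes <- table(cluster)
  if (any(sizes == 0L)) stop_cea("empty cluster present")
  arm_of_cluster <- tapply(records$arm, cluster, function(a) a[1])
  n_per_arm <- table(arm_of_cluster)
  if (length(n_per_arm) < 2L) {
    stop_cea("both a control and an intervention arm are required")
  }
  if (any(n_per_arm < 2L)) {
    stop_cea("need at least 2 clusters per arm (got %s)",
             paste(sprintf("%s=%d", names(n_per_arm), n_per_arm), collapse = ", "))
  }
  if (length(unique(records$outcome)) < 2L) {
    stop_cea("outcome is constant; both outcome levels must be present")
  }

  if (adjust && is.null(covariates)) {
    covariates <- setdiff(names(records), c("school_id", "arm", "outcome"))
  }
  if (!adjust) covariates <- character(0)
  if (length(covariates) && !all(covariates %in% names(records))) {
    stop_cea("covariate column(s) not found: %s",
             paste(setdiff(covariates, names(records)), collapse = ", "))
  }

  df <- records
  df$.arm_int <- as.numeric(df$arm == "intervention")
  rhs <- paste(c(".arm_int", covariates), collapse = " + ")
  fml <- stats::as.formula(paste("outcome ~", rhs))

  fallback <- FALSE
  converged <- TRUE
  fit <- tryCatch({
    start <- c(mean(df$outcome), rep(0, 1L + length(covariates)))
    g <- suppressWarnings(stats::glm(fml, family = stats::binomial(link = "identity"),
                                     data = df, start = start))
    if (!g$converged || any(g$fitted.values < 0) || any(g$fitted.values > 1)) {
      stop("identity-link fit invalid")
    }
    g
  }, error = function(e) {
    fallback <<- TRUE
    stats::lm(fml, data = df)
  })
  if (fallback) converged <- FALSE

  X <- stats::model.matrix(fit)
  e <- df$outcome - stats::fitted(fit)
  V <- cluster_sandwich_vcov(X, e, cluster)
  co <- stats::coef(fit)[".arm_int"]
  se <- sqrt(V[".arm_int", ".arm_int"])

  # control-minus-intervention orientation: protective effects are positive
  rd <- -as.numeric(co)
  structure(
    list(
      risk_difference = rd,
      se = as.numeric(se),
      ci_low = rd - ci_multiplier * se,
      ci_high = rd + ci_multiplier * se,
      n_clusters = length(sizes),
      adjusted = adjust,
      converged = converged,
      fallback_lpm = fallback,
      ci_multiplier = ci_multiplier
    ),
    class = "effect_estimate"
  )
}

#' Build an effect estimate from known values
#'
#' For worked examples and sensitivity analyses where the risk difference and
#' its confidence bounds are stated rather than estimated from pupil data.
#'
#' @param risk_difference,ci_low,ci_high point estimate and 95% bounds
#'   (control minus intervention).
#' @param se optional standard error; back-filled from the bounds when absent.
#' @param n_clusters number of clusters, if known.
#' @return an `effect_estimate`.
#' @export
effect_estimate <- function(risk_difference, ci_low, ci_high, se = NULL,
                            n_clusters = NA_integer_) {
  if (ci_low > risk_difference || risk_difference > ci_high) {
    stop_cea("risk_difference must lie within [ci_low, ci_high]")
  }
  structure(
    list(
      risk_difference = risk_difference, se = se %||% ((ci_high - ci_low) / (2 * 1.96)),
      ci_low = ci_low, ci_high = ci_high, n_clusters = n_clusters,
      adjusted = NA, converged = NA, fallback_lpm = NA, ci_multiplier = 1.96
    ),
    class = "effect_estimate"
  )
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("Risk difference (control - intervention): %.4f\n", x$risk_difference))
  cat(sprintf("  SE (cluster-robust, CR1): %.4f\n", x$se))
  cat(sprintf("  95%% CI: (%.4f, %.4f)   clusters: %s\n", x$ci_low, x$ci_high,
              x$n_clusters))
  if (isTRUE(x$fallback_lpm)) {
    cat("  note: identity-link binomial fit failed; linear-probability fallback used\n")
  }
  invisible(x)
}

#' Serialise an effect estimate to JSON
#' @param effect an `effect_estimate`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @export
effect_to_json <- function(effect, path = NULL) {
  stopifnot(inherits(effect, "effect_estimate"))
  obj <- list(
    estimate = effect$risk_difference, se = effect$se,
    ci = c(effect$ci_low, effect$ci_high),
    n_clusters = effect$n_clusters, adjusted = effect$adjusted,
    diagnostics = list(converged = effect$converged,
                       fallback_lpm = effect$fallback_lpm)
  )
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
}

#' Counterfactual case counts and cases averted
#'
#' Cases averted are the difference between the cases expected in the
#' intervention group in the absence of the intervention (counterfactual
#' prevalence times population) and the cases actually observed.
#'
#' @param n_pupils number of pupils in the intervention group.
#' @param expected_prevalence counterfactual prevalence absent intervention.
#' @param observed_prevalence observed prevalence under the intervention.
#' @return object of class `case_counts` with full-precision counts, half-up
#'   rounded `*_reported` counts and the descriptive
#'   `relative_reduction = (expected - observed) / expected`.
#' @export
#' @examples
#' counterfactual_cases(9000, 0.49, 0.31) # 4410 expected, 2790 observed, 1620 averted
counterfactual_cases <- function(n_pupils, expected_prevalence, observed_prevalence) {
  assert_scalar_number(n_pupils, "n_pupils", min = 1)
  assert_scalar_number(expected_prevalence, "expected_prevalence", min = 0, max = 1)
  assert_scalar_number(observed_prevalence, "observed_prevalence", min = 0, max = 1)
  expected <- n_pupils * expected_prevalence
  observed <- n_pupils * observed_prevalence
  averted <- expected - observed
  if (averted < 0) {
    warning("observed prevalence exceeds expected: negative cases averted (harm)",
            call. = FALSE)
  }
  structure(
    list(
      n_pupils = as.integer(n_pupils),
      expected_prevalence = expected_prevalence,
      observed_prevalence = observed_prevalence,
      expected_cases = expected, observed_cases = observed,
      averted_cases = averted,
      expected_reported = round_half_up(expected),
      observed_reported = round_half_up(observed),
      averted_reported = round_half_up(averted),
      relative_reduction = if (expected > 0) averted / expected else NA_real_
    ),
    class = "case_counts"
  )
}

#' @export
print.case_counts <- function(x, ...) {
  cat(sprintf("Among %d pupils: expected %g, observed %g, averted %g cases\n",
              x$n_pupils, x$expected_reported, x$observed_reported,
              x$averted_reported))
  invisible(x)
}

#' Bounds on cases averted from the risk-difference confidence interval
#'
#' @param n_pupils intervention-group population.
#' @param effect an `effect_estimate` with finite confidence bounds.
#' @return named numeric `c(low =, high =)`, each `n_pupils` times the CI
#'   bound, rounded half-up.
#' @export
#' @examples
#' averted_bounds(9000, effect_estimate(0.18, 0.08, 0.27)) # 720, 2430
averted_bounds <- function(n_pupils, effect) {
  stopifnot(inherits(effect, "effect_estimate"))
  if (!is.finite(effect$ci_low) || !is.finite(effect$ci_high)) {
    stop_cea("effect estimate must have finite confidence bounds")
  }
  c(low = round_half_up(n_pupils * effect$ci_low),
    high = round_half_up(n_pupils * effect$ci_high))
}
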