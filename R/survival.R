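# Survival comparison across NSS quartiles.
#
# The Kaplan-Meier estimator and the log-rank test are implemented
# directly (they are small, and the direct implementation keeps the
# package dependency-free); the survival package serves as an
# independent cross-check in the test suite.

#' Assign patients to NSS quartile groups
#'
#' Computes a per-patient NSS from the patient's stratum prevalence and
#' own examined-node count, then cuts at the empirical 25/50/75
#' percentiles.  Ties at a cut point go to the lower group, so group
#' sizes can be unequal when the score is heavily discrete.
#'
#' @param nss Numeric vector of per-patient NSS values.
#' @return Factor with levels `Q1`..`Q4` (`Q1` = lowest scores).
#' @export
assign_nss_groups <- function(nss) {
  if (anyNA(nss)) stop("NSS values must not be missing", call. = FALSE)
  if (length(unique(nss)) < 4L)
    stop("fewer than 4 distinct NSS values: no quartile structure",
         call. = FALSE)
  qs <- stats::quantile(nss, c(0.25, 0.5, 0.75), names = FALSE)
  g <- 1L + (nss > qs[1L]) + (nss > qs[2L]) + (nss > qs[3L])
  factor(paste0("Q", g), levels = paste0("Q", 1:4))
}

#' Per-patient NSS for a cohort
#'
#' Evaluates each patient's NSS at their own examined-node count, using
#' the corrected prevalence of their level of one stratifying factor.
#' Applied to all patients regardless of observed node status (set
#' `ln_negative_only = TRUE` to restrict to observed node-negative
#' patients).
#'
#' @param cohort A cohort data frame.
#' @param strata Data frame from [stratum_estimates()].
#' @param params A [betabin_params()] object.
#' @param factor_name Which clinicopathological factor's curves to use.
#' @param ln_negative_only If `TRUE`, return `NA` for observed
#'   node-positive patients.
#' @return Numeric vector of NSS values aligned with `cohort` rows
#'   (`NA` for patients whose factor level is missing).
#' @export
cohort_nss <- function(cohort, strata, params, factor_name = "gender",
                       ln_negative_only = FALSE) {
  params <- as_betabin_params(params)
  rows <- strata[strata$factor == factor_name, ]
  if (nrow(rows) == 0L)
    stop("no strata for factor '", factor_name, "'", call. = FALSE)
  prev <- stats::setNames(rows$corrected_prevalence, rows$level)
  out <- rep(NA_real_, nrow(cohort))
  for (l in names(prev)) {
    i <- which(cohort[[factor_name]] == l)
    if (length(i))
      out[i] <- nss_value(cohort$nodes_examined[i], prev[[l]], params)
  }
  if (ln_negative_only) out[cohort$nodes_positive >= 1] <- NA_real_
  out
}

#' Kaplan-Meier product-limit estimate
#'
#' Right-continuous survival step function with `S(0) = 1`; the estimate
#' steps down only at event times.
#'
#' @param time Nonnegative follow-up times.
#' @param event Event indicators (1 = death, 0 = censored).
#' @return A data frame with one row per distinct event time: `time`,
#'   `n_risk`, `n_event`, `survival`.
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0L) stop("empty input", call. = FALSE)
  if (length(time) != length(event))
    stop("'time' and 'event' must have equal length", call. = FALSE)
  if (any(time < 0)) stop("times must be nonnegative", call. = FALSE)
  event <- as.integer(event)
  ut <- sort(unique(time[event == 1L]))
  if (length(ut) == 0L)
    return(data.frame(time = numeric(0), n_risk = integer(0),
                      n_event = integer(0), survival = numeric(0)))
  n_risk <- vapply(ut, function(t) sum(time >= t), integer(1L))
  n_event <- vapply(ut, function(t) sum(time == t & event == 1L), integer(1L))
  data.frame(time = ut, n_risk = n_risk, n_event = n_event,
             survival = cumprod(1 - n_event / n_risk))
}

#' Log-rank test for two or more survival groups
#'
#' At each distinct event time the observed events per group are
#' compared with the expectation under the hypergeometric null; the
#' statistic is the quadratic form of the observed-minus-expected vector
#' in its estimated covariance (last group dropped), referred to a
#' chi-square with `groups - 1` degrees of freedom.
#'
#' @param time Follow-up times.
#' @param event Event indicators (1 = event, 0 = censored).
#' @param group Group labels (coerced to factor); at least two non-empty
#'   groups and at least one event overall.
#' @return List with `statistic`, `df`, `p_value`, and the per-group
#'   `observed` and `expected` event counts.
#' @export
logrank_test <- function(time, event, group) {
  group <- factor(group)
  group <- droplevels(group)
  g <- nlevels(group)
  if (g < 2L) stop("at least two non-empty groups are required", call. = FALSE)
  event <- as.integer(event)
  if (sum(event) == 0L)
    stop("no events: the log-rank test is undefined", call. = FALSE)

  ut <- sort(unique(time[event == 1L]))
  O <- stats::setNames(numeric(g), levels(group))
  E <- O
  V <- matrix(0, g, g)
  for (t in ut) {
    at_risk <- time >= t
    n <- sum(at_risk)
    if (n < 2L) next  # no variance contribution from a single subject
    nj <- vapply(levels(group),
                 function(l) sum(at_risk & group == l), numeric(1L))
    dj <- vapply(levels(group),
                 function(l) sum(time == t & event == 1L & group == l),
                 numeric(1L))
    d <- sum(dj)
    O <- O + dj
    E <- E + d * nj / n
    # V_t[j,l] = d(n-d)/(n-1) * (delta_jl nj/n - nj nl/n^2)
    f <- d * (n - d) / ((n - 1) * n)
    V <- V + f * (diag(nj, g) - tcrossprod(nj) / n)
  }
  z <- (O - E)[-g]
  Vr <- V[-g, -g, drop = FALSE]
  stat <- tryCatch(drop(t(z) %*% solve(Vr, z)), error = function(e) NA_real_)
  if (!is.finite(stat))
    stop("singular covariance: groups are degenerate", call. = FALSE)
  df <- g - 1L
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       observed = O, expected = E)
}

#' Compare overall survival across NSS quartiles
#'
#' Groups a cohort by quartiles of the per-patient NSS for one
#' clinicopathological factor and runs the four-group log-rank test,
#' returning per-group Kaplan-Meier curves alongside the test.  By
#' default only observed node-negative patients enter: the NSS is a
#' negative predictive value, defined for patients whose examined nodes
#' are all negative, and only for them do NSS strata order the risk of
#' occult residual disease (set `ln_negative_only = FALSE` to group the
#' whole cohort).
#'
#' @inheritParams cohort_nss
#' @return List with `groups` (factor of quartile labels), `test`
#'   (from [logrank_test()]), `km` (named list of per-group
#'   [km_estimate()] tables), and `group_sizes`.
#' @export
survival_by_nss <- function(cohort, strata, params, factor_name = "gender",
                            ln_negative_only = TRUE) {
  nss <- cohort_nss(cohort, strata, params, factor_name, ln_negative_only)
  keep <- !is.na(nss)
  grp <- assign_nss_groups(nss[keep])
  sub <- cohort[keep, ]
  test <- logrank_test(sub$followup_months, sub$event, grp)
  # heavy ties can leave a quartile empty; report its curve as empty
  km <- lapply(stats::setNames(levels(grp), levels(grp)), function(l) {
    i <- grp == l
    if (!any(i))
      return(data.frame(time = numeric(0), n_risk = integer(0),
                        n_event = integer(0), survival = numeric(0)))
    km_estimate(sub$followup_months[i], sub$event[i])
  })
  list(groups = grp, test = test, km = km, group_sizes = table(grp))
}
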