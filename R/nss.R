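# Prevalence correction and the nodal staging score (NSS).
#
# Limited node sampling misclassifies some truly node-positive patients
# as negative; the observed metastasis prevalence therefore understates
# the truth.  The moment estimator below corrects it, and Bayes' rule
# turns the corrected prevalence plus the false-negative curve into the
# NSS: the posterior probability that an all-negative examination
# reflects a truly node-negative patient.

#' Corrected metastasis prevalence for a stratum
#'
#' Moment estimator of the true metastasis prevalence that accounts for
#' false-negative staging: `pi_hat = (# observed positive) /
#' sum_i (1 - p0(n_i))`, the solution of the unbiased estimating
#' equation `E[# positive] = pi * sum_i (1 - p0(n_i))` over all patients
#' in the stratum.  It always lies at or above the observed prevalence
#' and is clipped at 1 (with a warning) if sampling noise pushes the
#' ratio beyond it.
#'
#' @param observed_positive Logical (or 0/1) vector: patient has at
#'   least one positive node.
#' @param nodes_examined Integer vector of examined-node counts, aligned
#'   with `observed_positive`.
#' @param params A [betabin_params()] object.
#' @return The corrected prevalence (single number in `[0, 1]`).
#' @examples
#' # two patients with a single node examined each, one positive:
#' corrected_prevalence(c(TRUE, FALSE), c(1, 1), betabin_params(1.51, 1.15))
#' @export
corrected_prevalence <- function(observed_positive, nodes_examined, params) {
  params <- as_betabin_params(params)
  observed_positive <- as.logical(observed_positive)
  if (length(observed_positive) != length(nodes_examined))
    stop("inputs must have equal length", call. = FALSE)
  if (length(observed_positive) == 0L)
    stop("at least one patient is required", call. = FALSE)
  denom <- sum(1 - staging_fn_prob(nodes_examined, params))
  if (denom <= 0)
    stop("all patients have zero nodes examined; the corrected prevalence ",
         "is undefined", call. = FALSE)
  est <- sum(observed_positive) / denom
  if (est > 1) {
    warning("corrected prevalence exceeded 1 and was clipped", call. = FALSE)
    est <- 1
  }
  est
}

#' Nodal staging score
#'
#' Posterior probability that a patient whose `n` examined nodes are all
#' negative is truly node-negative:
#' `NSS(n) = (1 - pi) / ((1 - pi) + pi * p0(n))`,
#' where `pi` is the (corrected) metastasis prevalence of the patient's
#' stratum and `p0(n)` the false-negative staging probability.  At
#' `n = 0` the score is the prior `1 - pi`; it increases towards 1 as
#' more nodes are examined.
#'
#' @param n Examined-node count(s), `>= 0`.  Vectorised.
#' @param prevalence Corrected metastasis prevalence `pi` in `[0, 1]`.
#' @param params A [betabin_params()] object.
#' @return NSS value(s) in `[0, 1]`.
#' @examples
#' nss_value(1, 0.776, betabin_params(1.51, 1.15))  # 0.400
#' @export
nss_value <- function(n, prevalence, params) {
  params <- as_betabin_params(params)
  if (!is.numeric(prevalence) || length(prevalence) != 1L ||
      !is.finite(prevalence) || prevalence < 0 || prevalence > 1)
    stop("'prevalence' must be a single number in [0, 1]", call. = FALSE)
  p0 <- staging_fn_prob(n, params)
  (1 - prevalence) / ((1 - prevalence) + prevalence * p0)
}

#' Examined nodes needed to reach an NSS threshold
#'
#' Smallest `n >= 1` with `nss_value(n) >= threshold`, or `NA` if the
#' threshold is unreachable within `n_max` (high-prevalence strata can
#' never reach high thresholds at realistic dissection extents; tables
#' render this as an em-dash).
#'
#' @param threshold Target negative predictive value in `(0, 1)`.
#' @param prevalence Corrected metastasis prevalence.
#' @param params A [betabin_params()] object.
#' @param n_max Largest examined-node count to scan (default 100).
#' @return Integer node count, or `NA_integer_` if unreachable.
#' @examples
#' p <- betabin_params(1.51, 1.15)
#' nodes_needed(0.90, 0.776, p)  # males: 12 nodes
#' nodes_needed(0.90, 0.538, p)  # females: 6 nodes
#' @export
nodes_needed <- function(threshold, prevalence, params, n_max = 100L) {
  params <- as_betabin_params(params)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stop("'threshold' must lie strictly between 0 and 1", call. = FALSE)
  if (n_max < 1L) stop("'n_max' must be >= 1", call. = FALSE)
  vals <- nss_value(seq_len(n_max), prevalence, params)
  hit <- which(vals >= threshold)
  if (length(hit) == 0L) NA_integer_ else as.integer(hit[1L])
}

#' Round half away from zero
#'
#' Decimal rounding with halves always rounded up, matching how the
#' percentage tables are printed (base R's `round()` rounds halves to
#' even).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded values.
#' @export
round_half_up <- function(x, digits = 1L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Per-stratum observed and corrected prevalence estimates
#'
#' Splits a cohort by each requested clinicopathological factor and
#' estimates, per level: patient count, observed node-positive count and
#' prevalence, and the corrected prevalence via
#' [corrected_prevalence()].  Patients with a missing level (e.g. tumour
#' size unavailable) are excluded from that factor's strata.
#'
#' @param cohort A cohort data frame in the schema of [read_cohort()].
#' @param params A [betabin_params()] object (typically from
#'   [fit_betabin_truncated()]).
#' @param factors Character vector of factor column names.
#' @return A data frame with columns `factor`, `level`, `n_patients`,
#'   `n_positive`, `observed_prevalence`, `corrected_prevalence`.
#' @export
stratum_estimates <- function(cohort, params,
                              factors = c("gender", "age_group", "ete",
                                          "multifocal", "size_cat", "t_stage")) {
  params <- as_betabin_params(params)
  missing_cols <- setdiff(factors, names(cohort))
  if (length(missing_cols) > 0L)
    stop("cohort lacks factor column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  pos <- cohort$nodes_positive >= 1
  out <- list()
  for (f in factors) {
    lev <- cohort[[f]]
    keep <- !is.na(lev) & lev != "missing"
    for (l in unique(lev[keep])) {
      i <- keep & lev == l
      out[[length(out) + 1L]] <- data.frame(
        factor = f, level = as.character(l),
        n_patients = sum(i), n_positive = sum(pos[i]),
        observed_prevalence = mean(pos[i]),
        corrected_prevalence = corrected_prevalence(
          pos[i], cohort$nodes_examined[i], params),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' NSS and nodes-needed result tables
#'
#' For a set of strata (each with a corrected prevalence), tabulates
#' (i) the NSS at each examined-node count of `node_grid`, as percentages
#' rounded half-up to one decimal, and (ii) the smallest examined-node
#' count reaching each threshold of `threshold_grid` (unreachable cells
#' are `NA`, rendered as an em-dash when formatted).
#'
#' @param strata Data frame from [stratum_estimates()], or any data
#'   frame with columns `factor`, `level`, `corrected_prevalence`.
#' @param params A [betabin_params()] object.
#' @param node_grid Increasing positive integers (default
#'   `c(1, 5, 10, 15, 20, 25)`).
#' @param threshold_grid Increasing proportions in `(0, 1)` (default
#'   `c(0.80, 0.85, 0.90, 0.95)`).
#' @param n_max Scan limit for [nodes_needed()].
#' @return A list with data frames `nss` (one row per stratum, one
#'   column per node count, percentages) and `nodes_needed` (one row per
#'   stratum, one column per threshold, integer or `NA`).
#' @export
build_nss_tables <- function(strata, params,
                             node_grid = c(1L, 5L, 10L, 15L, 20L, 25L),
                             threshold_grid = c(0.80, 0.85, 0.90, 0.95),
                             n_max = 100L) {
  params <- as_betabin_params(params)
  if (nrow(strata) == 0L) stop("'strata' must be non-empty", call. = FALSE)
  if (length(node_grid) > 0L &&
      (any(node_grid < 1) || any(diff(node_grid) <= 0)))
    stop("'node_grid' must be strictly increasing positive integers",
         call. = FALSE)
  if (length(threshold_grid) > 0L &&
      (any(threshold_grid <= 0) || any(threshold_grid >= 1) ||
       any(diff(threshold_grid) <= 0)))
    stop("'threshold_grid' must be strictly increasing in (0, 1)", call. = FALSE)

  base <- strata[, c("factor", "level", "corrected_prevalence")]
  nss_tab <- base
  for (n in node_grid) {
    nss_tab[[paste0("n", n)]] <- round_half_up(vapply(
      base$corrected_prevalence,
      function(pi) 100 * nss_value(n, pi, params), numeric(1L)), 1L)
  }
  need_tab <- base
  for (t in threshold_grid) {
    need_tab[[sprintf("nss%.0f", 100 * t)]] <- vapply(
      base$corrected_prevalence,
      function(pi) nodes_needed(t, pi, params, n_max), integer(1L))
  }
  list(nss = nss_tab, nodes_needed = need_tab)
}

#' Format a nodes-needed table for display
#'
#' Replaces unreachable (`NA`) cells with an em-dash, matching the
#' printed-table convention.
#'
#' @param tab The `nodes_needed` data frame from [build_nss_tables()].
#' @return A character data frame.
#' @export
format_nodes_needed <- function(tab) {
  out <- tab
  for (j in grep("^nss", names(out))) {
    out[[j]] <- ifelse(is.na(out[[j]]), "—", as.character(out[[j]]))
  }
  out
}
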