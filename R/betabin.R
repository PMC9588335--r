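# Beta-binomial model of positive-node counts.
#
# The number of positive nodes k among n examined is modelled as binomial
# with a per-patient success probability p drawn from Beta(alpha, beta);
# integrating p out gives the beta-binomial pmf.  All evaluation is done
# in log space through lbeta()/lchoose() so that large n and extreme
# shape parameters stay numerically stable.

#' Beta-binomial shape parameters
#'
#' Construct a validated pair of beta-binomial shape parameters.  The
#' latent per-patient metastasis probability of an individual node is a
#' Beta(alpha, beta) random variable; it is integrated out analytically
#' and never stored.
#'
#' @param alpha,beta Positive, finite shape parameters.
#' @return An object of class `"betabin_params"`: a list with elements
#'   `alpha` and `beta`.
#' @examples
#' betabin_params(1.51, 1.15)
#' @export
betabin_params <- function(alpha, beta) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop("'alpha' must be a single finite positive number", call. = FALSE)
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0)
    stop("'beta' must be a single finite positive number", call. = FALSE)
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta)),
            class = "betabin_params")
}

#' @export
print.betabin_params <- function(x, ...) {
  cat(sprintf("Beta-binomial shape parameters: alpha = %.4f, beta = %.4f\n",
              x$alpha, x$beta))
  invisible(x)
}

as_betabin_params <- function(params) {
  if (inherits(params, "betabin_params")) return(params)
  if (is.numeric(params) && length(params) == 2L)
    return(betabin_params(params[[1L]], params[[2L]]))
  stop("'params' must be a betabin_params object or a numeric vector of length 2",
       call. = FALSE)
}

#' Beta-binomial probability mass function
#'
#' Probability of observing `k` positive nodes among `n` examined under
#' the beta-binomial model, `choose(n, k) * B(k + alpha, n - k + beta) /
#' B(alpha, beta)`, evaluated via log-gamma.
#'
#' @param k Number of positive nodes, `0 <= k <= n`.  Vectorised.
#' @param n Number of nodes examined, `n >= 1`.  Vectorised.
#' @param params A [betabin_params()] object.
#' @param log If `TRUE`, return the log probability.
#' @return Probability (or log probability) of each `(k, n)` pair.
#' @examples
#' betabin_pmf(0, 1, betabin_params(1.51, 1.15))  # beta / (alpha + beta)
#' @export
betabin_pmf <- function(k, n, params, log = FALSE) {
  params <- as_betabin_params(params)
  if (length(k) == 0L || length(n) == 0L) return(numeric(0))
  pair <- recycle_kn(k, n)
  k <- pair$k; n <- pair$n
  if (any(n < 1)) stop("'n' must be >= 1", call. = FALSE)
  if (any(k < 0) || any(k > n)) stop("'k' must satisfy 0 <= k <= n", call. = FALSE)
  lp <- lchoose(n, k) +
    lbeta(k + params$alpha, n - k + params$beta) -
    lbeta(params$alpha, params$beta)
  if (log) lp else exp(lp)
}

recycle_kn <- function(k, n) {
  if (any(k != floor(k)) || any(n != floor(n)))
    stop("'k' and 'n' must be integer-valued", call. = FALSE)
  m <- max(length(k), length(n))
  list(k = rep_len(as.numeric(k), m), n = rep_len(as.numeric(n), m))
}

#' False-negative staging probability
#'
#' The probability that a truly node-positive patient shows zero positive
#' nodes among `n` examined: `p0(n) = B(alpha, beta + n) / B(alpha, beta)
#' = prod_{i=0}^{n-1} (beta + i) / (alpha + beta + i)`.  It equals 1 at
#' `n = 0` (no nodes examined, staging is always negative) and decreases
#' strictly towards 0 as more nodes are examined.
#'
#' @param n Number of nodes examined, `n >= 0`.  Vectorised.
#' @inheritParams betabin_pmf
#' @return The false-negative probability for each `n`.
#' @examples
#' staging_fn_prob(c(1, 3, 5, 8), betabin_params(1.51, 1.15))
#' @export
staging_fn_prob <- function(n, params, log = FALSE) {
  params <- as_betabin_params(params)
  if (length(n) == 0L) return(numeric(0))
  if (any(!is.finite(n)) || any(n < 0) || any(n != floor(n)))
    stop("'n' must be a nonnegative integer", call. = FALSE)
  lp <- lbeta(params$alpha, params$beta + n) - lbeta(params$alpha, params$beta)
  if (log) lp else exp(lp)
}

# log(1 - exp(lp)) without cancellation; lp <= 0
log1mexp <- function(lp) {
  ifelse(lp > -log(2), log(-expm1(lp)), log1p(-exp(lp)))
}

#' Zero-truncated beta-binomial log-likelihood
#'
#' Log-likelihood of beta-binomial positive-node counts conditioned on
#' at least one positive node being observed.  The model is fitted only
#' to node-positive patients, so every term is the log pmf minus
#' `log(1 - p0(n))`, the log probability of clearing the truncation.
#'
#' @param params A [betabin_params()] object or numeric `c(alpha, beta)`.
#' @param k Positive-node counts, all `>= 1`.
#' @param n Examined-node counts, aligned with `k`, each `>= k`.
#' @return The zero-truncated log-likelihood (a single number).
#' @seealso [fit_betabin_truncated()]
#' @export
betabin_truncated_loglik <- function(params, k, n) {
  params <- as_betabin_params(params)
  if (length(k) != length(n))
    stop("'k' and 'n' must have equal length", call. = FALSE)
  if (length(k) == 0L) stop("no records", call. = FALSE)
  if (any(k < 1)) stop("zero-truncated likelihood requires k >= 1", call. = FALSE)
  if (any(k > n)) stop("'k' must not exceed 'n'", call. = FALSE)
  lpmf <- betabin_pmf(k, n, params, log = TRUE)
  lp0 <- staging_fn_prob(n, params, log = TRUE)
  sum(lpmf) - sum(log1mexp(lp0))
}

#' Untruncated beta-binomial log-likelihood
#'
#' Companion to [betabin_truncated_loglik()] for simulation diagnostics
#' where node-negative patients are retained (k = 0 allowed).  Not used
#' for model fitting, which conditions on node positivity.
#'
#' @inheritParams betabin_truncated_loglik
#' @return The log-likelihood.
#' @export
betabin_loglik <- function(params, k, n) {
  sum(betabin_pmf(k, n, params, log = TRUE))
}

# Method-of-moments starting values from the observed ratios k/n.
# Truncation biases these; they only seed the optimiser.
mom_start <- function(k, n) {
  r <- k / n
  m <- mean(r)
  v <- stats::var(r)
  if (!is.finite(v) || v <= 0 || m <= 0 || m >= 1) return(c(1, 1))
  cc <- m * (1 - m) / v - 1
  if (!is.finite(cc) || cc <= 0) return(c(1, 1))
  pmax(pmin(c(m * cc, (1 - m) * cc), 50), 0.02)
}

#' Fit the beta-binomial model by zero-truncated maximum likelihood
#'
#' Maximises [betabin_truncated_loglik()] over `(log alpha, log beta)`
#' with BFGS, which enforces positivity without box constraints.  Three
#' deterministic starting points are used (method-of-moments on `k/n`,
#' the uniform prior `(1, 1)`, and an overdispersed point) to guard
#' against flat regions; the best finisher is returned.
#'
#' @param k Positive-node counts, all `>= 1` (node-positive patients only).
#' @param n Examined-node counts aligned with `k`.
#' @param start Optional starting `c(alpha, beta)`; replaces the
#'   method-of-moments start.
#' @param reltol Relative convergence tolerance passed to [stats::optim()].
#' @param max_param Estimates whose shapes exceed this bound are flagged
#'   as boundary solutions (`converged = FALSE`), which arises for
#'   degenerate inputs such as every examined node being positive.
#' @return An object of class `"betabin_fit"`: list with `params`
#'   ([betabin_params()]), `loglik`, `converged`, `n_patients`,
#'   `iterations`, `stderr_alpha`, `stderr_beta` (observed-information
#'   approximation via the numerically differentiated Hessian on the log
#'   scale, delta method back; `NA` when the Hessian is not positive
#'   definite).
#' @examples
#' set.seed(42)
#' sim <- simulate_positive_records(500, betabin_params(1.51, 1.15))
#' fit_betabin_truncated(sim$nodes_positive, sim$nodes_examined)
#' @export
fit_betabin_truncated <- function(k, n, start = NULL, reltol = 1e-12,
                                  max_param = exp(12)) {
  if (length(k) != length(n))
    stop("'k' and 'n' must have equal length", call. = FALSE)
  if (length(k) < 2L) stop("at least 2 records are required", call. = FALSE)
  if (any(k < 1) || any(k > n))
    stop("records must satisfy 1 <= k <= n", call. = FALSE)
  if (all(n == 1))
    stop(paste("all records have n = 1: the zero-truncated likelihood is",
               "constant and the parameters are not identifiable"),
         call. = FALSE)

  negll <- function(theta) {
    al <- exp(theta[1L]); be <- exp(theta[2L])
    if (!is.finite(al) || !is.finite(be)) return(.Machine$double.xmax)
    ll <- betabin_truncated_loglik(c(al, be), k, n)
    if (!is.finite(ll)) return(.Machine$double.xmax)
    -ll
  }

  starts <- list(log(mom_start(k, n)), c(0, 0), log(c(0.5, 0.5)))
  if (!is.null(start)) starts[[1L]] <- log(as.numeric(start))

  best <- NULL
  iters <- 0L
  for (s in starts) {
    o <- tryCatch(
      stats::optim(s, negll, method = "BFGS",
                   control = list(reltol = reltol, maxit = 500L)),
      error = function(e) NULL)
    if (is.null(o)) next
    iters <- iters + as.integer(o$counts[["function"]])
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) stop("optimisation failed from every start", call. = FALSE)

  est <- exp(best$par)
  at_boundary <- any(est > max_param) || any(est < 1 / max_param)
  if (at_boundary)
    warning("estimate at a parameter boundary; the fit is degenerate ",
            "(e.g. every examined node positive)", call. = FALSE)
  est <- pmin(pmax(est, 1 / max_param), max_param)

  se <- c(NA_real_, NA_real_)
  if (!at_boundary) {
    H <- tryCatch(stats::optimHess(log(est), negll), error = function(e) NULL)
    if (!is.null(H)) {
      ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
      if (all(ev > 0)) {
        # covariance on the log scale, delta method to the natural scale
        se <- sqrt(diag(solve(H))) * est
      }
    }
  }

  structure(list(
    params = betabin_params(est[1L], est[2L]),
    loglik = -best$value,
    converged = best$convergence == 0L && !at_boundary,
    n_patients = length(k),
    iterations = iters,
    stderr_alpha = se[1L],
    stderr_beta = se[2L]
  ), class = "betabin_fit")
}

#' @export
print.betabin_fit <- function(x, ...) {
  cat("Zero-truncated beta-binomial maximum-likelihood fit\n")
  cat(sprintf("  alpha = %.4f (se %.4f)\n", x$params$alpha, x$stderr_alpha))
  cat(sprintf("  beta  = %.4f (se %.4f)\n", x$params$beta, x$stderr_beta))
  cat(sprintf("  log-likelihood %.3f on %d node-positive patients; converged: %s\n",
              x$loglik, x$n_patients, x$converged))
  invisible(x)
}
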