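test_that("parameter construction rejects invalid shapes", {
  expect_error(betabin_params(0, 1), "alpha")
  expect_error(betabin_params(1, -2), "beta")
  expect_error(betabin_params(Inf, 1), "alpha")
  expect_error(betabin_params(NA_real_, 1), "alpha")
  p <- betabin_params(1.51, 1.15)
  expect_s3_class(p, "betabin_params")
  expect_equal(p$alpha, 1.51)
})

test_that("pmf matches closed forms and normalises", {
  p <- published_params()
  # k = 0 cases reduce to the product form of the false-negative probability
  expect_equal(betabin_pmf(0, 1, p), 1.15 / (1.51 + 1.15), tolerance = 1e-12)
  expect_equal(betabin_pmf(0, 5, p), p0_product(5, 1.51, 1.15),
               tolerance = 1e-12)
  # normalisation across a parameter grid, n up to 100
  for (ab in list(c(0.2, 0.3), c(1.51, 1.15), c(5, 0.5), c(20, 20))) {
    q <- betabin_params(ab[1], ab[2])
    for (n in c(1, 7, 100)) {
      expect_equal(sum(betabin_pmf(0:n, n, q)), 1, tolerance = 1e-12)
    }
  }
  expect_error(betabin_pmf(2, 1, p), "k")
  expect_error(betabin_pmf(0, 0, p), "n")
})

test_that("pmf approaches the binomial limit as dispersion vanishes", {
  M <- 1e6
  pr <- 0.3
  q <- betabin_params(pr * M, (1 - pr) * M)
  n <- 12
  expect_equal(betabin_pmf(0:n, n, q), dbinom(0:n, n, pr), tolerance = 1e-4)
})

test_that("false-negative probability agrees with the explicit product", {
  p <- published_params()
  ns <- c(0:10, 50, 200)
  expect_equal(staging_fn_prob(ns, p), p0_product(ns, 1.51, 1.15),
               tolerance = 1e-12)
  q <- betabin_params(0.4, 7)
  expect_equal(staging_fn_prob(ns, q), p0_product(ns, 0.4, 7),
               tolerance = 1e-12)
  expect_identical(staging_fn_prob(0, p), 1)
  # equals pmf at k = 0
  expect_equal(staging_fn_prob(1:30, p), betabin_pmf(0, 1:30, p),
               tolerance = 1e-14)
  expect_error(staging_fn_prob(-1, p), "nonnegative")
})

test_that("false-negative probability is monotone in n and in beta", {
  for (ab in list(c(1.51, 1.15), c(0.3, 2), c(8, 0.4))) {
    p <- betabin_params(ab[1], ab[2])
    v <- staging_fn_prob(0:60, p)
    expect_true(all(diff(v) < 0))
  }
  # increasing in beta at fixed alpha and n >= 1
  betas <- c(0.2, 0.5, 1.15, 3, 10)
  for (n in c(1, 5, 20)) {
    v <- vapply(betas, function(b) staging_fn_prob(n, betabin_params(1.51, b)),
                numeric(1))
    expect_true(all(diff(v) > 0))
  }
})

test_that("zero-truncated log-likelihood matches enumeration", {
  p <- published_params()
  # a single (k=1, n=1) record is certain under truncation
  expect_equal(betabin_truncated_loglik(p, 1, 1), 0, tolerance = 1e-12)
  expect_equal(betabin_truncated_loglik(betabin_params(3, 0.2), 1, 1), 0,
               tolerance = 1e-12)
  # uniform (alpha = beta = 1) case: pmf is 1/(n+1) for every k, so each
  # truncated term is (1/3) / (1 - 1/3) = 1/2 by direct enumeration
  expect_equal(betabin_truncated_loglik(betabin_params(1, 1),
                                        c(1, 2), c(2, 2)),
               log(1 / 2) + log(1 / 2), tolerance = 1e-12)
  expect_error(betabin_truncated_loglik(p, 0, 3), "k >= 1")
  expect_error(betabin_truncated_loglik(p, 4, 3), "exceed")
})

test_that("truncated fit agrees with a grid-search maximiser on small data", {
  set.seed(101)
  k <- c(1, 2, 1, 3, 1, 2, 4, 1, 2, 1)
  n <- c(2, 3, 1, 4, 3, 2, 4, 2, 4, 4)
  fit <- fit_betabin_truncated(k, n)
  grid <- exp(seq(log(0.05), log(20), length.out = 80))
  ll <- outer(grid, grid, Vectorize(function(a, b)
    betabin_truncated_loglik(c(a, b), k, n)))
  best <- which(ll == max(ll), arr.ind = TRUE)[1, ]
  # the optimiser must do at least as well as the grid, and land within
  # one grid spacing of the best grid point
  expect_gte(fit$loglik, max(ll) - 1e-8)
  spacing <- exp(diff(log(grid))[1])
  expect_lt(fit$params$alpha / grid[best[1]], spacing^2)
  expect_gt(fit$params$alpha / grid[best[1]], 1 / spacing^2)
  expect_lt(fit$params$beta / grid[best[2]], spacing^2)
  expect_gt(fit$params$beta / grid[best[2]], 1 / spacing^2)
  expect_true(fit$converged)
  expect_identical(fit$n_patients, 10L)
})

test_that("fit is invariant to record order and duplication", {
  set.seed(7)
  sim <- simulate_positive_records(300, published_params())
  f1 <- fit_betabin_truncated(sim$nodes_positive, sim$nodes_examined)
  o <- sample.int(nrow(sim))
  f2 <- fit_betabin_truncated(sim$nodes_positive[o], sim$nodes_examined[o])
  expect_equal(f1$params$alpha, f2$params$alpha, tolerance = 1e-6)
  expect_equal(f1$params$beta, f2$params$beta, tolerance = 1e-6)
  f3 <- fit_betabin_truncated(rep(sim$nodes_positive, 2),
                              rep(sim$nodes_examined, 2))
  expect_equal(f1$params$alpha, f3$params$alpha, tolerance = 1e-4)
  expect_equal(f1$params$beta, f3$params$beta, tolerance = 1e-4)
})

test_that("degenerate fitting sets are reported, not silently fitted", {
  p <- published_params()
  # all records with n = 1 carry no information under truncation
  expect_error(fit_betabin_truncated(rep(1, 10), rep(1, 10)),
               "not identifiable")
  # every examined node positive drives the fit to a boundary
  expect_warning(
    fit <- fit_betabin_truncated(c(2, 3, 4, 2, 5), c(2, 3, 4, 2, 5)),
    "boundary")
  expect_false(fit$converged)
  expect_true(all(is.finite(c(fit$params$alpha, fit$params$beta))))
  expect_error(fit_betabin_truncated(1, 2), "at least 2")
})
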