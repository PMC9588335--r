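test_that("generation is deterministic and respects the ground-truth contract", {
  cfg <- synth_config(n_patients = 2000, seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  # no false-positive nodes: truly negative patients show zero positives
  expect_true(all(a$nodes_positive[!a$true_positive] == 0))
  expect_true(all(a$nodes_positive <= a$nodes_examined))
  expect_true(all(a$nodes_examined >= 1))
  expect_true(all(a$followup_months >= 0))
})

test_that("degenerate prevalences behave as specified", {
  # pi = 0 everywhere: no positive nodes at all
  cfg0 <- synth_config(n_patients = 500, prevalence_factor = "gender",
                       stratum_prevalences = c(male = 0, female = 0),
                       seed = 9)
  expect_true(all(generate_cohort(cfg0)$nodes_positive == 0))
  # pi = 1 with 50 nodes examined: observed positivity above 1 - p0(50)
  cfg1 <- synth_config(n_patients = 2000, prevalence_factor = "gender",
                       stratum_prevalences = c(male = 1, female = 1),
                       node_law = list(fixed = 50), seed = 10)
  coh <- generate_cohort(cfg1)
  expect_gt(mean(coh$nodes_positive >= 1), 0.99)
})

test_that("joint prevalence calibration hits every factor-level marginal", {
  cfg <- synth_config(n_patients = 30000, seed = 2024)
  coh <- generate_cohort(cfg)
  targets <- nodalstaging:::default_prevalences()
  for (f in names(targets)) {
    for (l in names(targets[[f]])) {
      i <- coh[[f]] == l
      expect_equal(mean(coh$true_positive[i]), targets[[f]][[l]],
                   tolerance = 0.035)
    }
  }
})

test_that("cohort summary mirrors the baseline-table layout", {
  coh <- tiny_cohort()
  s <- cohort_summary(coh, factors = "gender")
  expect_identical(sort(s$level), c("female", "male"))
  expect_equal(sum(s$pct), 100)
  expect_identical(sum(s$ln_positive), 2L)
  one <- cohort_summary(coh[1, ], factors = "gender")
  expect_identical(one$n, 1L)
  expect_equal(one$median_nodes, 3)
  # examined-node quartiles at scale approach the configured law
  cfg <- synth_config(n_patients = 20000, seed = 5)
  big <- cohort_summary(generate_cohort(cfg), factors = "t_stage")
  t4 <- big[big$level == "T4", ]
  expect_true(t4$median_nodes %in% 3:5)
  expect_true(t4$q3_nodes %in% 11:16)
})

test_that("occult rate matches the Bayes identity at fixed n", {
  p <- published_params()
  pi <- 0.6
  for (n in c(1, 5)) {
    cfg <- synth_config(n_patients = 60000, prevalence_factor = "gender",
                        stratum_prevalences = c(male = pi, female = pi),
                        node_law = list(fixed = n), seed = 300 + n)
    coh <- generate_cohort(cfg)
    expect_equal(occult_rate(coh), 1 - nss_value(n, pi, p), tolerance = 0.02)
  }
  # all truly negative: occult rate is zero
  cfg0 <- synth_config(n_patients = 200, prevalence_factor = "gender",
                       stratum_prevalences = c(male = 0, female = 0), seed = 1)
  expect_identical(occult_rate(generate_cohort(cfg0)), 0)
  coh <- tiny_cohort()
  coh$true_positive <- NULL
  expect_error(occult_rate(coh), "ground-truth")
})

test_that("end-to-end refit recovers the generating quantities", {
  p <- published_params()
  cfg <- synth_config(n_patients = 12000, seed = 88)
  coh <- generate_cohort(cfg)
  posi <- coh$nodes_positive >= 1
  fit <- fit_betabin_truncated(coh$nodes_positive[posi],
                               coh$nodes_examined[posi])
  expect_true(fit$converged)
  expect_lt(abs(fit$params$alpha - 1.51), 0.15)
  expect_lt(abs(fit$params$beta - 1.15), 0.10)
  # corrected prevalence recovers the generating marginals per stratum
  st <- stratum_estimates(coh, fit$params, c("gender", "t_stage"))
  targets <- nodalstaging:::default_prevalences()
  for (i in seq_len(nrow(st))) {
    expect_equal(st$corrected_prevalence[i],
                 targets[[st$factor[i]]][[st$level[i]]], tolerance = 0.04)
  }
})

test_that("config validation rejects malformed specifications", {
  expect_error(synth_config(n_patients = 100), "seed")
  expect_error(synth_config(prevalence_factor = "gender",
                            stratum_prevalences = c(male = 1.2, female = 0.5),
                            seed = 1), "\\[0, 1\\]")
  expect_error(synth_config(missing_size_frac = 2, seed = 1), "\\[0, 1\\]")
  expect_error(synth_config(node_law = list(factor = "nope", levels = list()),
                            seed = 1), "covariate")
})

test_that("simulated node-positive records satisfy the truncation contract", {
  set.seed(2)
  sim <- simulate_positive_records(4000, published_params())
  expect_true(all(sim$nodes_positive >= 1))
  expect_true(all(sim$nodes_positive <= sim$nodes_examined))
  expect_true(all(sim$nodes_examined <= 25))
  expect_true(median(sim$nodes_examined) %in% 2:4)
})
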