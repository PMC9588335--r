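---
title: "Nodal staging scores for occult lymph-node metastasis: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nodal staging scores for occult lymph-node metastasis: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nodalstaging)
```

## The problem

In papillary thyroid carcinoma (PTC), cervical lymph-node metastasis is
common and drives both prognosis and the extent of surgery. A patient whose
examined nodes are all negative (pN0) may still harbour occult metastases:
with few nodes examined, a truly node-positive patient can easily show zero
positive nodes. The question a surgeon faces is therefore not "were the
examined nodes negative?" but "given that `n` examined nodes were negative,
how confident can I be that the patient is truly node-negative?" — and,
turned around, "how many nodes must be examined to reach a target level of
confidence?"

This package answers both questions with a nodal staging score (NSS): the
posterior probability of true node negativity given an all-negative
examination of `n` nodes.

## The model

### Positive-node counts are beta-binomial

Among truly node-positive patients, the number of positive nodes `k` out of
`n` examined is modelled as binomial with a per-patient involvement
probability `p` that varies between patients as `p ~ Beta(α, β)`.
Marginalising `p` gives the beta-binomial

$$
P(k \mid n) = \binom{n}{k}\,
  \frac{B(k + \alpha,\; n - k + \beta)}{B(\alpha, \beta)},
$$

which captures the overdispersion real nodal data show (some patients have
nearly every node involved, others a single one). Three assumptions carry
the whole construction: no false-positive nodes, exchangeable nodes (every
node equally likely to be involved), and equally sensitive examinations.

### The false-negative staging probability

Setting `k = 0`,

$$
p_0(n) = \frac{B(\alpha, \beta + n)}{B(\alpha, \beta)}
       = \prod_{i=0}^{n-1} \frac{\beta + i}{\alpha + \beta + i}
$$

is the probability that a truly node-positive patient is staged pN0 after
`n` nodes are examined. It is 1 at `n = 0` and strictly decreasing; it does
not depend on any covariate. `staging_fn_prob()` evaluates it through
log-gamma; the test suite pins it against the explicit product form to
1e-12 up to `n = 200`.

### Zero-truncated maximum likelihood

The shapes are estimated only from node-positive patients (`k ≥ 1`),
because the node-negative group mixes truly negative patients with occult
false negatives in unknown proportions. The likelihood is therefore
conditioned on clearing the truncation:

$$
\ell(\alpha, \beta) = \sum_i \Big[ \log P(k_i \mid n_i)
  - \log\big(1 - p_0(n_i)\big) \Big].
$$

`fit_betabin_truncated()` maximises this over `(log α, log β)` with BFGS —
the log scale enforces positivity without box constraints — from three
deterministic starts (method-of-moments on `k/n`, the uniform `(1, 1)`, and
an overdispersed point). Records with `n = 1` carry no information under
truncation (the conditional probability is 1 for any parameters), so a
fitting set consisting solely of them is rejected as non-identifiable
rather than returning an arbitrary boundary value; a set where every
examined node is positive drives the likelihood to a boundary and is
flagged `converged = FALSE` with a warning. Standard errors come from the
numerically differentiated Hessian on the log scale, delta-method back.

`1 − p₀` is computed as `-expm1(log p₀)` when `p₀` is large, so the
truncation correction stays accurate for records with a single examined
node.

### Prevalence correction

The observed per-stratum metastasis prevalence understates the truth,
because some truly positive patients are staged pN0. The package uses the
moment estimator

$$
\hat\pi = \frac{\#\{\text{observed positive}\}}
               {\sum_i \big(1 - p_0(n_i)\big)},
$$

summing over *all* patients of the stratum: it solves the unbiased
estimating equation
$E[\#\text{positive}] = \pi \sum_i (1 - p_0(n_i))$. The estimator always
lies at or above the observed prevalence and is clipped at 1 (with a
warning) when sampling noise in a small, high-prevalence stratum pushes it
beyond. An EM formulation would be asymptotically equivalent here; the
moment estimator was preferred for transparency and because the correction
direction and magnitude it produces match the published adjusted
incidences.

### The nodal staging score

Bayes' rule combines the two pieces. With prior prevalence `π` and an
all-negative examination of `n` nodes,

$$
\mathrm{NSS}(n) = \frac{1 - \pi}{(1 - \pi) + \pi\, p_0(n)},
$$

the posterior probability of true node negativity — a negative predictive
value. At `n = 0` it is the prior `1 − π`; it rises monotonically towards 1.
`nodes_needed()` inverts the curve: the smallest `n` with
`NSS(n) ≥ threshold`, scanning up to `n_max` (default 100; beyond that the
answer is reported as unreachable, rendered as an em-dash in formatted
tables — high-prevalence strata such as T4 cannot reach high thresholds at
realistic dissection extents). Ties count as reached (`≥`). Table
percentages are rounded half-up to one decimal, matching how such tables
are conventionally printed; raw values stay available in the unformatted
output.

```{r}
p <- betabin_params(1.51, 1.15)
round_half_up(100 * nss_value(c(1, 5, 10, 15, 20, 25), 0.776, p), 1)
nodes_needed(0.90, 0.776, p)
```

## The synthetic cohort

No patient-level data ship with the package; `generate_cohort()` draws a
synthetic cohort with exactly the generative structure the analysis
assumes, plus ground-truth labels that real data cannot have.

- **Covariates.** Six factors (gender, age group, extrathyroidal
  invasion, multifocality, tumour-size category, T stage) drawn
  independently at the published marginal frequencies. Tumour size is
  masked to `"missing"` in 6.9% of patients *after* the truth is drawn, so
  missingness is non-informative.
- **True positivity.** Each patient's probability of truly harbouring
  metastasis sits on a logit-additive scale over all six factors,
  calibrated by cyclic fixed-point updates until every factor-level
  marginal matches its published corrected incidence (e.g. males 77.6%,
  T4 95.7%). Passing a plain named vector instead makes the levels of one
  factor exactly homogeneous — the configuration the oracle experiments
  use, since the Bayes identity `1 − NSS(n)` = occult fraction holds
  exactly only under within-stratum homogeneity.
- **Examined nodes.** Zero-truncated negative binomial keyed by T stage,
  with `(size, mu)` chosen by grid search so the truncated quartiles match
  the published per-T-stage medians and IQRs (T1 1–2–5 up to T4 2–4–14).
  Keying by T stage reproduces the fact that node-positive patients have
  more nodes examined (they have higher T stages), at the cost that the
  male/female median difference is not separately reproduced.
- **Positive nodes.** Truly positive patients draw `k` from the
  beta-binomial at shapes (1.51, 1.15); `k = 0` *is* the occult false
  negative. Truly negative patients always have `k = 0`. Only the fitting
  set conditions on `k ≥ 1`; generation never does.
- **Survival.** Exponential with baseline hazard 0.002/month, hazard ratio
  2.0 for true node positivity, and uniform administrative censoring over
  120 months — a deliberately minimal fixture in which true metastasis
  status is the *only* prognostic signal.

What the generator does **not** emulate: correlation between covariates
(real T stage and size are strongly dependent), per-compartment nodal
anatomy (central vs lateral vs mediastinal), calendar-time or geographic
structure, and non-exponential hazards. Passing tests therefore validate
the estimators under the model's own assumptions; they cannot certify
behaviour under the violations real registries exhibit.

## The survival comparison

`survival_by_nss()` scores each patient at their own examined-node count
with their stratum's curve, cuts the scores at the empirical quartiles
(ties to the lower group), and compares overall survival across the four
groups with a directly implemented log-rank test (hypergeometric
observed-minus-expected at each event time; quadratic form with the last
group dropped; chi-square with 3 degrees of freedom). The Kaplan-Meier
and log-rank routines are pinned against the survival package on random
datasets in the test suite.

By default only observed pN0 patients enter the comparison. This is a
considered choice: the NSS is a negative predictive value, defined for
patients whose examined nodes were all negative, and among them the score
orders the risk of occult residual disease (at quartile level roughly 50%
down to 5% truly positive in the default cohort). Including observed
node-positive patients is supported (`ln_negative_only = FALSE`) but
uninformative by construction in the synthetic cohort: their true status
is independent of how many nodes were examined, so quartiles would differ
only in covariate mix. The T-stage comparison is the featured one — its
corrected incidences span 0.42 to 0.96, giving the steepest occult-risk
gradient across quartiles; the other five factors are run alongside.

## Numerical and design choices

- All pmf and likelihood evaluation in log space via `lbeta`/`lchoose`;
  optimisation tolerance `reltol = 1e-12`; estimates beyond `exp(±12)`
  treated as boundary solutions.
- Quartile cut points use the default empirical quantile; with heavily
  discrete scores the groups can be unequal (reported, never rebalanced),
  and a stratum whose corrected prevalence clipped at 1 yields a constant
  zero NSS, which the grouping handles by reporting an empty quartile.
- Problem sizes in the test suite: parameter recovery uses 50 replicates
  of 5,000 node-positive patients; the Bayes-consistency oracle uses
  200,000 patients per examined-node count; null calibration of the
  log-rank uses 400 replicates of 2,000 patients and the power check 20
  replicates at the full cohort size of 12,431 — sizes chosen so
  Monte-Carlo error is well inside the asserted tolerances.
- The binomial lower envelope is used for replicate-count assertions
  (e.g. 17/20 rejections is the 2.5% envelope of a 95% rejection rate),
  so stochastic checks fail on genuine defects rather than on sampling
  noise.

## Limitations

The model's exchangeability assumption is known to be wrong in detail for
PTC (central-compartment nodes are involved more often than lateral or
mediastinal ones); the NSS is a whole-neck summary. The shapes `(α, β)`
are global, not covariate-dependent — strata share one false-negative
curve and differ only in prevalence. No confidence intervals are attached
to NSS values or nodes-needed counts, and recurrence is out of scope. The
corrected-prevalence estimator assumes within-stratum homogeneity; under
the joint generator the detectability weighting biases it upward by about
one percentage point in strata whose node counts correlate with prevalence
through T stage — visible, and documented, rather than hidden.
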