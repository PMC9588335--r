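# nodalstaging

Nodal staging scores (NSS) for occult cervical lymph-node metastasis in
papillary thyroid carcinoma (PTC).

A pN0 staging result — every examined node negative — does not prove a
patient is free of nodal metastasis: with few nodes examined, a truly
node-positive patient easily shows none. This package quantifies that
residual risk for surgeons and biostatisticians working with
registry-style cohorts. It models positive-node counts among
node-positive patients as beta-binomial,

    P(k | n) = C(n,k) · B(k+α, n−k+β) / B(α,β),

fits (α, β) by **zero-truncated maximum likelihood** (the fitting set is
conditioned on k ≥ 1), derives the false-negative staging probability

    p0(n) = ∏_{i=0}^{n−1} (β+i)/(α+β+i),

corrects each stratum's observed metastasis prevalence for occult false
negatives (π̂ = #observed-positive / Σ(1−p0(nᵢ))), and combines the two
by Bayes' rule into the nodal staging score

    NSS(n) = (1−π) / ((1−π) + π·p0(n)),

the posterior probability that a patient with n negative examined nodes
is truly node-negative. Inverting the curve gives the number of nodes
that must be examined to reach a target negative predictive value. A
synthetic SEER-like cohort generator (with ground-truth occult labels)
and a Kaplan–Meier / log-rank comparison of overall survival across NSS
quartiles complete the pipeline.

## Worked example

```r
library(nodalstaging)

p <- betabin_params(1.51, 1.15)          # fitted beta-binomial shapes

# false-negative staging probability after 1, 3, 5, 8 examined nodes
round(100 * staging_fn_prob(c(1, 3, 5, 8), p), 1)
#> [1] 43.2 17.2  9.7  5.4

# NSS for a male patient (corrected prevalence 77.6%) by nodes examined
round_half_up(100 * nss_value(c(1, 5, 10, 15, 20, 25), 0.776, p), 1)
#> [1] 40.0 74.8 87.6 92.5 94.8 96.2

# nodes needed for a 90% negative predictive value
nodes_needed(0.90, 0.776, p)   # males
#> [1] 12
nodes_needed(0.90, 0.538, p)   # females
#> [1] 6
```

So a male pN0 patient with a single examined node still has a 60% chance
of harbouring occult metastasis (NSS 40.0%), and 12 nodes must be
examined before his negative staging is 90% credible; for females, whose
corrected prevalence is lower, 6 nodes suffice.

## The analysis workflow

The `analysis/` scripts run the full study on a synthetic cohort and
write their tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R   # 12,431 synthetic patients
Rscript analysis/02_fit_betabin.R       # zero-truncated ML fit on LN+ patients
Rscript analysis/03_nss_tables.R        # corrected prevalences, NSS tables
Rscript analysis/04_survival.R          # log-rank across NSS quartiles
```

On the default cohort (seed 20260924) the fit recovers
α̂ = 1.539 (se 0.073), β̂ = 1.159 (se 0.044) from 5,660 node-positive
patients; the corrected incidence exceeds the observed incidence in all
16 strata (median +13.7 points); and the four-group log-rank across NSS
quartiles of observed pN0 patients rejects for every factor, e.g.
χ² = 19.23 (df = 3, p = 0.00025) for T stage.

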