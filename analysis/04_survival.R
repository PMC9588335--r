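#!/usr/bin/env Rscript
# Step 4: overall survival across NSS quartiles.
#
# For each clinicopathological factor, observed node-negative patients
# are grouped by quartiles of their NSS and compared by the four-group
# log-rank test; per-group Kaplan-Meier curves are exported.

library(nodalstaging)

cohort <- read_cohort("scratch/cohort.tsv")
fit_tab <- read.delim("results/betabin_fit.tsv")
params <- betabin_params(fit_tab$alpha, fit_tab$beta)

strata <- stratum_estimates(cohort, params)
dir.create("results/survival", showWarnings = FALSE)

for (f in unique(strata$factor)) {
  s <- survival_by_nss(cohort, strata, params, f)
  cat(sprintf("%-11s log-rank chi2 = %6.2f, df = %d, p = %.2g  (groups: %s)\n",
              f, s$test$statistic, s$test$df, s$test$p_value,
              paste(s$group_sizes, collapse = "/")))
  for (l in names(s$km)) {
    write.table(s$km[[l]],
                sprintf("results/survival/km_%s_%s.tsv", f, l),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
}
cat("Kaplan-Meier curves written to results/survival/\n")
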