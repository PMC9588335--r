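#!/usr/bin/env Rscript
# Step 2: fit the beta-binomial model to the node-positive patients.
#
# Zero-truncated maximum likelihood on (k, n) of every patient with at
# least one positive node; exports the fitted shapes and the
# false-negative probability curve p0(n).

library(nodalstaging)

cohort <- read_cohort("scratch/cohort.tsv")
pos <- cohort$nodes_positive >= 1

fit <- fit_betabin_truncated(cohort$nodes_positive[pos],
                             cohort$nodes_examined[pos])
print(fit)

curve <- data.frame(nodes_examined = 0:60,
                    fn_prob = staging_fn_prob(0:60, fit$params))
write.table(curve, "results/false_negative_curve.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(data.frame(alpha = fit$params$alpha, beta = fit$params$beta,
                       loglik = fit$loglik, n = fit$n_patients,
                       converged = fit$converged),
            "results/betabin_fit.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)

cat(sprintf("False-negative probability at n = 1, 3, 5, 8: %s\n",
            paste(sprintf("%.1f%%",
                          100 * staging_fn_prob(c(1, 3, 5, 8), fit$params)),
                  collapse = ", ")))
cat("Curve written to results/false_negative_curve.tsv\n")
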