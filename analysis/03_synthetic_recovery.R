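#!/usr/bin/env Rscript
# End-to-end validation on synthetic data with known ground truth: generate
# a fragmented system of 32 states x 6 institutions (three nationwide,
# three partial - the presence profile that yields ~153 DMUs), with each
# unit radially inflated from a common CRS frontier by a known 1/theta*,
# then re-estimate every efficiency and quantify recovery. Also runs the
# annual-variation summary on a 7-year synthetic series.
#
# Run from the repository root: Rscript analysis/03_synthetic_recovery.R

library(deacare)

g <- generate_panel(synthesis_spec(n_states = 32, seed = 7))
cat("synthetic DMUs (excl. anchors):", sum(g$presence), "\n")

th <- efficiency_scores(dea_frontier(g$panel))
err <- abs(th[names(g$truth)] - g$truth)
cat(sprintf("recovery: max |theta_hat - theta*| = %.2e over %d units\n",
            max(err), length(err)))

rec <- data.frame(dmu_id = names(g$truth),
                  theta_true = unname(g$truth),
                  theta_hat = unname(th[names(g$truth)]),
                  abs_error = unname(err))
dir.create("results", showWarnings = FALSE)
write.csv(rec, "results/synthetic_recovery.csv", row.names = FALSE)

# Pipeline round trip: scores -> matrix -> aggregates, on known truth
fr <- dea_frontier(g$panel)
df <- as.data.frame(fr)
mat <- as_efficiency_matrix(df[df$institution != "ANCHOR", ])
s <- summarize_efficiency(mat)
print(s)

# Temporal stability demo: 7 yearly panels with 5% lognormal noise on a
# constant base. Institution totals pool the noise of all that
# institution's units, so their CV shrinks to roughly 0.05 / sqrt(units
# per institution) (~0.01 here); a single-unit series keeps CV ~ 0.05.
set.seed(7)
years <- as.character(2012:2018)
base <- as.data.frame(g$panel)[, -1]
yearly <- lapply(setNames(years, years), function(y) {
  d <- base
  dims <- setdiff(names(d), c("institution", "state"))
  d[dims] <- d[dims] * matrix(rlnorm(nrow(d) * length(dims), 0, 0.05),
                              nrow(d))
  dea_panel(d, inputs = g$panel$input_dims, outputs = g$panel$output_dims)
})
av <- annual_variation(yearly)
cat(sprintf("median CV of yearly institution totals: %.3f (unit-level noise sd 0.05, pooled over ~%d units)\n",
            median(av$cv$cv), round(mean(table(base$institution)))))
write.csv(av$cv, "results/annual_variation_cv.csv", row.names = FALSE)
cat("wrote results/synthetic_recovery.csv, results/annual_variation_cv.csv\n")
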