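#!/usr/bin/env Rscript

# Binomial null model for tubulin occupancy of IFT trains.
#
# Worked examples at p_bound = 1/2; the predicted occupancy-vs-length curve
# under length-independent per-particle binding (trains shrink with length,
# N = 16 - 9.96 log10 L); and recovery of the per-particle binding
# probability from synthetic occupancy tables.
#
# Writes: results/occupancy_curve.csv
#         results/occupancy_recovery.csv

suppressPackageStartupMessages(library(flagbalance))
dir.create("results", showWarnings = FALSE)

cat("Worked examples at p_bound = 0.5:\n")
for (N in c(1, 2, 4)) {
  cat(sprintf("  N = %d particles/train -> occupancy %.4g%%\n",
              N, 100 * occupancy_probability(0.5, N)))
}

# Null-model occupancy curve: even with constant per-particle binding,
# train occupancy falls with flagellar length because trains get smaller.
curve <- predict_occupancy_curve(0.5, seq(2, 30, length.out = 100))
write.csv(curve, "results/occupancy_curve.csv", row.names = FALSE)
cat(sprintf("\nPredicted occupancy falls from %.3f at 2 um to %.3f at 30 um\n",
            curve$predicted_occupancy[1],
            tail(curve$predicted_occupancy, 1)))

# Parameter recovery: 100 seeded synthetic datasets per the study layout
# (20 log-spaced lengths, 50 trains each), p_bound in {0.2, 0.5, 0.8}.
ps <- rep(c(0.2, 0.5, 0.8), length.out = 100)
rec <- do.call(rbind, lapply(seq_along(ps), function(i) {
  d <- make_occupancy_dataset(ps[i], seed = 1000 + i)
  est <- suppressWarnings(estimate_p_bound(d$data))
  data.frame(seed = 1000 + i, p_true = ps[i], p_est = est$p_bound,
             n_used = est$n_used, n_saturated = est$n_excluded_full,
             r_squared = est$r_squared)
}))
write.csv(rec, "results/occupancy_recovery.csv", row.names = FALSE)

err <- abs(rec$p_est - rec$p_true)
cat(sprintf("\nBinding-probability recovery over %d datasets:\n", nrow(rec)))
cat(sprintf("  median |error| %.4f (by truth: %s)\n", median(err),
            paste(sprintf("%.2f -> %.4f", unique(ps),
                          tapply(err, rec$p_true, median)), collapse = ", ")))
cat("  log10 P_empty is linear in N by construction; saturated rows\n")
cat("  (all trains occupied) are excluded and counted per dataset.\n")
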