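#!/usr/bin/env Rscript

# Injection-scaling analysis of the long-flagella mutants.
#
# Part A reproduces the published strain-comparison tables from the printed
# per-strain statistics (mean lengths and mean log10 deviations from the
# wild-type trend lines), chaining each injection fold change through the
# balance-point model with D/A = 8.
#
# Part B re-runs the identical pipeline on a synthetic dataset with planted
# folds to show the whole chain recovers known truth from raw
# per-flagellum measurements.
#
# Writes: results/table_injection_printed.csv
#         results/table_predictions_printed.csv
#         results/table_injection_synthetic.csv
#         results/table_predictions_synthetic.csv

suppressPackageStartupMessages(library(flagbalance))
dir.create("results", showWarnings = FALSE)

## Part A: printed per-strain statistics -------------------------------------
printed <- printed_strain_stats()
su <- summaries_from_printed(printed, d_over_a = 8)
t_inj <- format_injection_table(su)
t_pred <- format_prediction_table(su)
write.csv(t_inj, "results/table_injection_printed.csv", row.names = FALSE)
write.csv(t_pred, "results/table_predictions_printed.csv", row.names = FALSE)

cat("Injection fold changes (from printed deviations):\n")
print(t_inj, row.names = FALSE)
cat("\nPredicted vs observed length fold changes (D/A = 8):\n")
print(t_pred, row.names = FALSE)
cat("\nEvery mutant's predicted length increase falls short of the one",
    "\nobserved (e.g. 1.5 predicted vs 1.8 observed for lf1): increased IFT",
    "\ninjection explains part, not all, of the length phenotype.\n\n")

## Part B: synthetic end-to-end with planted folds ----------------------------
ds <- make_scaling_dataset(seed = 2026)
res <- run_pipeline(measurements = ds$data)
write.csv(res$table_injection, "results/table_injection_synthetic.csv",
          row.names = FALSE)
write.csv(res$table_predictions, "results/table_predictions_synthetic.csv",
          row.names = FALSE)

planted <- ds$truth$folds[c("lf1", "lf2-1", "lf4")]
rec <- res$summaries$fold_injection_slope1[
  match(names(planted), res$summaries$strain)]
cat("Synthetic recovery of planted injection folds (slope -1 fit):\n")
for (i in seq_along(planted)) {
  cat(sprintf("  %-6s planted %.2f recovered %.2f\n",
              names(planted)[i], planted[i], rec[i]))
}
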