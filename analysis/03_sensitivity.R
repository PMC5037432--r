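#!/usr/bin/env Rscript
# Sensitivity re-analysis on a constructed synthetic dataset: five clean
# studies plus one study whose controls violate Hardy-Weinberg equilibrium
# (and carry an inflated odds ratio) and one non-white-population study.
# Excluding the flagged studies should pull the pooled OR back toward the
# design value.

suppressPackageStartupMessages(library(credmeta))
dir.create("results", showWarnings = FALSE)

set.seed(303)
clean <- simulate_meta_dataset(simulation_design(k = 5, true_or = 1.6,
                                                 seed = 303))
extra <- data.frame(
  variant_id = "rs_sim", gene = "SIM", phenotype = "CD",
  study_id = c("hwe_violator", "nonwhite_study"),
  ethnicity = c("white", "African American"),
  case_wtwt = c(120, 160), case_wtvar = c(220, 170), case_varvar = c(160, 170),
  control_wtwt = c(620, 480), control_wtvar = c(180, 430),
  control_varvar = c(200, 90), carrier_only = FALSE, stringsAsFactors = FALSE)
ds <- new_dataset(rbind(clean$records, extra), clean$variants,
                  provenance = "synthetic sensitivity battery")

cfg <- pipeline_config()
full <- run_pipeline(ds, cfg)
crit <- exclusion_criteria(drop_hwe_violating = TRUE, drop_non_white = TRUE)
excl <- apply_exclusions(ds, crit)
cat("excluded studies:\n")
print(excl$log[, c("study_id", "reason")])
reduced <- run_pipeline(excl$dataset, cfg)

cmp <- sensitivity_compare(full, reduced, alpha = cfg$alpha)
write.table(cmp$models, "results/sensitivity_deltas.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(cmp$verdicts, "results/sensitivity_verdicts.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

dom <- cmp$models[cmp$models$model == "dominant", ]
cat(sprintf("\ndominant model: OR %.3f -> %.3f (design value 1.6)\n",
            dom$or_full, dom$or_reduced))
cat(sprintf("significance flips: %d; tier flips: %d\n",
            sum(cmp$models$sig_flip), sum(cmp$verdicts$tier_flip)))
cat("wrote results/sensitivity_deltas.tsv, results/sensitivity_verdicts.tsv\n")
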