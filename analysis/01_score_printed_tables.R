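#!/usr/bin/env Rscript
# Re-scores the published paediatric CD and UC per-model summary tables
# through the credibility layer (BFDP, Venice grades, three-tier
# classification) and writes the verdicts and formatted summary tables.

suppressPackageStartupMessages(library(credmeta))
dir.create("results", showWarnings = FALSE)

cfg <- pipeline_config()

for (phen in c("CD", "UC")) {
  rows <- load_printed_summaries(phen)
  scored <- score_reported(rows, cfg)
  write_summary_table(scored$models,
                      file.path("results", sprintf("%s_summary.tsv", tolower(phen))))
  write.table(scored$verdicts,
              file.path("results", sprintf("%s_verdicts.tsv", tolower(phen))),
              sep = "\t", row.names = FALSE, quote = FALSE)

  tiers <- table(factor(scored$verdicts$tier,
                        c("highly_credible", "less_credible", "not_credible")))
  cat(sprintf("\n== paediatric %s: %d variants ==\n", phen,
              nrow(scored$verdicts)))
  print(tiers)
  cat(sprintf("significant in >=2 eligible models: %d\n",
              sum(scored$verdicts$n_significant_models >= 2)))
  hc <- scored$verdicts[scored$verdicts$tier == "highly_credible", ]
  if (nrow(hc)) {
    cat("highly credible:",
        paste(sprintf("%s/%s", hc$gene, hc$variant_id), collapse = ", "), "\n")
  }
  lc <- scored$verdicts[scored$verdicts$tier == "less_credible", ]
  if (nrow(lc)) {
    cat("less credible:  ",
        paste(sprintf("%s/%s", lc$gene, lc$variant_id), collapse = ", "), "\n")
  }
}
cat("\nwrote results/{cd,uc}_summary.tsv, results/{cd,uc}_verdicts.tsv\n")
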