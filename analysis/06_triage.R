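#!/usr/bin/env Rscript
# Full cascade in one call: the staged triage over the complete input
# bundle, with the per-compound audit trail and final candidate list.

source("analysis/00_config.R")

report <- run_triage(study_bundle, study_config)
print(report)

write_triage_report(report, file.path(OUT_DIR, "triage"))

stage_cols <- c("toxicity", "luc_qpcr_a1", "specificity_a6", "snca_qpcr_wt",
                "protein_icw", "protein_wb")
hits_only <- report$stages[report$stages$luc_class != "inactive", ]
cat("\nFunnel over", nrow(hits_only), "primary hits:\n")
for (s in stage_cols) {
  v <- hits_only[[s]]
  cat(sprintf("  %-15s pass %3d  fail %3d  n/a %3d\n", s,
              sum(v == "pass", na.rm = TRUE),
              sum(grepl("^fail", v), na.rm = TRUE),
              sum(is.na(v))))
}

truth <- read.csv(file.path(OUT_DIR, "simulated", "ground_truth.csv"))
expected <- sort(truth$compound_id[truth$final_candidate])
cat("\nGround-truth candidate set:", paste(expected, collapse = ", "), "\n")
cat("Recovered candidate set:   ",
    paste(report$final_candidates, collapse = ", "), "\n")
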