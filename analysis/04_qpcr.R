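#!/usr/bin/env Rscript
# Relative expression analysis: reporter (LUC) qPCR in the screening (A1)
# and counter-screen (A6) lines for the surviving hits, then SNCA qPCR in
# wildtype cells, all Pfaffl-normalized to the housekeeping panels and
# Dunnett-tested against DMSO.

source("analysis/00_config.R")

hits <- read.csv(file.path(OUT_DIR, "hit_table.csv"))
tox <- read.csv(file.path(OUT_DIR, "toxicity_table.csv"))
survivors <- c(
  hits$compound_id[hits$classification == "activator"],
  setdiff(hits$compound_id[hits$classification == "inhibitor"],
          tox$compound_id[tox$toxic]))
cat(length(survivors), "compounds enter the qPCR assays\n")

qpcr_summary <- function(ct_table, target, refs, label) {
  keep <- ct_table$condition == "DMSO" | ct_table$compound_id %in% survivors
  rs <- relative_expression_samples(ct_table[keep, ], target, refs)
  dn <- dunnett_test(rs$ratio,
                     ifelse(rs$condition == "DMSO", "DMSO", rs$compound_id),
                     control = "DMSO")
  ratios <- relative_expression_table(ct_table[keep, ], target, refs)
  out <- merge(ratios[, c("compound_id", "ratio")],
               dn[, c("group", "adjusted_p", "stars")],
               by.x = "compound_id", by.y = "group")
  names(out)[2] <- paste0("ratio_", label)
  names(out)[3] <- paste0("p_", label)
  names(out)[4] <- paste0("stars_", label)
  out
}

a1 <- qpcr_summary(study_bundle$qpcr_a1, study_config$target_luc,
                   study_config$refs_luc, "a1")
a6 <- qpcr_summary(study_bundle$qpcr_a6, study_config$target_luc,
                   study_config$refs_luc, "a6")
wt <- qpcr_summary(study_bundle$qpcr_wt, study_config$target_wt,
                   study_config$refs_wt, "wt")
qpcr <- Reduce(function(x, y) merge(x, y, by = "compound_id"),
               list(a1, a6, wt))
write.csv(qpcr, file.path(OUT_DIR, "qpcr_table.csv"), row.names = FALSE)

sig_a1 <- qpcr$compound_id[qpcr$p_a1 < study_config$alpha & qpcr$ratio_a1 > 1]
cat(length(sig_a1), "compounds significantly increase LUC mRNA in A1\n")
spec <- classify_specificity(sig_a1,
                             qpcr$ratio_a1[match(sig_a1, qpcr$compound_id)],
                             TRUE,
                             qpcr$ratio_a6[match(sig_a1, qpcr$compound_id)],
                             band = study_config$specificity_band)
cat(sum(spec$specific), "of these are quiet in the A6 counter-screen",
    "(specific for the SNCA locus)\n")
conf <- qpcr$compound_id %in% spec$compound_id[spec$specific] &
  qpcr$p_wt < study_config$alpha & qpcr$ratio_wt > 1
cat(sum(conf), "confirmed to raise SNCA mRNA in wildtype cells:",
    paste(qpcr$compound_id[conf], collapse = ", "), "\n")
cat(sprintf("  wildtype SNCA ratios: %s\n",
            paste(sprintf("%.2f", qpcr$ratio_wt[conf]), collapse = ", ")))
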