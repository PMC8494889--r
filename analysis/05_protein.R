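#!/usr/bin/env Rscript
# Protein-level confirmation: In-Cell Western (CellTag700-normalized) and
# Western blot (loading-normalized), both vehicle-normalized per batch and
# Dunnett-tested against DMSO.

source("analysis/00_config.R")

qpcr <- read.csv(file.path(OUT_DIR, "qpcr_table.csv"))
confirmed <- qpcr$compound_id[qpcr$p_a1 < study_config$alpha &
                                qpcr$ratio_a1 > 1 &
                                qpcr$ratio_a6 >= study_config$specificity_band[1] &
                                qpcr$ratio_a6 <= study_config$specificity_band[2] &
                                qpcr$p_wt < study_config$alpha &
                                qpcr$ratio_wt > 1]
cat(length(confirmed), "mRNA-confirmed compounds enter protein assays\n")

protein_summary <- function(signals, label) {
  keep <- signals$compound_id %in% c(confirmed, "DMSO", "BACKGROUND")
  fc <- protein_fold_change_table(signals[keep, ])
  dn <- dunnett_test(fc$fold_change, fc$compound_id, control = "DMSO")
  s <- attr(fc, "summary")
  out <- merge(s[s$compound_id != "DMSO", ],
               dn[, c("group", "adjusted_p", "stars")],
               by.x = "compound_id", by.y = "group")
  names(out)[-1] <- paste0(c("fold_change_", "n_", "p_", "stars_"), label)
  out
}

icw <- protein_summary(study_bundle$protein_icw, "icw")
wb <- protein_summary(study_bundle$protein_wb, "wb")
prot <- merge(icw, wb, by = "compound_id")
write.csv(prot, file.path(OUT_DIR, "protein_table.csv"), row.names = FALSE)
print(prot)

both <- prot$p_icw < study_config$alpha & prot$fold_change_icw > 1 &
  prot$p_wb < study_config$alpha & prot$fold_change_wb > 1
cat(sum(both), "compounds show a concordant significant protein increase",
    "in both assays\n")
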