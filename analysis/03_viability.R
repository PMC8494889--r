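#!/usr/bin/env Rscript
# Toxicity triage of the inhibitor hits: resazurin + live/dead-count
# viability over the dose series, OR-combined verdict at the screen dose.

source("analysis/00_config.R")

hits <- read.csv(file.path(OUT_DIR, "hit_table.csv"))
inhibitors <- hits$compound_id[hits$classification == "inhibitor"]
cat("Inhibitor hits entering viability testing:", length(inhibitors), "\n")

res <- study_bundle$resazurin
hcs <- study_bundle$hcs
tox <- toxicity_table(
  res[res$compound_id %in% c(inhibitors, "DMSO"), ],
  hcs[hcs$compound_id %in% inhibitors, ],
  assay_concentration = study_config$assay_concentration,
  threshold = study_config$toxicity_threshold)
write.csv(tox, file.path(OUT_DIR, "toxicity_table.csv"), row.names = FALSE)

n_toxic <- sum(tox$toxic)
cat(n_toxic, "inhibitors toxic at <=", study_config$assay_concentration,
    "uM (viability <", study_config$toxicity_threshold, ");",
    length(inhibitors) - n_toxic, "non-toxic inhibitors remain\n")
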