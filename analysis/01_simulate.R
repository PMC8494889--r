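#!/usr/bin/env Rscript
# Generate the synthetic screen inputs (plate tables, viability tables, CT
# tables, protein tables) with ground truth kept in a separate file, and
# write them under results/simulated/.

source("analysis/00_config.R")

sim_dir <- file.path(OUT_DIR, "simulated")
dir.create(sim_dir, showWarnings = FALSE, recursive = TRUE)

b <- study_bundle
write_plate_table(b$screen, file.path(sim_dir, "luc_screen_plates.csv"),
                  header_comment = paste0("seed=", b$seed))
for (nm in c("resazurin", "hcs", "qpcr_a1", "qpcr_a6", "qpcr_wt",
             "protein_icw", "protein_wb")) {
  write.csv(b[[nm]], file.path(sim_dir, paste0(nm, ".csv")),
            row.names = FALSE)
}
# ground truth lives in its own file, never alongside assay signals
write.csv(b$truth, file.path(sim_dir, "ground_truth.csv"), row.names = FALSE)
jsonlite::write_json(
  list(seed = b$seed, n_compounds = nrow(study_effects),
       n_replicates = b$screen$n_replicates,
       geometry = b$screen$geometry,
       noise = unclass(study_noise)),
  file.path(sim_dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)

cat("Simulated screen:", nrow(study_effects), "compounds,",
    length(plate_ids(b$screen)), "plates,",
    nrow(b$screen$wells), "wells\n")
cat("True class counts:\n")
print(table(b$truth$luc_label))
cat("Inputs written to", sim_dir, "\n")
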