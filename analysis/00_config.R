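# Shared configuration of the simulated study: compound library composition,
# effect sizes and noise, at the scale of the original screen (1649
# compounds, three replicate experiments). Sourced by every numbered
# analysis script so all stages run on the same deterministic bundle.

library(sncascreen)

SEED <- 20210L
OUT_DIR <- "results"

# library composition: a handful of genuine, specific activators with
# concordant mRNA/protein effects; a larger shell of reporter-only
# activators and pleiotropic compounds; inhibitors dominated by cytotoxins.
build_study_effects <- function(seed = SEED) {
  set.seed(seed)
  n_total <- 1649
  ids <- sprintf("CPD%04d", seq_len(n_total))
  fc <- rep(1, n_total)
  mrna <- rep(1, n_total)
  prot <- rep(1, n_total)
  specific <- rep(TRUE, n_total)
  ic <- rep(NA_real_, n_total)

  i <- 0
  take <- function(n) { idx <- i + seq_len(n); i <<- i + n; idx }

  # 3 true specific activators (clomiphene / conivaptan / emodin analogues)
  idx <- take(3)
  fc[idx] <- runif(3, 1.5, 1.9)
  mrna[idx] <- runif(3, 1.4, 2.0)   # confirmed mRNA range
  prot[idx] <- runif(3, 1.3, 2.0)   # confirmed protein range
  # 12 pleiotropic activators (move the randomly-integrated reporter too)
  idx <- take(12)
  fc[idx] <- runif(12, 1.4, 1.8)
  mrna[idx] <- fc[idx]
  specific[idx] <- FALSE
  # 149 reporter-only activators: luciferase signal up, no transcript change
  idx <- take(149)
  fc[idx] <- runif(149, 1.4, 2.0)
  # 153 apparent inhibitors; most are cytotoxic at screen dose
  idx <- take(153)
  fc[idx] <- runif(153, 0.45, 0.65)
  tox_idx <- idx[seq_len(112)]
  ic[tox_idx] <- runif(112, 0.5, 6)  # Hill midpoint below the 10 uM screen dose

  effect_model(ids, true_luc_fc = fc, specific = specific, toxic_ic = ic,
               true_mrna_fc = mrna, true_protein_fc = prot)
}

study_effects <- build_study_effects()
study_noise <- noise_model(seed = SEED)  # defaults: well CV 8%, CT SD 0.15
study_config <- triage_config()          # k = 4, mean consensus, 10 uM screen

study_bundle <- generate_validation_bundle(
  study_effects, study_noise,
  assay_concentration = study_config$assay_concentration,
  toxicity_threshold = study_config$toxicity_threshold)

dir.create(OUT_DIR, showWarnings = FALSE)
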