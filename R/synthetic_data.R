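# Synthetic screen generator: every input the pipeline consumes, with known
# ground truth, emulating the study design — 384-well plates with a fixed
# control layout, compound positions re-randomized across three replicate
# experiments, multiplicative (log-normal) well noise, per-plate scale
# factors, Hill-curve dose-dependent toxicity, and CT tables for a target
# plus housekeeping genes.

#' Per-compound ground-truth effect table
#'
#' One row per compound. `true_luc_fc` is the true reporter fold change
#' (1 = inert); `specific` marks compounds acting only in the screening
#' line (FALSE = pleiotropic, also active in the counter-screen line);
#' `toxic_ic` is the Hill midpoint of the viability curve (µM, `NA` =
#' never toxic); `true_mrna_fc` / `true_protein_fc` are the true
#' downstream effect sizes.
#'
#' @param compound_id Compound identifiers (unique).
#' @param true_luc_fc,true_mrna_fc,true_protein_fc Positive effect sizes,
#'   recycled; mRNA and protein effects default to the reporter effect.
#' @param specific Logical, recycled (default TRUE).
#' @param toxic_ic Hill midpoint in µM or `NA`, recycled.
#' @param hill_slope Positive Hill slope, recycled (default 2).
#' @return Validated effect data frame of class `effect_model`.
#' @export
effect_model <- function(compound_id, true_luc_fc = 1, specific = TRUE,
                         toxic_ic = NA_real_, hill_slope = 2,
                         true_mrna_fc = true_luc_fc,
                         true_protein_fc = true_luc_fc) {
  n <- length(compound_id)
  if (anyDuplicated(compound_id)) stop("duplicate compound_id in effect model")
  ef <- data.frame(
    compound_id = as.character(compound_id),
    true_luc_fc = rep_len(true_luc_fc, n),
    specific = rep_len(as.logical(specific), n),
    toxic_ic = rep_len(as.numeric(toxic_ic), n),
    hill_slope = rep_len(hill_slope, n),
    true_mrna_fc = rep_len(true_mrna_fc, n),
    true_protein_fc = rep_len(true_protein_fc, n),
    stringsAsFactors = FALSE
  )
  if (any(ef$true_luc_fc <= 0 | ef$true_mrna_fc <= 0 | ef$true_protein_fc <= 0)) {
    stop("effect fold changes must be positive")
  }
  if (any(ef$hill_slope <= 0)) stop("hill_slope must be positive")
  inert <- ef$true_luc_fc == 1 & ef$true_mrna_fc == 1 & ef$true_protein_fc == 1
  if (any(inert & !is.na(ef$toxic_ic))) {
    stop("inert compounds (all fold changes 1) must not carry a toxic_ic")
  }
  class(ef) <- c("effect_model", "data.frame")
  ef
}

#' Measurement noise model
#'
#' @param well_cv Coefficient of variation of the multiplicative log-normal
#'   well noise (default 0.08).
#' @param plate_factor_sd SD of the log of the per-plate multiplicative
#'   scale factor (default 0.10).
#' @param ct_sd SD of additive CT noise, in cycles (default 0.15).
#' @param count_n Cells counted per live/dead well (default 500).
#' @param seed Integer RNG seed — mandatory, recorded in every generated
#'   file header so a run is reproducible from its outputs.
#' @param exact_counts Replace the binomial live/dead sampling by its
#'   expectation (used for fully noise-free bundles).
#' @return A `noise_model` list.
#' @export
noise_model <- function(well_cv = 0.08, plate_factor_sd = 0.10, ct_sd = 0.15,
                        count_n = 500L, seed, exact_counts = FALSE) {
  if (missing(seed)) stop("noise_model requires an explicit seed")
  stopifnot(well_cv >= 0, plate_factor_sd >= 0, ct_sd >= 0, count_n > 0)
  structure(
    list(well_cv = well_cv, plate_factor_sd = plate_factor_sd,
         ct_sd = ct_sd, count_n = as.integer(count_n),
         seed = as.integer(seed), exact_counts = isTRUE(exact_counts)),
    class = "noise_model"
  )
}

#' Noise-free measurement model
#'
#' All dispersions zero and deterministic (expected-value) cell counts:
#' every pipeline stage must recover the effect table exactly from data
#' generated with this model.
#'
#' @param seed RNG seed (still required: placement randomization remains).
#' @return A `noise_model`.
#' @export
noise_free <- function(seed) {
  noise_model(well_cv = 0, plate_factor_sd = 0, ct_sd = 0, seed = seed,
              exact_counts = TRUE)
}

# independent sub-streams per generator, kept below 2^31
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}

# multiplicative log-normal factor with mean exactly 1
lognormal_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

#' Fixed control layout of a plate
#'
#' Control wells occupy a fixed block filled from the last column backwards
#' (the study kept controls at fixed addresses in all replicates while
#' compounds moved). The per-plate control complement is a generator
#' parameter: the original plate map prints no counts.
#'
#' @param geometry Plate geometry name.
#' @param n_untreated,n_vehicle,n_positive Control wells per plate.
#' @return Data frame `{row, col, well_type}` of the control addresses.
#' @export
control_layout <- function(geometry = "w384", n_untreated = 22L,
                           n_vehicle = 8L, n_positive = 2L) {
  geom <- plate_geometry(geometry)
  n_ctrl <- n_untreated + n_vehicle + n_positive
  if (n_ctrl >= geom$capacity) stop("control layout exceeds plate capacity")
  slots <- expand.grid(row = LETTERS[seq_len(geom$n_row)],
                       col = seq_len(geom$n_col), stringsAsFactors = FALSE)
  slots <- slots[order(-slots$col, match(slots$row, LETTERS)), ]
  ctrl <- slots[seq_len(n_ctrl), , drop = FALSE]
  ctrl$well_type <- rep(c("untreated_control", "vehicle_control",
                          "positive_control"),
                        times = c(n_untreated, n_vehicle, n_positive))
  rownames(ctrl) <- NULL
  ctrl
}

#' Generate a reporter-screen run with ground truth
#'
#' Simulates the primary luciferase screen: per replicate, compounds are
#' placed uniformly at random on the compound slots of as many plates as
#' needed (re-randomized each replicate), controls sit in the fixed layout,
#' and the measured signal is
#' `base_signal * plate_factor * true_fold_change * lognormal_noise`.
#' In the counter-screen line (`line = "counter"`) compounds flagged
#' `specific` are inert; pleiotropic compounds act in both lines.
#'
#' @param effects An [effect_model()] table.
#' @param noise A [noise_model()].
#' @param geometry Plate geometry (default `"w384"`).
#' @param n_replicates Independent experiments (default 3).
#' @param n_untreated,n_vehicle,n_positive Control wells per plate.
#' @param base_signal Mean control signal in counts (default 1000).
#' @param positive_fc True fold change of the positive-control wells
#'   (default 1.6, an activator-strength reference).
#' @param concentration_uM Screen treatment concentration (default 10).
#' @param line `"screening"` or `"counter"`.
#' @return List: `run` (a [screen_run()]) and `truth` (compound_id, the
#'   true fold change acting in this line, and its `luc_label`
#'   activator/inhibitor/inactive).
#' @export
generate_screen <- function(effects, noise, geometry = "w384",
                            n_replicates = 3L, n_untreated = 22L,
                            n_vehicle = 8L, n_positive = 2L,
                            base_signal = 1000, positive_fc = 1.6,
                            concentration_uM = 10, line = c("screening", "counter")) {
  line <- match.arg(line)
  stopifnot(inherits(effects, "effect_model"), inherits(noise, "noise_model"))
  geom <- plate_geometry(geometry)
  layout <- control_layout(geometry, n_untreated, n_vehicle, n_positive)
  ccap <- geom$capacity - nrow(layout)
  n_cmpd <- nrow(effects)
  if (ccap < 1) stop("no compound slots left on plate")
  n_plates <- ceiling(n_cmpd / ccap)

  fc <- effects$true_luc_fc
  if (line == "counter") fc[effects$specific] <- 1

  all_slots <- expand.grid(row = LETTERS[seq_len(geom$n_row)],
                           col = seq_len(geom$n_col), stringsAsFactors = FALSE)
  is_ctrl_slot <- paste(all_slots$row, all_slots$col) %in%
    paste(layout$row, layout$col)
  cmpd_slots <- all_slots[!is_ctrl_slot, , drop = FALSE]

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(noise$seed, if (line == "screening") 101L else 102L))

  reps <- lapply(seq_len(n_replicates), function(r) {
    pf <- exp(stats::rnorm(n_plates, 0, noise$plate_factor_sd))
    # uniform re-randomization of compound positions for this replicate
    slot_idx <- sample(n_plates * nrow(cmpd_slots), n_cmpd)
    plate_of <- (slot_idx - 1L) %/% nrow(cmpd_slots) + 1L
    within <- (slot_idx - 1L) %% nrow(cmpd_slots) + 1L
    cmpd <- data.frame(
      plate_id = sprintf("R%d_P%02d", r, plate_of),
      replicate = r,
      row = cmpd_slots$row[within],
      col = cmpd_slots$col[within],
      well_type = "compound",
      compound_id = effects$compound_id,
      concentration_uM = concentration_uM,
      signal = base_signal * pf[plate_of] * fc *
        lognormal_factor(n_cmpd, noise$well_cv),
      stringsAsFactors = FALSE
    )
    ctrl <- do.call(rbind, lapply(seq_len(n_plates), function(p) {
      ctrl_fc <- ifelse(layout$well_type == "positive_control", positive_fc, 1)
      data.frame(
        plate_id = sprintf("R%d_P%02d", r, p),
        replicate = r,
        row = layout$row, col = layout$col, well_type = layout$well_type,
        compound_id = NA_character_,
        concentration_uM = ifelse(layout$well_type == "untreated_control",
                                  NA_real_, concentration_uM),
        signal = base_signal * pf[p] * ctrl_fc *
          lognormal_factor(nrow(layout), noise$well_cv),
        stringsAsFactors = FALSE
      )
    }))
    rbind(cmpd, ctrl)
  })
  wells <- do.call(rbind, reps)
  run <- screen_run(wells, geometry = geometry, n_replicates = n_replicates)
  truth <- data.frame(
    compound_id = effects$compound_id,
    true_fold_change = fc,
    luc_label = factor(ifelse(fc > 1, "activator",
                              ifelse(fc < 1, "inhibitor", "inactive")),
                       levels = HIT_CLASSES),
    stringsAsFactors = FALSE
  )
  list(run = run, truth = truth)
}

# noise-free Hill viability at concentration c
hill_viability <- function(conc, toxic_ic, hill_slope) {
  if (is.na(toxic_ic)) return(rep(1, length(conc)))
  1 / (1 + (conc / toxic_ic)^hill_slope)
}

#' Generate dose-response viability tables
#'
#' Resazurin signals and live/dead counts over a concentration series.
#' True viability follows a descending Hill curve
#' `1 / (1 + (c / toxic_ic)^slope)` for toxic compounds and 1 otherwise;
#' resazurin signals are multiplicatively noised, live counts are drawn
#' binomially at the true viability (or set to its expectation when the
#' noise model requests exact counts).
#'
#' @param effects An [effect_model()] table.
#' @param noise A [noise_model()].
#' @param concentrations Tested concentrations in µM, strictly increasing
#'   (default `0.25, 2.5, 10, 25, 40`, spanning the 0.25--40 µM range).
#' @param n_control_wells Vehicle-control resazurin wells (default 6).
#' @param base_signal Mean control resazurin signal (default 1000).
#' @return List of two data frames: `resazurin`
#'   `{compound_id, concentration_uM, signal}` (controls as
#'   `compound_id = "DMSO"`) and `hcs`
#'   `{compound_id, concentration_uM, live, dead}`.
#' @export
generate_dose_response <- function(effects, noise,
                                   concentrations = c(0.25, 2.5, 10, 25, 40),
                                   n_control_wells = 6L, base_signal = 1000) {
  stopifnot(inherits(effects, "effect_model"), inherits(noise, "noise_model"),
            all(concentrations > 0), all(diff(concentrations) > 0))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(noise$seed, 103L))

  grid <- expand.grid(i = seq_len(nrow(effects)),
                      concentration_uM = concentrations)
  v <- mapply(function(i, conc) {
    hill_viability(conc, effects$toxic_ic[i], effects$hill_slope[i])
  }, grid$i, grid$concentration_uM)

  resazurin <- data.frame(
    compound_id = effects$compound_id[grid$i],
    concentration_uM = grid$concentration_uM,
    signal = base_signal * v * lognormal_factor(nrow(grid), noise$well_cv),
    stringsAsFactors = FALSE
  )
  ctrl <- data.frame(
    compound_id = "DMSO",
    concentration_uM = 0,
    signal = base_signal * lognormal_factor(n_control_wells, noise$well_cv),
    stringsAsFactors = FALSE
  )
  resazurin <- rbind(resazurin, ctrl)

  live <- if (noise$exact_counts) {
    round(noise$count_n * v)
  } else {
    stats::rbinom(nrow(grid), noise$count_n, v)
  }
  hcs <- data.frame(
    compound_id = effects$compound_id[grid$i],
    concentration_uM = grid$concentration_uM,
    live = live,
    dead = noise$count_n - live,
    stringsAsFactors = FALSE
  )
  list(resazurin = resazurin, hcs = hcs)
}

#' Generate a qPCR CT table
#'
#' Emulates the relative-expression assays: per compound,
#' `n_samples` treated replicates, plus `n_control_samples` vehicle (DMSO)
#' replicates shared by all compounds. The treated target CT sits
#' `log_E(true_mrna_fc)` cycles below the base CT (an up-regulated
#' transcript crosses threshold earlier); reference-gene CTs are unaffected
#' by compound effects. In the counter-screen line, compounds flagged
#' `specific` leave the target untouched.
#'
#' @param effects An [effect_model()] table.
#' @param noise A [noise_model()] (`ct_sd` cycles of additive CT noise).
#' @param target_gene Target gene id (e.g. `"LUC"`, `"SNCA"`).
#' @param reference_genes Housekeeping gene ids.
#' @param base_ct Named base CT per gene (all genes), values in (10, 35).
#' @param n_samples Treated replicates per compound (default 3).
#' @param n_control_samples Vehicle replicates (default 6).
#' @param efficiency Amplification factor per cycle used to convert fold
#'   changes to cycles (default 2).
#' @param line `"screening"`, `"counter"` or `"wildtype"`.
#' @return Data frame `{sample_id, compound_id, condition, gene_id, ct}`
#'   with `condition` `"treated"` / `"DMSO"`.
#' @export
generate_ct_table <- function(effects, noise, target_gene, reference_genes,
                              base_ct, n_samples = 3L, n_control_samples = 6L,
                              efficiency = 2,
                              line = c("wildtype", "screening", "counter")) {
  line <- match.arg(line)
  stopifnot(inherits(effects, "effect_model"), inherits(noise, "noise_model"))
  genes <- c(target_gene, reference_genes)
  if (!all(genes %in% names(base_ct))) {
    stop("base_ct must name every gene: ", paste(genes, collapse = ", "))
  }
  if (any(base_ct[genes] <= 10 | base_ct[genes] >= 35)) {
    stop("base CT values must lie in (10, 35)")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  offset <- c(wildtype = 104L, screening = 105L, counter = 106L)[[line]]
  set.seed(derive_seed(noise$seed, offset))

  fc <- effects$true_mrna_fc
  if (line == "counter") fc[effects$specific] <- 1

  mk_rows <- function(sample_id, compound_id, condition, target_fc) {
    ct <- base_ct[genes]
    ct[target_gene] <- ct[target_gene] - log(target_fc, base = efficiency)
    data.frame(sample_id = sample_id, compound_id = compound_id,
               condition = condition, gene_id = genes,
               ct = ct + stats::rnorm(length(genes), 0, noise$ct_sd),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  ctrl <- do.call(rbind, lapply(seq_len(n_control_samples), function(s) {
    mk_rows(sprintf("DMSO_%s_%d", line, s), "DMSO", "DMSO", 1)
  }))
  treated <- do.call(rbind, lapply(seq_len(nrow(effects)), function(i) {
    do.call(rbind, lapply(seq_len(n_samples), function(s) {
      mk_rows(sprintf("%s_%s_%d", effects$compound_id[i], line, s),
              effects$compound_id[i], "treated", fc[i])
    }))
  }))
  rbind(ctrl, treated)
}

#' Generate a protein signal table (ICW / WB)
#'
#' Per compound, `n_reps` replicate samples with
#' `target = base_target * true_protein_fc * noise + background` and a
#' loading-reference channel unaffected by the compound; vehicle (DMSO)
#' samples and — for the ICW — secondary-antibody-only `BACKGROUND` wells
#' are included.
#'
#' @param effects An [effect_model()] table.
#' @param noise A [noise_model()] (`well_cv` drives both channels).
#' @param assay `"icw"` (with background wells) or `"wb"`.
#' @param n_reps Replicates per compound (default 6).
#' @param n_vehicle Vehicle samples (default 8).
#' @param n_background Background wells for the ICW (default 4).
#' @param base_target,base_loading Mean channel signals.
#' @param background Mean additive background signal (default 30).
#' @return Data frame `{sample_id, compound_id, batch_id, target_signal,
#'   loading_signal}`.
#' @export
generate_protein_table <- function(effects, noise, assay = c("icw", "wb"),
                                   n_reps = 6L, n_vehicle = 8L,
                                   n_background = 4L, base_target = 500,
                                   base_loading = 1500, background = 30) {
  assay <- match.arg(assay)
  stopifnot(inherits(effects, "effect_model"), inherits(noise, "noise_model"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(noise$seed, if (assay == "icw") 107L else 108L))
  with_bg <- assay == "icw"
  bg_t <- if (with_bg) background else 0
  bg_l <- if (with_bg) background else 0

  mk <- function(compound_id, fc, n) {
    data.frame(
      sample_id = sprintf("%s_%s_%d", compound_id, assay, seq_len(n)),
      compound_id = compound_id,
      batch_id = paste0(assay, "_B1"),
      target_signal = base_target * fc * lognormal_factor(n, noise$well_cv) + bg_t,
      loading_signal = base_loading * lognormal_factor(n, noise$well_cv) + bg_l,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, c(
    list(mk("DMSO", 1, n_vehicle)),
    lapply(seq_len(nrow(effects)), function(i) {
      mk(effects$compound_id[i], effects$true_protein_fc[i], n_reps)
    })
  ))
  if (with_bg) {
    bg <- data.frame(
      sample_id = sprintf("BG_%d", seq_len(n_background)),
      compound_id = "BACKGROUND",
      batch_id = paste0(assay, "_B1"),
      target_signal = bg_t * lognormal_factor(n_background, noise$well_cv / 2),
      loading_signal = bg_l * lognormal_factor(n_background, noise$well_cv / 2),
      stringsAsFactors = FALSE
    )
    out <- rbind(out, bg)
  }
  out
}

#' Generate the complete input bundle for the triage cascade
#'
#' One call producing every table [run_triage()] consumes, all from one
#' effect table, one noise model and one seed, together with the full
#' ground-truth table (kept separate from the assay tables so pipeline code
#' cannot read it by accident).
#'
#' @param effects An [effect_model()] table.
#' @param noise A [noise_model()].
#' @param assay_concentration Screen concentration in µM (default 10) —
#'   also the concentration the ground-truth toxicity label refers to.
#' @param toxicity_threshold Viability threshold for the truth label
#'   (default 0.70).
#' @param base_ct Named base CTs; defaults cover LUC, SNCA, UBC, HPRT1,
#'   GUSB.
#' @param ... Passed to [generate_screen()].
#' @return List of inputs (`screen`, `resazurin`, `hcs`, `qpcr_a1`,
#'   `qpcr_a6`, `qpcr_wt`, `protein_icw`, `protein_wb`) plus `truth`.
#' @export
generate_validation_bundle <- function(effects, noise,
                                       assay_concentration = 10,
                                       toxicity_threshold = 0.70,
                                       base_ct = c(LUC = 22, SNCA = 24,
                                                   UBC = 20, HPRT1 = 26,
                                                   GUSB = 25), ...) {
  scr <- generate_screen(effects, noise,
                         concentration_uM = assay_concentration,
                         line = "screening", ...)
  dr <- generate_dose_response(effects, noise)
  qpcr_a1 <- generate_ct_table(effects, noise, "LUC", c("UBC", "GUSB"),
                               base_ct, line = "screening")
  qpcr_a6 <- generate_ct_table(effects, noise, "LUC", c("UBC", "GUSB"),
                               base_ct, line = "counter")
  qpcr_wt <- generate_ct_table(effects, noise, "SNCA",
                               c("UBC", "HPRT1", "GUSB"),
                               base_ct, line = "wildtype")
  icw <- generate_protein_table(effects, noise, "icw")
  wb <- generate_protein_table(effects, noise, "wb")

  toxic <- vapply(seq_len(nrow(effects)), function(i) {
    conc <- c(0.25, 2.5, 10, 25, 40)
    conc <- conc[conc <= assay_concentration]
    any(hill_viability(conc, effects$toxic_ic[i],
                       effects$hill_slope[i]) < toxicity_threshold)
  }, logical(1))
  truth <- data.frame(
    compound_id = effects$compound_id,
    luc_label = scr$truth$luc_label,
    toxic = toxic,
    specific = effects$specific,
    true_luc_fc = effects$true_luc_fc,
    true_mrna_fc = effects$true_mrna_fc,
    true_protein_fc = effects$true_protein_fc,
    stringsAsFactors = FALSE
  )
  # a compound survives the cascade when every stage applicable to its class
  # passes: activators are exempt from the toxicity filter by design
  truth$final_candidate <-
    (truth$luc_label == "activator" & truth$specific &
       truth$true_mrna_fc > 1 & truth$true_protein_fc > 1) |
    (truth$luc_label == "inhibitor" & !truth$toxic & truth$specific &
       truth$true_mrna_fc < 1 & truth$true_protein_fc < 1)
  list(screen = scr$run, screen_truth = scr$truth,
       resazurin = dr$resazurin, hcs = dr$hcs,
       qpcr_a1 = qpcr_a1, qpcr_a6 = qpcr_a6, qpcr_wt = qpcr_wt,
       protein_icw = icw, protein_wb = wb,
       truth = truth, seed = noise$seed)
}
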