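# The staged triage cascade: primary reporter hits -> toxicity filter
# (inhibitors only) -> LUC qPCR in the screening line -> counter-screen
# specificity -> wildtype SNCA qPCR -> protein confirmation (ICW + WB).
# Every compound carries an append-only audit trail of stage verdicts; a
# later stage never overwrites an earlier exclusion.

#' Triage configuration
#'
#' All tunable stage parameters in one validated list.
#'
#' @param k Hit-threshold SD multiplier (default 4).
#' @param consensus Replicate consensus rule for hit calling.
#' @param control_type Normalization reference of the primary screen.
#' @param toxicity_threshold Viability fraction below which a dose is
#'   toxic (default 0.70).
#' @param assay_concentration Screen treatment concentration, µM.
#' @param alpha Significance level of the ANOVA/Dunnett stages.
#' @param specificity_band Fallback inactive band `(lo, hi)` for the
#'   counter-screen ratio (default 0.8--1.25).
#' @param min_band_controls Minimum counter-screen vehicle sample ratios
#'   required to derive the band from the data as `1 +/- k * SD`; below
#'   this the fallback band is used.
#' @param target_luc,refs_luc Target / reference genes of the reporter
#'   (LUC) qPCR assays.
#' @param target_wt,refs_wt Target / reference genes of the wildtype
#'   (SNCA) qPCR assay.
#' @param control_label Condition label of the qPCR calibrator samples.
#' @param vehicle_id Vehicle compound label in protein tables.
#' @param protein_rule `"both"` (ICW and WB must confirm, default) or
#'   `"either"`.
#' @param cap_inhibitors,cap_activators Optional caps on the number of
#'   compounds per class carried into the qPCR stages, selected by potency
#'   rank (default unlimited).
#' @param efficiencies Named per-gene amplification efficiencies
#'   (default 2 for every gene).
#' @return A `triage_config` list.
#' @export
triage_config <- function(k = 4, consensus = "mean",
                          control_type = "untreated_control",
                          toxicity_threshold = 0.70,
                          assay_concentration = 10,
                          alpha = 0.05,
                          specificity_band = c(0.8, 1.25),
                          min_band_controls = 6L,
                          target_luc = "LUC", refs_luc = c("UBC", "GUSB"),
                          target_wt = "SNCA",
                          refs_wt = c("UBC", "HPRT1", "GUSB"),
                          control_label = "DMSO", vehicle_id = "DMSO",
                          protein_rule = c("both", "either"),
                          cap_inhibitors = Inf, cap_activators = Inf,
                          efficiencies = NULL) {
  protein_rule <- match.arg(protein_rule)
  stopifnot(k > 0, toxicity_threshold > 0, toxicity_threshold < 1,
            assay_concentration > 0, alpha > 0, alpha < 1,
            length(specificity_band) == 2,
            specificity_band[1] < 1, specificity_band[2] > 1)
  structure(
    list(k = k, consensus = consensus, control_type = control_type,
         toxicity_threshold = toxicity_threshold,
         assay_concentration = assay_concentration, alpha = alpha,
         specificity_band = specificity_band,
         min_band_controls = as.integer(min_band_controls),
         target_luc = target_luc, refs_luc = refs_luc,
         target_wt = target_wt, refs_wt = refs_wt,
         control_label = control_label, vehicle_id = vehicle_id,
         protein_rule = protein_rule,
         cap_inhibitors = cap_inhibitors, cap_activators = cap_activators,
         efficiencies = efficiencies),
    class = "triage_config"
  )
}

#' Toxicity filter over primary hits
#'
#' Inhibitors flagged toxic are removed; activators pass unconditionally
#' (an activating signal cannot be mimicked by cell death, whereas a toxic
#' compound trivially lowers a viability-coupled reporter). An activator
#' that happens to carry a toxic flag passes with a logged note; an
#' inhibitor with no toxicity call at all is a coverage error.
#'
#' @param hits Hit-call table from [call_hits()] (hit classes only;
#'   inactive rows are ignored).
#' @param toxicity Toxicity-call table (`compound_id`, `toxic`), e.g. from
#'   [toxicity_table()].
#' @return The surviving hit rows; attribute `removed` lists the excluded
#'   compounds, attribute `notes` any toxic-but-passing activators.
#' @export
apply_toxicity_filter <- function(hits, toxicity) {
  hits <- hits[hits$classification != "inactive", , drop = FALSE]
  if (nrow(hits) == 0) {
    out <- hits
    attr(out, "removed") <- character(0)
    attr(out, "notes") <- character(0)
    return(out)
  }
  tox <- stats::setNames(toxicity$toxic, toxicity$compound_id)
  inh <- hits$compound_id[hits$classification == "inhibitor"]
  uncovered <- setdiff(inh, names(tox))
  if (length(uncovered) > 0) {
    stop("inhibitor(s) without a toxicity call: ",
         paste(utils::head(uncovered, 5), collapse = ", "))
  }
  is_inh <- hits$classification == "inhibitor"
  drop_mask <- is_inh & tox[hits$compound_id] %in% TRUE
  notes <- hits$compound_id[!is_inh & tox[hits$compound_id] %in% TRUE]
  if (length(notes) > 0) {
    message("toxic-flagged activator(s) pass by design: ",
            paste(notes, collapse = ", "))
  }
  out <- hits[!drop_mask, , drop = FALSE]
  attr(out, "removed") <- hits$compound_id[drop_mask]
  attr(out, "notes") <- notes
  out
}

#' Counter-screen specificity call
#'
#' A compound is specific when its effect is significant in the screening
#' line (A1) *and* its counter-screen (A6) ratio sits inside the inactive
#' band — a compound moving the randomly-integrated reporter as well is a
#' pleiotropic transcriptional modulator, not an SNCA-specific one.
#'
#' @param compound_id Compound identifier(s).
#' @param a1_ratio Screening-line expression ratio(s).
#' @param a1_significant Logical: Dunnett-significant vs vehicle in A1.
#' @param a6_ratio Counter-screen expression ratio(s).
#' @param band Inactive band `(lo, hi)`, inclusive.
#' @return Data frame: `compound_id`, `a1_ratio`, `a1_significant`,
#'   `a6_ratio`, `specific`.
#' @export
classify_specificity <- function(compound_id, a1_ratio, a1_significant,
                                 a6_ratio, band = c(0.8, 1.25)) {
  stopifnot(length(band) == 2, band[1] < band[2])
  if (any(is.na(a6_ratio))) {
    stop("missing counter-screen ratio for ",
         paste(compound_id[is.na(a6_ratio)], collapse = ", "))
  }
  data.frame(
    compound_id = compound_id,
    a1_ratio = a1_ratio,
    a1_significant = a1_significant,
    a6_ratio = a6_ratio,
    specific = a1_significant & a6_ratio >= band[1] & a6_ratio <= band[2],
    stringsAsFactors = FALSE
  )
}

# ANOVA-gated Dunnett significance of per-sample values versus the control
# group. Degenerate (zero within-group variance) data fall back to exact
# mean comparison: a difference of means with zero residual spread is
# treated as significant, equality as not.
group_significance <- function(values, groups, control, alpha = 0.05) {
  split_vals <- split(values, as.character(groups))
  treat <- setdiff(names(split_vals), control)
  means <- vapply(split_vals, mean, numeric(1))
  ss_within <- sum(vapply(split_vals, function(x) sum((x - mean(x))^2),
                          numeric(1)))
  if (ss_within == 0) {
    sig <- abs(means[treat] - means[[control]]) > 1e-12 * max(1, abs(means[[control]]))
    return(data.frame(group = treat, mean = means[treat],
                      adjusted_p = ifelse(sig, 0, 1),
                      significant = unname(sig),
                      degenerate = TRUE,
                      row.names = NULL, stringsAsFactors = FALSE))
  }
  aov_res <- one_way_anova(values, groups)
  dn <- dunnett_test(values, groups, control)
  sig <- aov_res$p < alpha & dn$adjusted_p < alpha
  data.frame(group = dn$group, mean = means[dn$group],
             adjusted_p = dn$adjusted_p, significant = sig,
             degenerate = FALSE, row.names = NULL, stringsAsFactors = FALSE)
}

stage_names <- c("luc_class", "toxicity", "luc_qpcr_a1", "specificity_a6",
                 "snca_qpcr_wt", "protein_icw", "protein_wb")

#' Run the full triage cascade
#'
#' Orchestrates every stage over a complete input bundle (real tables or a
#' [generate_validation_bundle()]) and returns a per-compound audit trail.
#' The surviving set at each stage is a subset of the previous stage's
#' survivors; a compound missing data for a stage it reached is reported in
#' the `incomplete` section, never silently passed. Given identical inputs
#' and configuration the report is deterministic.
#'
#' @param inputs List with elements `screen` (a [screen_run()]),
#'   `resazurin`, `hcs` (viability tables), `qpcr_a1`, `qpcr_a6`,
#'   `qpcr_wt` (CT tables) and `protein_icw`, `protein_wb` (signal
#'   tables). See the generators in this package for the table layouts.
#' @param config A [triage_config()].
#' @return A `triage_report`: `stages` (per-compound verdict table),
#'   `final_candidates`, `exclusion_log`, `incomplete`, `threshold`,
#'   `hits`, `config`.
#' @export
run_triage <- function(inputs, config = triage_config()) {
  stopifnot(inherits(config, "triage_config"))
  need <- c("screen", "resazurin", "hcs", "qpcr_a1", "qpcr_a6", "qpcr_wt",
            "protein_icw", "protein_wb")
  missing_in <- setdiff(need, names(inputs))
  if (length(missing_in) > 0) {
    stop("triage inputs missing: ", paste(missing_in, collapse = ", "))
  }

  # --- stage 1: primary screen hit calling -------------------------------
  records <- normalize_run(inputs$screen, config$control_type)
  threshold <- suppressWarnings(
    estimate_control_sd(records, k = config$k,
                        control_type = config$control_type))
  hits <- call_hits(records, threshold, consensus = config$consensus)

  verdicts <- data.frame(
    compound_id = hits$compound_id,
    luc_class = as.character(hits$classification),
    mean_fold_change = hits$mean_fold_change,
    stringsAsFactors = FALSE
  )
  for (s in stage_names[-1]) verdicts[[s]] <- NA_character_
  rownames(verdicts) <- verdicts$compound_id
  exclusions <- list()
  incomplete <- list()
  exclude <- function(ids, stage, reason) {
    if (length(ids) > 0) {
      exclusions[[length(exclusions) + 1]] <<- data.frame(
        compound_id = ids, stage = stage, reason = reason,
        stringsAsFactors = FALSE)
    }
  }
  mark <- function(ids, stage, verdict) {
    if (length(ids) > 0) verdicts[ids, stage] <<- verdict
  }

  surviving <- hits[hits$classification != "inactive", , drop = FALSE]
  exclude(hits$compound_id[hits$classification == "inactive"],
          "luc_class", "inside hit threshold")

  # optional potency caps into the follow-up assays
  for (cls in c("inhibitor", "activator")) {
    cap <- if (cls == "inhibitor") config$cap_inhibitors else config$cap_activators
    sub <- surviving[surviving$classification == cls, , drop = FALSE]
    if (is.finite(cap) && nrow(sub) > cap) {
      keep <- utils::head(rank_by_potency(sub)$compound_id, cap)
      dropped <- setdiff(sub$compound_id, keep)
      exclude(dropped, "luc_class", paste0("beyond ", cls, " potency cap"))
      surviving <- surviving[!surviving$compound_id %in% dropped, , drop = FALSE]
    }
  }

  # --- stage 2: toxicity filter (inhibitors only) ------------------------
  inh_ids <- surviving$compound_id[surviving$classification == "inhibitor"]
  covered <- intersect(inh_ids,
                       intersect(unique(inputs$resazurin$compound_id),
                                 unique(inputs$hcs$compound_id)))
  uncovered <- setdiff(inh_ids, covered)
  if (length(uncovered) > 0) {
    incomplete$toxicity <- uncovered
    mark(uncovered, "toxicity", "incomplete: no viability data")
    surviving <- surviving[!surviving$compound_id %in% uncovered, , drop = FALSE]
  }
  tox <- if (length(covered) > 0) {
    toxicity_table(
      inputs$resazurin[inputs$resazurin$compound_id %in%
                         c(covered, config$vehicle_id), , drop = FALSE],
      inputs$hcs[inputs$hcs$compound_id %in% covered, , drop = FALSE],
      assay_concentration = config$assay_concentration,
      threshold = config$toxicity_threshold,
      control_id = config$vehicle_id)
  } else {
    data.frame(compound_id = character(0), toxic = logical(0))
  }
  filtered <- suppressMessages(apply_toxicity_filter(surviving, tox))
  removed <- attr(filtered, "removed")
  mark(removed, "toxicity", "fail: toxic")
  exclude(removed, "toxicity", "toxic at or below assay concentration")
  mark(setdiff(surviving$compound_id, removed), "toxicity", "pass")
  surviving <- filtered

  # --- stage 3: reporter qPCR in the screening line ----------------------
  st3 <- qpcr_stage(inputs$qpcr_a1, surviving, config,
                    config$target_luc, config$refs_luc)
  surviving <- apply_stage(st3, surviving, "luc_qpcr_a1",
                           "no reporter mRNA confirmation", mark, exclude,
                           incomplete)
  incomplete <- attr(surviving, "incomplete")

  # --- stage 4: counter-screen specificity -------------------------------
  if (nrow(surviving) > 0) {
    a6 <- relative_expression_table(inputs$qpcr_a6, config$target_luc,
                                    config$refs_luc, config$control_label,
                                    config$efficiencies)
    a6_ratio <- stats::setNames(a6$ratio, a6$compound_id)
    have <- surviving$compound_id %in% names(a6_ratio)
    if (any(!have)) {
      ids <- surviving$compound_id[!have]
      incomplete$specificity_a6 <- ids
      mark(ids, "specificity_a6", "incomplete: no counter-screen data")
      surviving <- surviving[have, , drop = FALSE]
    }
    if (nrow(surviving) > 0) {
      band <- a6_band(inputs$qpcr_a6, config)
      spec <- classify_specificity(
        surviving$compound_id,
        a1_ratio = st3$mean[match(surviving$compound_id, st3$group)],
        a1_significant = TRUE,   # survivors of stage 3 by construction
        a6_ratio = a6_ratio[surviving$compound_id],
        band = band)
      fail <- spec$compound_id[!spec$specific]
      mark(fail, "specificity_a6", "fail: pleiotropic in counter-screen")
      exclude(fail, "specificity_a6", "counter-screen ratio outside inactive band")
      mark(setdiff(spec$compound_id, fail), "specificity_a6", "pass")
      surviving <- surviving[!surviving$compound_id %in% fail, , drop = FALSE]
    }
  }

  # --- stage 5: wildtype SNCA qPCR ---------------------------------------
  st5 <- qpcr_stage(inputs$qpcr_wt, surviving, config,
                    config$target_wt, config$refs_wt)
  surviving <- apply_stage(st5, surviving, "snca_qpcr_wt",
                           "no SNCA mRNA confirmation in wildtype cells",
                           mark, exclude, incomplete)
  incomplete <- attr(surviving, "incomplete")

  # --- stage 6: protein confirmation (ICW + WB) --------------------------
  if (nrow(surviving) > 0) {
    conf <- lapply(list(icw = inputs$protein_icw, wb = inputs$protein_wb),
                   protein_stage, surviving = surviving, config = config)
    have <- surviving$compound_id %in% intersect(conf$icw$group, conf$wb$group)
    if (any(!have)) {
      ids <- surviving$compound_id[!have]
      incomplete$protein <- ids
      mark(ids, "protein_icw", "incomplete: no protein data")
      mark(ids, "protein_wb", "incomplete: no protein data")
      surviving <- surviving[have, , drop = FALSE]
    }
    if (nrow(surviving) > 0) {
      ok_icw <- protein_pass(conf$icw, surviving)
      ok_wb <- protein_pass(conf$wb, surviving)
      mark(surviving$compound_id[ok_icw], "protein_icw", "pass")
      mark(surviving$compound_id[!ok_icw], "protein_icw", "fail: not confirmed")
      mark(surviving$compound_id[ok_wb], "protein_wb", "pass")
      mark(surviving$compound_id[!ok_wb], "protein_wb", "fail: not confirmed")
      ok <- if (config$protein_rule == "both") ok_icw & ok_wb else ok_icw | ok_wb
      fail <- surviving$compound_id[!ok]
      exclude(fail, "protein", "no concordant significant protein change")
      surviving <- surviving[ok, , drop = FALSE]
    }
  }

  structure(
    list(stages = verdicts,
         final_candidates = sort(surviving$compound_id),
         exclusion_log = if (length(exclusions) > 0) {
           do.call(rbind, exclusions)
         } else {
           data.frame(compound_id = character(0), stage = character(0),
                      reason = character(0))
         },
         incomplete = incomplete,
         threshold = threshold, hits = hits, config = config),
    class = "triage_report"
  )
}

# Dunnett-based qPCR confirmation of the surviving compounds; requires
# significance and a ratio on the same side of 1 as the hit class.
qpcr_stage <- function(ct_table, surviving, config, target, refs) {
  if (nrow(surviving) == 0) {
    return(data.frame(group = character(0), mean = numeric(0),
                      significant = logical(0)))
  }
  keep <- ct_table$condition == config$control_label |
    ct_table$compound_id %in% surviving$compound_id
  tab <- ct_table[keep, , drop = FALSE]
  rs <- relative_expression_samples(tab, target, refs,
                                    config$control_label,
                                    config$efficiencies)
  group_significance(rs$ratio,
                     ifelse(rs$condition == config$control_label,
                            config$control_label, rs$compound_id),
                     control = config$control_label, alpha = config$alpha)
}

apply_stage <- function(st, surviving, stage, fail_reason, mark, exclude,
                        incomplete) {
  if (nrow(surviving) > 0) {
    have <- surviving$compound_id %in% st$group
    if (any(!have)) {
      ids <- surviving$compound_id[!have]
      incomplete[[stage]] <- ids
      mark(ids, stage, "incomplete: no assay data")
      surviving <- surviving[have, , drop = FALSE]
    }
    if (nrow(surviving) > 0) {
      i <- match(surviving$compound_id, st$group)
      direction_ok <- ifelse(surviving$classification == "activator",
                             st$mean[i] > 1, st$mean[i] < 1)
      ok <- st$significant[i] & direction_ok
      fail <- surviving$compound_id[!ok]
      mark(fail, stage, "fail: not confirmed")
      exclude(fail, stage, fail_reason)
      mark(surviving$compound_id[ok], stage, "pass")
      surviving <- surviving[ok, , drop = FALSE]
    }
  }
  attr(surviving, "incomplete") <- incomplete
  surviving
}

# inactive band of the counter-screen: 1 +/- k * SD of the A6 vehicle
# sample ratios when enough controls exist, else the configured fallback
a6_band <- function(qpcr_a6, config) {
  rs <- relative_expression_samples(qpcr_a6, config$target_luc,
                                    config$refs_luc, config$control_label,
                                    config$efficiencies)
  ctrl <- rs$ratio[rs$condition == config$control_label]
  if (length(ctrl) >= config$min_band_controls && stats::sd(ctrl) > 0) {
    off <- config$k * stats::sd(ctrl)
    if (1 - off > 0) return(c(1 - off, 1 + off))
  }
  config$specificity_band
}

protein_stage <- function(signals, surviving, config) {
  keep <- signals$compound_id %in%
    c(surviving$compound_id, config$vehicle_id, "BACKGROUND")
  tab <- signals[keep, , drop = FALSE]
  fc <- suppressWarnings(
    protein_fold_change_table(tab, vehicle_id = config$vehicle_id))
  group_significance(fc$fold_change, fc$compound_id,
                     control = config$vehicle_id, alpha = config$alpha)
}

protein_pass <- function(st, surviving) {
  i <- match(surviving$compound_id, st$group)
  direction_ok <- ifelse(surviving$classification == "activator",
                         st$mean[i] > 1, st$mean[i] < 1)
  !is.na(i) & st$significant[i] & direction_ok
}

#' @export
print.triage_report <- function(x, ...) {
  n <- nrow(x$stages)
  cat("<triage_report> ", n, " compounds called; ",
      sum(x$stages$luc_class != "inactive"), " primary hits; ",
      length(x$final_candidates), " final candidate(s)\n", sep = "")
  if (length(x$final_candidates) > 0) {
    cat("  candidates:", paste(x$final_candidates, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a triage report to disk
#'
#' Emits `triage_report.json` (the machine-readable audit trail) and
#' `candidates.csv` into `dir`.
#'
#' @param report A `triage_report` from [run_triage()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_triage_report <- function(report, dir) {
  stopifnot(inherits(report, "triage_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  payload <- list(
    threshold = unclass(report$threshold)[c("control_sd", "k", "offset",
                                            "lower_bound", "upper_bound")],
    stages = report$stages,
    exclusion_log = report$exclusion_log,
    incomplete = report$incomplete,
    final_candidates = report$final_candidates
  )
  jsonlite::write_json(payload, file.path(dir, "triage_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(
    data.frame(compound_id = report$final_candidates),
    file.path(dir, "candidates.csv"), row.names = FALSE, quote = FALSE)
  invisible(dir)
}
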