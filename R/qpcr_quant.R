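# Relative expression ratios from qPCR threshold cycles: the Pfaffl
# efficiency-corrected method generalized to multiple reference genes.
#
# ratio = E_target^dCT_target / geomean_r( E_r^dCT_r )
#
# with dCT = CT_control - CT_treated per gene, so an earlier-amplifying
# (up-regulated) treated target gives a ratio > 1. With a single reference
# and efficiency 2 everywhere this reduces to the classic 2^(-ddCT).

#' Threshold-cycle difference
#'
#' `delta_ct(control, treated) = control - treated`: positive when the
#' treated sample crosses threshold earlier, i.e. carries more template.
#'
#' @param control_ct,treated_ct Finite CT values (cycles).
#' @return The CT difference.
#' @export
delta_ct <- function(control_ct, treated_ct) {
  stopifnot(all(is.finite(control_ct)), all(is.finite(treated_ct)))
  control_ct - treated_ct
}

#' Efficiency-corrected relative expression ratio
#'
#' Pfaffl ratio for one target gene against one or more reference
#' (housekeeping) genes. Per gene, the amplification factor per cycle `E`
#' (2 = perfect doubling) converts a CT difference into a linear expression
#' factor `E^dCT`; the reference factors are aggregated by geometric mean
#' (the geNorm convention), which makes the ratio invariant under
#' permutation of the reference genes.
#'
#' @param target_dct CT difference (control - treated) of the target gene.
#' @param ref_dct Numeric vector of CT differences of the reference genes.
#' @param target_eff Amplification efficiency of the target, in `(1, 2.2]`
#'   (default 2).
#' @param ref_eff Efficiencies of the reference genes, recycled to
#'   `length(ref_dct)`.
#' @return The relative expression ratio (positive scalar).
#' @export
pfaffl_ratio <- function(target_dct, ref_dct, target_eff = 2, ref_eff = 2) {
  stopifnot(length(ref_dct) >= 1)
  ref_eff <- rep_len(ref_eff, length(ref_dct))
  check_efficiency(c(target_eff, ref_eff))
  target_factor <- target_eff^target_dct
  # geometric mean on the log scale for numerical stability
  ref_factor <- exp(mean(ref_dct * log(ref_eff)))
  target_factor / ref_factor
}

check_efficiency <- function(e) {
  if (any(e <= 1 | e > 2.2)) {
    stop("amplification efficiency must lie in (1, 2.2], got ",
         paste(signif(e[e <= 1 | e > 2.2], 4), collapse = ", "))
  }
  invisible(e)
}

check_ct_table <- function(samples) {
  need <- c("compound_id", "condition", "gene_id", "ct")
  missing_cols <- setdiff(need, names(samples))
  if (length(missing_cols) > 0) {
    stop("CT table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (any(!is.finite(samples$ct))) stop("non-finite CT value in table")
  invisible(samples)
}

gene_efficiencies <- function(genes, efficiencies) {
  eff <- stats::setNames(rep(2, length(genes)), genes)
  if (!is.null(efficiencies)) {
    known <- intersect(names(efficiencies), genes)
    eff[known] <- efficiencies[known]
  }
  check_efficiency(eff)
  eff
}

control_mean_ct <- function(samples, genes, control_label) {
  is_ctrl <- samples$condition == control_label
  vapply(genes, function(g) {
    ct <- samples$ct[is_ctrl & samples$gene_id == g]
    if (length(ct) == 0) {
      stop("control condition '", control_label, "' has no CT for gene ", g)
    }
    mean(ct)
  }, numeric(1))
}

#' Relative expression table from a long CT table
#'
#' Computes one Pfaffl ratio per compound from a long CT table covering a
#' treated condition per compound plus a shared control condition.
#' Technical replicates are aggregated by arithmetic mean on the CT scale
#' (CT is the measured quantity) before any ratio is formed. Every
#' (compound, gene) combination must be present in both conditions;
#' incomplete designs are an error naming the missing piece, never a
#' silently dropped compound.
#'
#' @param samples Data frame `{compound_id, condition, gene_id, ct}`;
#'   control rows carry `condition == control_label` (their `compound_id`
#'   is ignored).
#' @param target_gene Target gene id.
#' @param reference_genes Character vector (>= 1) of reference gene ids.
#' @param control_label Condition label of the calibrator samples
#'   (default `"DMSO"`).
#' @param efficiencies Named numeric vector of per-gene amplification
#'   efficiencies; genes absent from it default to 2.
#' @return Data frame: `compound_id`, `target_gene`, `reference_genes`
#'   (comma-joined), `ratio`.
#' @export
relative_expression_table <- function(samples, target_gene, reference_genes,
                                      control_label = "DMSO",
                                      efficiencies = NULL) {
  stopifnot(length(reference_genes) >= 1)
  check_ct_table(samples)
  genes <- c(target_gene, reference_genes)
  eff <- gene_efficiencies(genes, efficiencies)
  ctrl_ct <- control_mean_ct(samples, genes, control_label)

  treated <- samples[samples$condition != control_label, , drop = FALSE]
  ids <- sort(unique(treated$compound_id))
  rows <- lapply(ids, function(id) {
    tr <- treated[treated$compound_id == id, , drop = FALSE]
    mean_ct <- vapply(genes, function(g) {
      ct <- tr$ct[tr$gene_id == g]
      if (length(ct) == 0) {
        stop("compound ", id, " has no treated CT for gene ", g)
      }
      mean(ct)
    }, numeric(1))
    dct <- ctrl_ct - mean_ct
    data.frame(
      compound_id = id,
      target_gene = target_gene,
      reference_genes = paste(reference_genes, collapse = ","),
      ratio = pfaffl_ratio(dct[[target_gene]], dct[reference_genes],
                           eff[[target_gene]], eff[reference_genes]),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Per-sample relative expression ratios
#'
#' Like [relative_expression_table()], but computes one Pfaffl ratio per
#' *sample* (each sample's CTs against the mean control CTs) instead of
#' aggregating replicates first. Control samples are included — their
#' ratios scatter around 1 — which is what the many-to-one significance
#' test consumes as the vehicle group.
#'
#' @inheritParams relative_expression_table
#' @return Data frame: `sample_id`, `compound_id`, `condition`, `ratio`.
#' @export
relative_expression_samples <- function(samples, target_gene, reference_genes,
                                        control_label = "DMSO",
                                        efficiencies = NULL) {
  stopifnot(length(reference_genes) >= 1, "sample_id" %in% names(samples))
  check_ct_table(samples)
  genes <- c(target_gene, reference_genes)
  eff <- gene_efficiencies(genes, efficiencies)
  ctrl_ct <- control_mean_ct(samples, genes, control_label)

  per_sample <- split(samples, samples$sample_id)
  rows <- lapply(per_sample, function(sm) {
    mean_ct <- vapply(genes, function(g) {
      ct <- sm$ct[sm$gene_id == g]
      if (length(ct) == 0) {
        stop("sample ", sm$sample_id[1], " has no CT for gene ", g)
      }
      mean(ct)
    }, numeric(1))
    dct <- ctrl_ct - mean_ct
    data.frame(
      sample_id = sm$sample_id[1],
      compound_id = sm$compound_id[1],
      condition = sm$condition[1],
      ratio = pfaffl_ratio(dct[[target_gene]], dct[reference_genes],
                           eff[[target_gene]], eff[reference_genes]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$compound_id, out$sample_id), , drop = FALSE]
}
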