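# Per-plate fold-change normalization to plate controls, control-SD-derived
# symmetric hit thresholds and replicate-consensus hit classification.
#
# The screen's hit rule: a compound is an effective modulator when its
# luciferase fold change versus untreated controls lies more than k standard
# deviations (k = 4) of the control fold-change distribution away from 1.

#' Normalize one plate to its control wells
#'
#' Divides every well's signal by the mean signal of the plate's reference
#' control wells, yielding fold changes on the linear scale. Control wells
#' receive fold changes as well — they are what the hit threshold's SD is
#' estimated from — and their per-plate mean is exactly 1 by construction.
#' Normalization is invariant to any positive multiplicative rescaling of
#' the whole plate, which is what makes fold changes comparable across
#' plates with different overall signal levels.
#'
#' @param plate Plate data frame from [plate_wells()].
#' @param control_type Reference wells: `"untreated_control"` for the
#'   primary screen, `"vehicle_control"` for DMSO-normalized validation
#'   assays.
#' @param min_controls Minimum usable control wells (default 3).
#' @return Data frame of fold-change records: `compound_id`,
#'   `replicate`, `plate_id`, `well_type`, `fold_change`. Wells with
#'   missing signal are excluded.
#' @export
normalize_plate <- function(plate, control_type = "untreated_control",
                            min_controls = 3L) {
  ctrl <- control_wells(plate, control_type)
  ctrl_sig <- ctrl$signal[!is.na(ctrl$signal)]
  if (length(ctrl_sig) < min_controls) {
    stop("plate ", plate$plate_id[1], ": ", length(ctrl_sig), " usable ",
         control_type, " wells, need >= ", min_controls)
  }
  m <- mean(ctrl_sig)
  if (m == 0) {
    stop("plate ", plate$plate_id[1], ": control mean signal is 0, ",
         "plate is degenerate")
  }
  keep <- !is.na(plate$signal) & plate$well_type != "empty"
  w <- plate[keep, , drop = FALSE]
  data.frame(
    compound_id = w$compound_id,
    replicate = w$replicate,
    plate_id = w$plate_id,
    well_type = w$well_type,
    fold_change = w$signal / m,
    stringsAsFactors = FALSE
  )
}

#' Normalize every plate of a run
#'
#' @inheritParams normalize_plate
#' @param run A [screen_run()].
#' @return Row-bound fold-change records of all plates.
#' @export
normalize_run <- function(run, control_type = "untreated_control",
                          min_controls = 3L) {
  stopifnot(inherits(run, "screen_run"))
  assert_control_complement(run, control_type, min_controls)
  recs <- lapply(plate_ids(run), function(pid) {
    normalize_plate(plate_wells(run, pid), control_type, min_controls)
  })
  do.call(rbind, recs)
}

#' Hit threshold from the control fold-change distribution
#'
#' Pools the reference-control fold changes across all plates of the run and
#' sets symmetric hit bounds `1 - k*sd` and `1 + k*sd` around the unit
#' control ratio (the screen's cutoff uses k = 4; with control SD 0.0825
#' the offset is 0.33 and the bounds are 0.67 / 1.33).
#'
#' @param records Fold-change records from [normalize_run()].
#' @param k SD multiplier (default 4).
#' @param control_type Which control wells define the null distribution.
#' @return An object of class `hit_threshold` with fields `control_sd`,
#'   `k`, `offset`, `lower_bound`, `upper_bound`, `n_controls`.
#' @export
estimate_control_sd <- function(records, k = 4,
                                control_type = "untreated_control") {
  stopifnot(k > 0)
  fc <- records$fold_change[records$well_type == control_type]
  if (length(fc) < 2) {
    stop("need >= 2 control fold changes to estimate the null SD, got ",
         length(fc))
  }
  hit_threshold(stats::sd(fc), k = k, n_controls = length(fc))
}

#' Construct a hit threshold from a known control SD
#'
#' @param control_sd Standard deviation of control fold changes (n-1
#'   denominator when estimated).
#' @param k SD multiplier.
#' @param n_controls Number of control values behind the estimate, if known.
#' @return A `hit_threshold` object.
#' @export
hit_threshold <- function(control_sd, k = 4, n_controls = NA_integer_) {
  stopifnot(control_sd >= 0, k > 0)
  offset <- k * control_sd
  lower <- 1 - offset
  upper <- 1 + offset
  if (lower <= 0) {
    stop("lower hit bound 1 - k*sd = ", signif(lower, 4),
         " is not positive; threshold unusable on the fold-change scale")
  }
  if (control_sd == 0) {
    warning("control SD is 0: degenerate threshold, every non-unit ",
            "fold change is a hit")
  }
  structure(
    list(control_sd = control_sd, k = k, offset = offset,
         lower_bound = lower, upper_bound = upper,
         n_controls = as.integer(n_controls)),
    class = "hit_threshold"
  )
}

#' @export
print.hit_threshold <- function(x, ...) {
  cat(sprintf(
    "<hit_threshold> control SD %.4g (n = %s), k = %g, offset %.4g, bounds (%.4g, %.4g)\n",
    x$control_sd, ifelse(is.na(x$n_controls), "?", x$n_controls),
    x$k, x$offset, x$lower_bound, x$upper_bound))
  invisible(x)
}

#' Classify compounds against the hit threshold
#'
#' Aggregates per-replicate fold changes per compound and compares the
#' consensus to the threshold bounds, strictly: a compound is an `activator`
#' when beyond the upper bound, an `inhibitor` when beyond the lower bound,
#' `inactive` otherwise (boundary values are inactive — the rule is "more
#' than" the cutoff). Consensus rules:
#' \describe{
#'   \item{`mean`}{the mean fold change over replicates is compared to the
#'     bounds (default).}
#'   \item{`majority`}{more than half of the replicates must individually
#'     fall on the same side outside the bounds.}
#'   \item{`all`}{every replicate must fall on the same side outside the
#'     bounds.}
#' }
#' The reported `mean_fold_change` is always the replicate mean.
#'
#' @param records Fold-change records from [normalize_run()].
#' @param threshold A [hit_threshold()].
#' @param consensus Consensus rule, see above.
#' @return Data frame: `compound_id`, `mean_fold_change`, `classification`
#'   (factor activator/inhibitor/inactive), `n_replicates_used`.
#' @export
call_hits <- function(records, threshold,
                      consensus = c("mean", "majority", "all")) {
  consensus <- match.arg(consensus)
  stopifnot(inherits(threshold, "hit_threshold"))
  cmpd <- records[records$well_type == "compound" & !is.na(records$compound_id), ]
  if (nrow(cmpd) == 0) {
    warning("no compound records to classify")
    return(data.frame(compound_id = character(0),
                      mean_fold_change = numeric(0),
                      classification = factor(character(0),
                                              levels = HIT_CLASSES),
                      n_replicates_used = integer(0)))
  }
  lo <- threshold$lower_bound
  hi <- threshold$upper_bound
  per <- split(cmpd$fold_change, cmpd$compound_id)
  cls <- vapply(per, function(fc) {
    m <- mean(fc)
    side <- ifelse(fc > hi, 1L, ifelse(fc < lo, -1L, 0L))
    switch(consensus,
      mean = if (m > hi) "activator" else if (m < lo) "inhibitor" else "inactive",
      majority = {
        if (sum(side == 1L) > length(fc) / 2) "activator"
        else if (sum(side == -1L) > length(fc) / 2) "inhibitor"
        else "inactive"
      },
      all = {
        if (all(side == 1L)) "activator"
        else if (all(side == -1L)) "inhibitor"
        else "inactive"
      })
  }, character(1))
  data.frame(
    compound_id = names(per),
    mean_fold_change = vapply(per, mean, numeric(1)),
    classification = factor(cls, levels = HIT_CLASSES),
    n_replicates_used = lengths(per),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

HIT_CLASSES <- c("activator", "inhibitor", "inactive")
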