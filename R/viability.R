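# Viability fractions from resazurin signals and live/dead counts, and the
# rule-based toxic / non-toxic verdict over a concentration series.

#' Resazurin viability fraction
#'
#' Bulk metabolic viability: mean treated signal divided by mean vehicle
#' control signal. Assay noise can push the ratio above 1; values are
#' clamped to `[0, 1]` with a warning, since a viability fraction above 1
#' has no biological meaning.
#'
#' @param treated_signals Numeric vector (>= 1 value) of treated-well
#'   signals.
#' @param control_signals Numeric vector (>= 3 values) of vehicle-control
#'   signals.
#' @return Viability fraction in `[0, 1]`.
#' @export
resazurin_viability <- function(treated_signals, control_signals) {
  treated_signals <- treated_signals[!is.na(treated_signals)]
  control_signals <- control_signals[!is.na(control_signals)]
  if (length(treated_signals) < 1) stop("need >= 1 treated signal")
  if (length(control_signals) < 3) stop("need >= 3 control signals")
  m <- mean(control_signals)
  if (m == 0) stop("control mean signal is 0; resazurin assay degenerate")
  v <- mean(treated_signals) / m
  clamp_viability(v)
}

#' Live/dead-count viability fraction
#'
#' High-content-screen readout: fraction of counted cells alive,
#' `live / (live + dead)`.
#'
#' @param live_count,dead_count Non-negative integer counts per well.
#' @return Viability fraction in `[0, 1]`.
#' @export
hcs_viability <- function(live_count, dead_count) {
  stopifnot(live_count >= 0, dead_count >= 0)
  total <- live_count + dead_count
  if (any(total == 0)) stop("live + dead = 0: viability undefined for well")
  live_count / total
}

clamp_viability <- function(v) {
  if (any(v > 1)) {
    warning(sum(v > 1), " viability value(s) > 1 clamped to 1")
    v <- pmin(v, 1)
  }
  pmax(v, 0)
}

#' Dose-response viability profile
#'
#' @param compound_id Compound identifier.
#' @param assay `"resazurin"` or `"hcs_count"`.
#' @param concentration_uM Strictly increasing concentrations (micromolar).
#' @param viability Viability fractions at those concentrations (values
#'   above 1 are clamped with a warning).
#' @return An object of class `dose_response_profile`.
#' @export
dose_response_profile <- function(compound_id, assay = c("resazurin", "hcs_count"),
                                  concentration_uM, viability) {
  assay <- match.arg(assay)
  stopifnot(length(concentration_uM) == length(viability),
            length(concentration_uM) >= 1)
  o <- order(concentration_uM)
  concentration_uM <- concentration_uM[o]
  viability <- clamp_viability(viability[o])
  if (any(diff(concentration_uM) <= 0)) {
    stop("concentrations must be strictly increasing")
  }
  structure(
    list(compound_id = compound_id, assay = assay,
         points = data.frame(concentration_uM = concentration_uM,
                             viability = viability)),
    class = "dose_response_profile"
  )
}

#' Toxicity verdict from paired dose-response profiles
#'
#' A compound is toxic when its viability drops below `threshold` in
#' *either* assay at *any* tested concentration at or below the screen's
#' treatment concentration. Concentrations above the screen concentration
#' do not count: toxicity beyond the tested dose cannot confound the screen
#' signal. The verdict is rule-based on the measured points; no
#' dose-response curve is fitted.
#'
#' @param profiles List of [dose_response_profile()] objects for one
#'   compound (typically one resazurin + one live/dead-count profile).
#' @param assay_concentration Screen treatment concentration (micromolar).
#' @param threshold Viability fraction below which a dose counts as toxic
#'   (default 0.70, the conventional cytotoxicity bound).
#' @return A one-row data frame: `compound_id`, `toxic`,
#'   `min_toxic_concentration` (`NA` when non-toxic), `threshold`,
#'   `assay_concentration`.
#' @export
classify_toxicity <- function(profiles, assay_concentration, threshold = 0.70) {
  if (inherits(profiles, "dose_response_profile")) profiles <- list(profiles)
  stopifnot(length(profiles) >= 1,
            all(vapply(profiles, inherits, logical(1), "dose_response_profile")))
  ids <- unique(vapply(profiles, `[[`, character(1), "compound_id"))
  if (length(ids) != 1) {
    stop("profiles mix compounds: ", paste(ids, collapse = ", "))
  }
  pts <- do.call(rbind, lapply(profiles, `[[`, "points"))
  in_range <- pts$concentration_uM <= assay_concentration
  if (!any(in_range)) {
    stop("no tested concentration at or below the assay concentration (",
         assay_concentration, " uM) for ", ids)
  }
  offending <- pts[in_range & pts$viability < threshold, , drop = FALSE]
  toxic <- nrow(offending) > 0
  data.frame(
    compound_id = ids,
    toxic = toxic,
    min_toxic_concentration = if (toxic) min(offending$concentration_uM) else NA_real_,
    threshold = threshold,
    assay_concentration = assay_concentration,
    stringsAsFactors = FALSE
  )
}

#' Toxicity table from raw viability input tables
#'
#' Convenience wrapper: builds per-compound resazurin and live/dead-count
#' profiles from long tables and classifies each compound.
#'
#' @param resazurin Data frame `{compound_id, concentration_uM, signal}` of
#'   treated wells, plus vehicle-control rows identified by
#'   `compound_id == control_id`.
#' @param hcs Data frame `{compound_id, concentration_uM, live, dead}`.
#' @param assay_concentration,threshold Passed to [classify_toxicity()].
#' @param control_id Identifier of the vehicle-control rows in `resazurin`.
#' @return Row-bound toxicity calls, one row per compound.
#' @export
toxicity_table <- function(resazurin, hcs, assay_concentration,
                           threshold = 0.70, control_id = "DMSO") {
  ctrl <- resazurin$signal[resazurin$compound_id == control_id]
  if (length(ctrl) < 3) stop("need >= 3 vehicle-control resazurin signals")
  res <- resazurin[resazurin$compound_id != control_id, , drop = FALSE]
  ids <- sort(unique(c(res$compound_id, hcs$compound_id)))
  calls <- lapply(ids, function(id) {
    profs <- list()
    r <- res[res$compound_id == id, , drop = FALSE]
    if (nrow(r) > 0) {
      agg <- vapply(split(r$signal, r$concentration_uM),
                    function(s) suppressWarnings(resazurin_viability(s, ctrl)),
                    numeric(1))
      profs <- c(profs, list(dose_response_profile(
        id, "resazurin", as.numeric(names(agg)), unname(agg))))
    }
    h <- hcs[hcs$compound_id == id, , drop = FALSE]
    if (nrow(h) > 0) {
      h <- h[order(h$concentration_uM), ]
      profs <- c(profs, list(dose_response_profile(
        id, "hcs_count", h$concentration_uM,
        hcs_viability(h$live, h$dead))))
    }
    classify_toxicity(profs, assay_concentration, threshold)
  })
  do.call(rbind, calls)
}

#' Rank hits by potency
#'
#' Utility ranking by distance of the consensus fold change from 1 (largest
#' deviation first). This is one plausible reading of "most potent"; it is a
#' helper for selecting candidates into follow-up assays, not an asserted
#' property of the original study's (unstated) ranking.
#'
#' @param hits Hit-call table from [call_hits()].
#' @return `hits` sorted by decreasing `abs(mean_fold_change - 1)`.
#' @export
rank_by_potency <- function(hits) {
  hits[order(abs(hits$mean_fold_change - 1), decreasing = TRUE), , drop = FALSE]
}
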