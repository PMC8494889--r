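# Loading- and vehicle-normalized protein quantification for In-Cell
# Western (CellTag700 reference) and Western blot (actin / Lamin B1
# reference) signals.

#' Loading-reference normalization
#'
#' Target signal divided by its loading reference (actin, CellTag700 whole
#' cell stain, or Lamin B1 for nuclear extracts). The ratio is invariant to
#' scanner gain: scaling both channels by a common factor cancels.
#'
#' @param target_signal Non-negative target-channel signal(s).
#' @param loading_signal Positive loading-channel signal(s).
#' @return `target_signal / loading_signal`.
#' @export
loading_normalize <- function(target_signal, loading_signal) {
  stopifnot(all(target_signal >= 0))
  if (any(loading_signal <= 0)) {
    stop("loading signal must be positive; 0 means no material loaded")
  }
  if (any(target_signal == 0)) {
    warning(sum(target_signal == 0), " sample(s) with zero target signal")
  }
  target_signal / loading_signal
}

#' Background subtraction for In-Cell Western channels
#'
#' Subtracts the mean of the secondary-antibody-only background wells from
#' every signal, per channel, before loading normalization. Signals driven
#' below zero by subtraction clamp to 0 with a warning.
#'
#' @param signal Numeric signals of the assay wells.
#' @param background_signal Signals of the background-control wells.
#' @return Background-corrected signals (>= 0).
#' @export
subtract_background <- function(signal, background_signal) {
  if (length(background_signal) == 0) return(signal)
  corrected <- signal - mean(background_signal)
  if (any(corrected < 0)) {
    warning(sum(corrected < 0),
            " signal(s) below background clamped to 0")
    corrected <- pmax(corrected, 0)
  }
  corrected
}

#' Fold changes versus the vehicle group
#'
#' Divides each sample's loading-normalized ratio by the mean ratio of the
#' vehicle (DMSO) samples, so the vehicle group's own mean fold change is
#' exactly 1 and compound effects read as multiples of the vehicle level.
#'
#' @param ratios Per-sample loading-normalized values.
#' @param compound_id Compound label per sample; vehicle samples carry
#'   `vehicle_id`.
#' @param vehicle_id Label of the vehicle samples (default `"DMSO"`).
#' @return Data frame with one row per sample: `compound_id`,
#'   `fold_change`; attribute `summary` holds the per-compound mean and n.
#' @export
fold_change_vs_vehicle <- function(ratios, compound_id, vehicle_id = "DMSO") {
  stopifnot(length(ratios) == length(compound_id))
  veh <- ratios[compound_id == vehicle_id]
  if (length(veh) < 2) {
    stop("need >= 2 vehicle ('", vehicle_id, "') samples, got ", length(veh))
  }
  fc <- ratios / mean(veh)
  out <- data.frame(compound_id = compound_id, fold_change = fc,
                    stringsAsFactors = FALSE)
  agg <- stats::aggregate(fold_change ~ compound_id, data = out,
                          FUN = function(x) c(mean = mean(x), n = length(x)))
  summ <- data.frame(compound_id = agg$compound_id,
                     mean_fold_change = agg$fold_change[, "mean"],
                     n = as.integer(agg$fold_change[, "n"]),
                     stringsAsFactors = FALSE)
  attr(out, "summary") <- summ
  out
}

#' Protein fold-change table from a raw signal table
#'
#' Full normalization path for one assay: optional per-channel background
#' subtraction (rows with `compound_id == "BACKGROUND"`), loading
#' normalization, then vehicle normalization — computed within each
#' membrane / plate batch separately, since loading references are only
#' comparable within a blot, and pooled afterwards.
#'
#' @param signals Data frame `{sample_id, compound_id, batch_id,
#'   target_signal, loading_signal}`; background wells flagged by
#'   `compound_id == "BACKGROUND"`.
#' @param vehicle_id Vehicle label (default `"DMSO"`).
#' @param subtract_bg Apply background subtraction when background rows are
#'   present (default TRUE).
#' @return Per-sample fold-change table `{sample_id, compound_id, batch_id,
#'   fold_change}` with a per-compound `summary` attribute (pooled over
#'   batches).
#' @export
protein_fold_change_table <- function(signals, vehicle_id = "DMSO",
                                      subtract_bg = TRUE) {
  need <- c("sample_id", "compound_id", "batch_id", "target_signal",
            "loading_signal")
  missing_cols <- setdiff(need, names(signals))
  if (length(missing_cols) > 0) {
    stop("signal table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  per_batch <- lapply(split(signals, signals$batch_id), function(b) {
    is_bg <- b$compound_id == "BACKGROUND"
    s <- b[!is_bg, , drop = FALSE]
    tgt <- s$target_signal
    load <- s$loading_signal
    if (subtract_bg && any(is_bg)) {
      tgt <- subtract_background(tgt, b$target_signal[is_bg])
      load <- subtract_background(load, b$loading_signal[is_bg])
      if (any(load <= 0)) {
        stop("batch ", b$batch_id[1],
             ": loading signal not above background")
      }
    }
    ratio <- loading_normalize(tgt, load)
    fc <- fold_change_vs_vehicle(ratio, s$compound_id, vehicle_id)
    data.frame(sample_id = s$sample_id, compound_id = s$compound_id,
               batch_id = s$batch_id, fold_change = fc$fold_change,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(per_batch, list(make.row.names = FALSE)))
  agg <- stats::aggregate(fold_change ~ compound_id, data = out,
                          FUN = function(x) c(mean = mean(x), n = length(x)))
  attr(out, "summary") <- data.frame(
    compound_id = agg$compound_id,
    mean_fold_change = agg$fold_change[, "mean"],
    n = as.integer(agg$fold_change[, "n"]),
    stringsAsFactors = FALSE)
  out
}
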