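# In-code fixtures shared across test files.

# minimal valid well table: n compound wells + controls on one plate
make_well_table <- function(n_compound = 2, n_untreated = 3, n_vehicle = 1,
                            plate_id = "P1", replicate = 1,
                            compound_signal = 100, control_signal = 100) {
  n <- n_compound + n_untreated + n_vehicle
  stopifnot(n <= 24)
  data.frame(
    plate_id = plate_id,
    replicate = replicate,
    row = "A",
    col = seq_len(n),
    well_type = rep(c("compound", "untreated_control", "vehicle_control"),
                    times = c(n_compound, n_untreated, n_vehicle)),
    compound_id = c(sprintf("C%02d", seq_len(n_compound)),
                    rep(NA_character_, n_untreated + n_vehicle)),
    concentration_uM = c(rep(10, n_compound),
                         rep(NA_real_, n_untreated + n_vehicle)),
    signal = rep(c(compound_signal, control_signal, control_signal),
                 times = c(n_compound, n_untreated, n_vehicle)),
    stringsAsFactors = FALSE
  )
}

# effect table with a standard mix of ground-truth classes
make_mixed_effects <- function(n_total = 50, n_specific_act = 3,
                               n_pleio_act = 2, n_toxic_inh = 5,
                               n_clean_inh = 0,
                               act_fc = 1.6, inh_fc = 0.5, toxic_ic = 2) {
  stopifnot(n_specific_act + n_pleio_act + n_toxic_inh + n_clean_inh <= n_total)
  ids <- sprintf("C%03d", seq_len(n_total))
  fc <- rep(1, n_total)
  specific <- rep(TRUE, n_total)
  ic <- rep(NA_real_, n_total)
  i <- 0
  idx_spec <- seq_len(n_specific_act); i <- n_specific_act
  idx_pleio <- i + seq_len(n_pleio_act); i <- i + n_pleio_act
  idx_tox <- i + seq_len(n_toxic_inh); i <- i + n_toxic_inh
  idx_inh <- i + seq_len(n_clean_inh)
  fc[idx_spec] <- act_fc
  fc[idx_pleio] <- act_fc
  specific[idx_pleio] <- FALSE
  fc[c(idx_tox, idx_inh)] <- inh_fc
  ic[idx_tox] <- toxic_ic
  effect_model(ids, true_luc_fc = fc, specific = specific, toxic_ic = ic)
}

expect_no_hit_warning <- function(expr) {
  suppressWarnings(expr)
}
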