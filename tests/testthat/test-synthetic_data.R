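test_that("effect and noise model constructors validate their invariants", {
  expect_error(effect_model(c("a", "a")), "duplicate")
  expect_error(effect_model("a", true_luc_fc = 0), "positive")
  expect_error(effect_model("a", hill_slope = -1), "positive")
  # inert compounds may not be toxic
  expect_error(effect_model("a", true_luc_fc = 1, toxic_ic = 5),
               "inert")
  expect_silent(effect_model("a", true_luc_fc = 0.5, toxic_ic = 5))
  expect_error(noise_model(), "seed")
  expect_error(noise_model(well_cv = -0.1, seed = 1))
})

test_that("zero-noise inert screens yield unit fold changes and no hits", {
  ef <- effect_model(sprintf("C%02d", 1:20))  # all inert
  g <- generate_screen(ef, noise_free(1))
  rec <- normalize_run(g$run)
  expect_equal(rec$fold_change[rec$well_type %in%
                                 c("compound", "untreated_control")],
               rep(1, sum(rec$well_type %in%
                            c("compound", "untreated_control"))),
               tolerance = 1e-12)
  hits <- call_hits(rec, hit_threshold(0.02, k = 4))
  expect_true(all(hits$classification == "inactive"))
})

test_that("plate scale factors cancel and effects pass through exactly", {
  ef <- effect_model(c("up", "down", "flat"), true_luc_fc = c(1.8, 0.5, 1))
  g <- generate_screen(ef, noise_model(well_cv = 0, plate_factor_sd = 0.3,
                                       ct_sd = 0, seed = 2))
  rec <- normalize_run(g$run)
  cmp <- rec[rec$well_type == "compound", ]
  for (id in ef$compound_id) {
    expect_equal(cmp$fold_change[cmp$compound_id == id],
                 rep(ef$true_luc_fc[ef$compound_id == id], 3),
                 tolerance = 1e-12)
  }
})

test_that("compound placement is re-randomized across replicates", {
  ef <- effect_model(sprintf("C%03d", 1:300))
  g <- generate_screen(ef, noise_model(seed = 17))
  w <- g$run$wells[g$run$wells$well_type == "compound", ]
  addr <- well_address(w$row, w$col)
  same12 <- vapply(split(paste(w$plate_id, addr), w$compound_id),
                   function(a) a[1] == a[2], logical(1))
  # chance of keeping the same slot is ~1/(n_slots); with 300 compounds the
  # expected count is << 5
  expect_lt(sum(same12), 5)
  # controls stay at fixed addresses on every plate
  ctrl <- g$run$wells[g$run$wells$well_type == "untreated_control", ]
  per_plate <- split(well_address(ctrl$row, ctrl$col), ctrl$plate_id)
  expect_true(all(vapply(per_plate, function(a) {
    identical(sort(a), sort(per_plate[[1]]))
  }, logical(1))))
})

test_that("identical seed and configuration reproduce bundles exactly", {
  ef <- make_mixed_effects(n_total = 25)
  b1 <- generate_validation_bundle(ef, noise_model(seed = 123))
  b2 <- generate_validation_bundle(ef, noise_model(seed = 123))
  expect_identical(b1$screen$wells, b2$screen$wells)
  expect_identical(b1$qpcr_wt, b2$qpcr_wt)
  expect_identical(b1$protein_icw, b2$protein_icw)
  b3 <- generate_validation_bundle(ef, noise_model(seed = 124))
  expect_false(identical(b1$screen$wells$signal, b3$screen$wells$signal))
})

test_that("generators do not disturb the caller's RNG stream", {
  ef <- make_mixed_effects(n_total = 10)
  set.seed(55)
  before <- rnorm(3)
  set.seed(55)
  invisible(generate_screen(ef, noise_model(seed = 1)))
  after <- rnorm(3)
  expect_identical(before, after)
})

test_that("dose-response generation honors the Hill model", {
  ef <- effect_model(c("tox", "safe"), true_luc_fc = c(0.5, 1.3),
                     toxic_ic = c(5, NA), hill_slope = c(2, 2))
  dr <- generate_dose_response(ef, noise_free(3),
                               concentrations = c(0.25, 5, 40))
  res <- dr$resazurin
  # Hill midpoint: viability exactly 0.5 at c == toxic_ic
  sig_mid <- res$signal[res$compound_id == "tox" & res$concentration_uM == 5]
  sig_ctrl <- mean(res$signal[res$compound_id == "DMSO"])
  expect_equal(sig_mid / sig_ctrl, 0.5, tolerance = 1e-12)
  # non-toxic compounds stay at full viability
  expect_equal(res$signal[res$compound_id == "safe"] / sig_ctrl,
               rep(1, 3), tolerance = 1e-12)
  # counts follow the same curve
  hcs <- dr$hcs
  mid <- hcs[hcs$compound_id == "tox" & hcs$concentration_uM == 5, ]
  expect_equal(hcs_viability(mid$live, mid$dead), 0.5, tolerance = 1e-2)
})

test_that("CT generation encodes fold changes as cycle shifts", {
  ef <- effect_model("X", true_luc_fc = 2)
  base_ct <- c(LUC = 22, UBC = 20, GUSB = 25)
  tab <- generate_ct_table(ef, noise_free(4), "LUC", c("UBC", "GUSB"),
                           base_ct)
  trt <- tab[tab$compound_id == "X" & tab$gene_id == "LUC", ]
  ctl <- tab[tab$condition == "DMSO" & tab$gene_id == "LUC", ]
  # true fold change 2 at efficiency 2: exactly one cycle earlier
  expect_equal(unique(trt$ct), unique(ctl$ct) - 1, tolerance = 1e-12)
  # reference genes unaffected
  for (g in c("UBC", "GUSB")) {
    expect_equal(unique(tab$ct[tab$gene_id == g]), base_ct[[g]],
                 tolerance = 1e-12)
  }
  expect_error(
    generate_ct_table(ef, noise_free(4), "LUC", "UBC", c(LUC = 22, UBC = 40)),
    "\\(10, 35\\)")
})

test_that("counter-screen tables silence specific compounds only", {
  ef <- effect_model(c("spec", "pleio"), true_luc_fc = c(1.8, 1.8),
                     specific = c(TRUE, FALSE))
  g6 <- generate_screen(ef, noise_free(5), line = "counter")
  rec <- normalize_run(g6$run)
  cmp <- rec[rec$well_type == "compound", ]
  expect_equal(unique(cmp$fold_change[cmp$compound_id == "spec"]), 1,
               tolerance = 1e-12)
  expect_equal(unique(cmp$fold_change[cmp$compound_id == "pleio"]), 1.8,
               tolerance = 1e-12)
  tab6 <- generate_ct_table(ef, noise_free(5), "LUC", c("UBC", "GUSB"),
                            c(LUC = 22, UBC = 20, GUSB = 25),
                            line = "counter")
  r6 <- relative_expression_table(tab6, "LUC", c("UBC", "GUSB"))
  expect_equal(r6$ratio[r6$compound_id == "spec"], 1, tolerance = 1e-9)
  expect_equal(r6$ratio[r6$compound_id == "pleio"], 1.8, tolerance = 1e-9)
})

test_that("control layout fills fixed addresses and respects capacity", {
  lay <- control_layout("w384", 22, 8, 2)
  expect_equal(nrow(lay), 32)
  expect_equal(sum(lay$well_type == "untreated_control"), 22)
  expect_true(all(lay$col >= 23))  # packed into the last columns
  expect_error(control_layout("w96", 90, 8, 2), "capacity")
})

test_that("calibration: control SD 0.0825 gives the printed 0.33 offset", {
  thr <- hit_threshold(0.0825, k = 4)
  expect_equal(thr$offset, 0.33, tolerance = 1e-12)
})
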