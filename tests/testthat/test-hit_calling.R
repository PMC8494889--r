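test_that("normalization divides by the plate's untreated-control mean", {
  # identical signals -> all fold changes 1
  tab <- make_well_table(compound_signal = 1000, control_signal = 1000)
  rec <- normalize_plate(screen_run(tab, n_replicates = 1)$wells)
  expect_true(all(rec$fold_change == 1))
  # forced arithmetic: {200, 50} vs controls {100, 100, 100}
  tab <- make_well_table()
  tab$signal <- c(200, 50, 100, 100, 100, 100)
  rec <- normalize_plate(screen_run(tab, n_replicates = 1)$wells)
  expect_equal(sort(rec$fold_change[rec$well_type == "compound"]), c(0.5, 2.0))
})

test_that("per-plate mean of untreated-control fold changes is exactly 1", {
  ef <- make_mixed_effects(n_total = 60)
  run <- generate_screen(ef, noise_model(seed = 21))$run
  rec <- normalize_run(run)
  for (pid in unique(rec$plate_id)) {
    ctrl <- rec$fold_change[rec$plate_id == pid &
                              rec$well_type == "untreated_control"]
    expect_equal(mean(ctrl), 1, tolerance = 1e-12)
  }
})

test_that("normalization is invariant to whole-plate rescaling", {
  ef <- make_mixed_effects(n_total = 20)
  run <- generate_screen(ef, noise_model(seed = 8), n_replicates = 1)$run
  pl <- plate_wells(run, plate_ids(run)[1])
  scaled <- pl
  scaled$signal <- scaled$signal * 1.7
  r1 <- normalize_plate(pl)
  r2 <- normalize_plate(scaled)
  expect_equal(r2$fold_change, r1$fold_change, tolerance = 1e-12)
})

test_that("degenerate plates raise errors", {
  tab <- make_well_table(control_signal = 0, compound_signal = 0)
  expect_error(normalize_plate(screen_run(tab, n_replicates = 1)$wells),
               "control mean signal is 0")
})

test_that("control-SD threshold reproduces known offsets and bounds", {
  thr <- hit_threshold(0.0825, k = 4)
  expect_equal(thr$offset, 0.33)
  expect_equal(thr$lower_bound, 0.67)
  expect_equal(thr$upper_bound, 1.33)
  # zero SD: degenerate threshold with warning, bounds collapse to 1
  expect_warning(thr0 <- hit_threshold(0, k = 4), "degenerate")
  expect_equal(c(thr0$lower_bound, thr0$upper_bound), c(1, 1))
  # unusably wide threshold is an error, not a negative bound
  expect_error(hit_threshold(0.3, k = 4), "not positive")
})

test_that("estimate_control_sd pools controls and recovers the generating SD", {
  # identical controls -> sd 0 with degenerate warning via hit_threshold
  rec <- data.frame(compound_id = NA, replicate = 1, plate_id = "P1",
                    well_type = "untreated_control", fold_change = rep(1, 5))
  expect_warning(thr <- estimate_control_sd(rec), "degenerate")
  expect_equal(thr$control_sd, 0)
  expect_error(estimate_control_sd(rec[1, ]), ">= 2 control")
  # >1000 simulated control fold changes: estimate within 10% of the
  # generating well CV
  ef <- make_mixed_effects(n_total = 5300, n_specific_act = 0,
                           n_pleio_act = 0, n_toxic_inh = 0)
  run <- generate_screen(ef, noise_model(well_cv = 0.08, seed = 31),
                         n_untreated = 22)$run
  thr <- estimate_control_sd(normalize_run(run), k = 4)
  expect_gte(thr$n_controls, 1000)
  expect_lt(abs(thr$control_sd - 0.08) / 0.08, 0.10)
})

test_that("hit classification respects bounds, strict ties and partitioning", {
  thr <- hit_threshold(0.0825, k = 4)  # bounds (0.67, 1.33)
  rec <- data.frame(
    compound_id = rep(c("up", "edge", "down", "flat"), each = 1),
    replicate = 1, plate_id = "P1", well_type = "compound",
    fold_change = c(1.40, 1.33, 0.50, 1.01))
  hits <- call_hits(rec, thr)
  got <- setNames(as.character(hits$classification), hits$compound_id)
  expect_equal(got[["up"]], "activator")
  expect_equal(got[["edge"]], "inactive")  # boundary is not "more than"
  expect_equal(got[["down"]], "inhibitor")
  expect_equal(got[["flat"]], "inactive")
  expect_equal(sum(table(hits$classification)), nrow(hits))
})

test_that("consensus rules mean / majority / all behave as documented", {
  thr <- hit_threshold(0.05, k = 4)  # bounds (0.8, 1.2)
  rec <- data.frame(
    compound_id = rep("A", 3), replicate = 1:3, plate_id = "P1",
    well_type = "compound", fold_change = c(1.5, 1.3, 1.1))
  expect_equal(as.character(call_hits(rec, thr, "mean")$classification),
               "activator")     # mean 1.3 > 1.2
  expect_equal(as.character(call_hits(rec, thr, "majority")$classification),
               "activator")     # 2 of 3 beyond
  expect_equal(as.character(call_hits(rec, thr, "all")$classification),
               "inactive")      # replicate 3 inside the band
})

test_that("bounds are monotone in k and in the control SD", {
  sds <- c(0.02, 0.05, 0.08)
  ks <- c(1, 2, 4)
  offsets <- outer(sds, ks)
  expect_true(all(diff(offsets[, 2]) > 0))  # wider with sd
  expect_true(all(diff(offsets[2, ]) > 0))  # wider with k
  for (sd in sds) for (k in ks) {
    thr <- hit_threshold(sd, k)
    expect_equal(thr$upper_bound - 1, 1 - thr$lower_bound)
  }
})

test_that("spiked activators are recovered on a noisy screen", {
  ids <- sprintf("C%03d", 1:200)
  fc <- rep(1, 200); fc[1:10] <- 1.6
  ef <- effect_model(ids, true_luc_fc = fc)
  g <- generate_screen(ef, noise_model(well_cv = 0.05, seed = 77))
  rec <- normalize_run(g$run)
  hits <- call_hits(rec, estimate_control_sd(rec, k = 4))
  spiked <- hits$classification[match(ids[1:10], hits$compound_id)]
  expect_true(all(spiked == "activator"))
  inert <- hits$classification[match(ids[11:200], hits$compound_id)]
  expect_lt(mean(inert != "inactive"), 0.05)
})
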