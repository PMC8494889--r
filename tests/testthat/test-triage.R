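test_that("toxicity filter removes toxic inhibitors and spares activators", {
  hits <- data.frame(
    compound_id = sprintf("I%03d", 1:94),
    mean_fold_change = 0.5,
    classification = factor("inhibitor", levels = c("activator", "inhibitor",
                                                    "inactive")),
    n_replicates_used = 3L, stringsAsFactors = FALSE)
  tox <- data.frame(compound_id = hits$compound_id,
                    toxic = c(rep(TRUE, 69), rep(FALSE, 25)))
  out <- apply_toxicity_filter(hits, tox)
  expect_equal(nrow(out), 25)
  expect_equal(length(attr(out, "removed")), 69)

  # empty hit list -> empty output
  empty <- apply_toxicity_filter(hits[0, ], tox)
  expect_equal(nrow(empty), 0)

  # a toxic-flagged activator passes, with a note
  hits2 <- hits[1:2, ]
  hits2$classification[1] <- "activator"
  tox2 <- data.frame(compound_id = hits2$compound_id, toxic = c(TRUE, FALSE))
  expect_message(out2 <- apply_toxicity_filter(hits2, tox2), "pass by design")
  expect_true(hits2$compound_id[1] %in% out2$compound_id)

  # inhibitor without a call is a coverage error
  expect_error(apply_toxicity_filter(hits, tox[-1, ]), "without a toxicity")
})

test_that("specificity calls follow the significant-and-quiet-counter rule", {
  band <- c(0.8, 1.25)
  sp <- classify_specificity("a", 1.8, TRUE, 1.05, band)
  expect_true(sp$specific)
  # not significant in the screening line: never specific
  expect_false(classify_specificity("a", 1.8, FALSE, 1.05, band)$specific)
  # pleiotropic: same response in the counter-screen line
  expect_false(classify_specificity("a", 1.8, TRUE, 1.8, band)$specific)
  expect_error(classify_specificity("a", 1.8, TRUE, NA, band),
               "missing counter-screen")
})

test_that("zero-noise cascade returns exactly the spiked specific activators", {
  ef <- make_mixed_effects(n_total = 50, n_specific_act = 3, n_pleio_act = 2,
                           n_toxic_inh = 5)
  b <- generate_validation_bundle(ef, noise_free(42))
  rep <- suppressWarnings(run_triage(b))
  expect_equal(rep$final_candidates,
               sort(b$truth$compound_id[b$truth$final_candidate]))
  # pleiotropic activators fall at the counter-screen stage
  pleio <- b$truth$compound_id[b$truth$luc_label == "activator" &
                                 !b$truth$specific]
  expect_true(all(rep$stages[pleio, "specificity_a6"] ==
                    "fail: pleiotropic in counter-screen"))
  # toxic inhibitors fall at the toxicity stage
  toxinh <- b$truth$compound_id[b$truth$luc_label == "inhibitor" &
                                  b$truth$toxic]
  expect_true(all(rep$stages[toxinh, "toxicity"] == "fail: toxic"))
})

test_that("stage survivors are nested and exclusions account for every hit", {
  ef <- make_mixed_effects(n_total = 60, n_specific_act = 4, n_pleio_act = 3,
                           n_toxic_inh = 6, n_clean_inh = 3)
  b <- generate_validation_bundle(ef, noise_model(well_cv = 0.03, seed = 7))
  rep <- suppressWarnings(run_triage(b))
  n_hits <- sum(rep$hits$classification != "inactive")
  log <- rep$exclusion_log
  excluded_hits <- log$compound_id[log$stage != "luc_class" |
                                     grepl("cap", log$reason)]
  incomplete <- unlist(rep$incomplete, use.names = FALSE)
  expect_equal(length(unique(excluded_hits)) + length(unique(incomplete)) +
                 length(rep$final_candidates), n_hits)
  # no stage overwrites an earlier exclusion: excluded compounds carry NA
  # for all later stages
  tox_fail <- log$compound_id[log$stage == "toxicity"]
  if (length(tox_fail) > 0) {
    expect_true(all(is.na(rep$stages[tox_fail, "luc_qpcr_a1"])))
  }
})

test_that("a screen with no hits yields an empty but complete report", {
  ef <- effect_model(sprintf("C%02d", 1:30))  # all inert
  b <- generate_validation_bundle(ef, noise_model(well_cv = 0.03, seed = 9))
  rep <- suppressWarnings(run_triage(b))
  expect_length(rep$final_candidates, 0)
  expect_equal(nrow(rep$stages), 30)
  expect_true(all(stats::complete.cases(rep$stages[, c("compound_id",
                                                       "luc_class")])))
})

test_that("triage reports are deterministic and serialize byte-identically", {
  ef <- make_mixed_effects(n_total = 40)
  b <- generate_validation_bundle(ef, noise_model(seed = 31))
  r1 <- suppressWarnings(run_triage(b))
  r2 <- suppressWarnings(run_triage(b))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_triage_report(r1, d1)
  write_triage_report(r2, d2)
  expect_identical(readLines(file.path(d1, "triage_report.json")),
                   readLines(file.path(d2, "triage_report.json")))
  expect_identical(readLines(file.path(d1, "candidates.csv")),
                   readLines(file.path(d2, "candidates.csv")))
})

test_that("potency caps limit the follow-up set by effect size", {
  ef <- make_mixed_effects(n_total = 40, n_specific_act = 6, n_pleio_act = 0,
                           n_toxic_inh = 0)
  # grade the activator strengths so the cap has an unambiguous order
  ef$true_luc_fc[1:6] <- c(2.0, 1.9, 1.8, 1.7, 1.6, 1.5)
  b <- generate_validation_bundle(ef, noise_free(13))
  cfg <- triage_config(cap_activators = 3)
  rep <- suppressWarnings(run_triage(b, cfg))
  expect_equal(rep$final_candidates, sprintf("C%03d", 1:3))
  capped <- rep$exclusion_log[grepl("cap", rep$exclusion_log$reason), ]
  expect_setequal(capped$compound_id, sprintf("C%03d", 4:6))
})
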