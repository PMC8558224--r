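test_that("the cohort plan has the full session grid and valid SMEQ scores", {
  co <- simulate_cohort(14, tiny_paradigm(20), acquisition = scaled_acq(),
                        seed = 1)
  expect_equal(nrow(co), 14 * 4)
  expect_setequal(unique(co$condition), c("low", "high"))
  expect_setequal(unique(co$session), c("pre", "post"))
  expect_true(all(co$smeq >= 0 & co$smeq <= 150))
  expect_true(all(co$hep_gain > 0))
  # high workload shortens the RR interval
  expect_true(all(co$mean_rr[co$condition == "high"] == 0.79))
  expect_true(all(co$mean_rr[co$condition == "low"] == 0.81))
  co2 <- simulate_cohort(14, tiny_paradigm(20), acquisition = scaled_acq(),
                         seed = 1)
  expect_identical(co$amplitude, co2$amplitude)
  expect_identical(co$seed, co2$seed)
  expect_error(simulate_cohort(1), "at least 2")
})

test_that("a null effect configuration yields near-zero effect sizes", {
  eff0 <- effect_config(amplitude_g = 0, latency_g = 0)
  co <- simulate_cohort(8, tiny_paradigm(25), effect = eff0,
                        acquisition = scaled_acq(), seed = 2)
  fe <- suppressWarnings(cohort_features(co))
  di <- feature_differences(fe)
  wide <- tidyr::pivot_wider(
    di[di$partition == "ERP_A-HEP" & di$measure == "amplitude", ],
    names_from = "condition", values_from = "value"
  )
  gs <- vapply(split(wide, wide$electrode), function(d) {
    hedges_g(mean(d$low), sd(d$low), mean(d$high), sd(d$high),
             n1 = nrow(d), n2 = nrow(d))
  }, numeric(1))
  expect_lt(abs(mean(gs)), 1)
})

test_that("cohort features line up with the plan and partition counts add up", {
  co <- simulate_cohort(2, tiny_paradigm(25), acquisition = scaled_acq(),
                        seed = 3)
  fe <- suppressWarnings(cohort_features(co))
  # 2 subjects x 4 sessions x 3 partitions x 8 electrodes x 2 measures
  expect_equal(nrow(fe), 2 * 4 * 3 * 8 * 2)
  counts <- attr(fe, "counts")
  wide <- tidyr::pivot_wider(counts, names_from = "partition",
                             values_from = "n_epochs")
  expect_equal(wide$ERP_T, wide$ERP_HEP + wide$`ERP_A-HEP`)
  di <- feature_differences(fe)
  expect_equal(nrow(di), 2 * 2 * 3 * 8 * 2)
  # diffs really are post minus pre
  one <- fe[fe$subject == 1 & fe$condition == "low" &
              fe$partition == "ERP_T" & fe$electrode == "P3" &
              fe$measure == "amplitude", ]
  expect_equal(
    di$value[di$subject == 1 & di$condition == "low" &
               di$partition == "ERP_T" & di$electrode == "P3" &
               di$measure == "amplitude"],
    one$value[one$session == "post"] - one$value[one$session == "pre"]
  )
})

test_that("the full pipeline runs, reports all partitions and is
           reproducible", {
  cfg <- pipeline_config(
    n_subjects = 4,
    paradigm = tiny_paradigm(25),
    classifier = classifier_spec(kernel_scale = 4, folds = 4),
    seed = 11
  )
  res1 <- suppressWarnings(run_pipeline(cfg))
  expect_s3_class(res1$effects, "effect_size_report")
  expect_setequal(unique(res1$effects$partition),
                  c("ERP_T", "ERP_HEP", "ERP_A-HEP"))
  expect_setequal(res1$classification$summary$partition,
                  c("ERP_T", "ERP_HEP", "ERP_A-HEP"))
  expect_equal(unique(res1$effects$alpha_family), 0.05 / 16)
  expect_equal(nrow(res1$correlations), 3 * 8 * 2)
  expect_true(all(abs(res1$correlations$r_partial) <= 1))
  res2 <- suppressWarnings(run_pipeline(cfg))
  expect_identical(res1$diffs, res2$diffs)
  expect_identical(res1$classification$summary, res2$classification$summary)
  expect_identical(res1$provenance$config_hash, res2$provenance$config_hash)

  out <- withr::local_tempdir()
  paths <- write_report(res1, out)
  expect_true(file.exists(file.path(out, "classification.tsv")))
  expect_true(file.exists(file.path(out, "effects_amplitude.tsv")))
  expect_true(file.exists(file.path(out, "report.json")))
  # round-trip: the classification table re-reads identically
  back <- utils::read.delim(file.path(out, "classification.tsv"))
  expect_equal(back$accuracy, res1$classification$summary$accuracy)
})

test_that("a minimal two-subject cohort runs with a low-n warning", {
  cfg <- pipeline_config(
    n_subjects = 2,
    paradigm = tiny_paradigm(20),
    classifier = classifier_spec(kernel_scale = 4, folds = 2),
    seed = 12
  )
  w <- testthat::capture_warnings(res <- run_pipeline(cfg))
  expect_true(any(grepl("unstable", w)))
  expect_equal(nrow(res$smeq), 1)
})

test_that("event tables and ground truth round-trip through text exports", {
  ev <- generate_paradigm_events(tiny_paradigm(10), seed = 5)
  rp <- generate_rpeaks(max(ev$onset_s) + 1, seed = 6)
  rec <- synthesize_recording(ev, rp, component_model(), scaled_acq(),
                              seed = 7)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_events_tsv(rec, path, session = "pre", condition = "low")
  back <- read_events_tsv(path)
  expect_equal(sum(back$type == "target"), sum(ev$is_target))
  expect_equal(sum(back$type == "rpeak"), nrow(rp))
  expect_equal(nrow(back), nrow(ev) + nrow(rp))
  tpath <- withr::local_tempfile(fileext = ".json")
  write_truth_json(rec, tpath)
  truth <- jsonlite::read_json(tpath, simplifyVector = TRUE)
  expect_equal(nrow(truth$targets), sum(ev$is_target))
})
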