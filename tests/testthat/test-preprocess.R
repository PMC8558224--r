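test_that("down-sampling 2048 -> 512 preserves duration and tone amplitude", {
  fs <- 2048
  t <- (0:(10 * fs - 1)) / fs
  mat <- cbind(sin(2 * pi * 10 * t), cos(2 * pi * 10 * t))
  colnames(mat) <- c("F3", "F4")
  rec <- make_recording(mat, fs)
  out <- resample_recording(rec, 512)
  expect_equal(nrow(out$signals), 5120)
  expect_equal(out$srate, 512)
  # steady-state amplitude within 1 % (skip filter edges)
  mid <- out$signals[500:4600, 1]
  expect_equal(max(abs(mid)), 1, tolerance = 0.01)
  # identity when the target rate equals the native rate
  expect_identical(resample_recording(rec, fs), rec)
  expect_error(resample_recording(rec, -1), "positive")
  expect_error(resample_recording(rec, fs * 2), "exceed")
})

test_that("common average referencing zeroes the channel sum", {
  rec <- make_recording(cbind(F3 = c(1, 3), F4 = c(3, 5)), 10)
  out <- apply_car(rec)
  expect_equal(unname(out$signals[, 1]), c(-1, -1))
  expect_equal(unname(out$signals[, 2]), c(1, 1))

  same <- make_recording(matrix(5, 4, 3), 10)
  expect_true(all(apply_car(same)$signals == 0))

  set.seed(1)
  big <- make_recording(matrix(rnorm(1000 * 64, sd = 20), 1000, 64), 512)
  ref <- apply_car(big)
  expect_lt(max(abs(rowSums(ref$signals))) / 64, 1e-9)
  # idempotence
  expect_equal(apply_car(ref)$signals, ref$signals, tolerance = 1e-12)
  expect_error(apply_car(make_recording(matrix(1, 5, 1), 10)), "2 channels")
})

test_that("epoch rejection is strict at the threshold and monotone", {
  ev <- tibble::tibble(onset_s = c(2, 4, 6), is_target = TRUE)
  mod <- component_model(noise_rms = 1, artifact_rate = 0)
  rec <- synthesize_recording(ev, numeric(), mod, scaled_acq(), seed = 1,
                              duration_s = 8)
  ep <- baseline_correct(extract_epochs(rec))
  # boundary: exactly at threshold is kept, just above is rejected
  ep$data[50, 3, 1] <- 99.9
  ep$data[50, 3, 2] <- 100.1
  out <- reject_epochs(ep, 100)
  expect_true(out$info$kept[1])
  expect_false(out$info$kept[2])
  log <- rejection_log(out)
  expect_equal(log$channel[2], out$channels[3])
  expect_equal(log$peak_uV[2], 100.1, tolerance = 1e-9)
  # boundary equality keeps
  ep2 <- ep
  ep2$data[10, 1, 3] <- 100
  expect_true(reject_epochs(ep2, 100)$info$kept[3])
  # monotone in the threshold
  kept_low <- reject_epochs(ep, 50)$info$kept
  kept_high <- reject_epochs(ep, 150)$info$kept
  expect_true(all(!kept_low | kept_high))
  # infinite threshold keeps everything
  expect_true(all(reject_epochs(ep, Inf)$info$kept))
})

test_that("an empty epoch set passes through rejection", {
  ev <- tibble::tibble(onset_s = numeric(), is_target = logical())
  mod <- component_model(noise_rms = 0, artifact_rate = 0)
  rec <- synthesize_recording(NULL, numeric(), mod, scaled_acq(), seed = 1,
                              duration_s = 3)
  ep <- extract_epochs(rec, events = ev)
  out <- reject_epochs(ep, 100)
  expect_equal(nrow(rejection_log(out)), 0)
})

test_that("features agree whether epoching happens before or after
           down-sampling on noiseless input", {
  mod <- component_model(noise_rms = 0, artifact_rate = 0, hep_amplitude = 0,
                         hep_slow_amplitude = 0, hep_coherent_alpha = 0)
  acq <- acquisition_config(native_rate = 640, analysis_rate = 320,
                            n_channels = 16)
  ev <- tibble::tibble(onset_s = c(2, 5), is_target = TRUE)
  rec <- synthesize_recording(ev, numeric(), mod, acq, seed = 1,
                              duration_s = 7)
  f_native <- p600_features(average_epochs(baseline_correct(
    extract_epochs(rec))))
  f_down <- p600_features(average_epochs(baseline_correct(
    extract_epochs(resample_recording(rec, 320)))))
  expect_equal(f_down$amplitude, f_native$amplitude, tolerance = 0.5)
  # latencies may differ by one sample period of the coarser grid
  expect_true(all(abs(f_down$latency - f_native$latency) <= 1000 / 320 + 1e-9))
})
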