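test_that("epochs span exactly [-200, 800) ms on the sampling grid", {
  mod <- component_model(noise_rms = 1, artifact_rate = 0)
  acq <- acquisition_config(native_rate = 512, analysis_rate = 512,
                            n_channels = 8)
  ev <- tibble::tibble(onset_s = 10, is_target = TRUE)
  rec <- synthesize_recording(ev, numeric(), mod, acq, seed = 1,
                              duration_s = 12)
  ep <- extract_epochs(rec)
  expect_equal(dim(ep$data)[1], 512)
  expect_equal(dim(ep$data)[3], 1)
  # the epoch covers samples from 9.8 s up to (excluding) 10.8 s
  expect_lt(min(ep$times_ms), -199)
  expect_gte(min(ep$times_ms), -200)
  expect_lt(max(ep$times_ms), 800)
})

test_that("events too close to a recording edge are skipped with a warning", {
  mod <- component_model(noise_rms = 1, artifact_rate = 0)
  ev <- tibble::tibble(onset_s = c(0.1, 2), is_target = TRUE)
  rec <- synthesize_recording(ev, numeric(), mod, scaled_acq(), seed = 1,
                              duration_s = 4)
  expect_warning(ep <- extract_epochs(rec), "skipped")
  expect_equal(dim(ep$data)[3], 1)
  expect_equal(ep$info$onset_s, 2)
})

test_that("all sufficiently padded targets yield epochs", {
  ev <- generate_paradigm_events(tiny_paradigm(40), seed = 3)
  rp <- generate_rpeaks(max(ev$onset_s) + 1.2, seed = 4)
  rec <- synthesize_recording(ev, rp, component_model(), scaled_acq(),
                              seed = 5, duration_s = max(ev$onset_s) + 1.2)
  ep <- extract_epochs(rec)
  expect_equal(dim(ep$data)[3], 40)
})

test_that("baseline correction removes the pre-stimulus mean", {
  mod <- component_model(noise_rms = 2, artifact_rate = 0)
  ev <- tibble::tibble(onset_s = c(2, 4), is_target = TRUE)
  rec <- synthesize_recording(ev, numeric(), mod, scaled_acq(), seed = 2,
                              duration_s = 6)
  ep <- extract_epochs(rec)
  # constant offset vanishes entirely
  ep$data[, , 1] <- 7
  out <- baseline_correct(ep)
  expect_true(all(abs(out$data[, , 1]) < 1e-12))
  pre <- out$times_ms < 0
  expect_lt(max(abs(colMeans(out$data[pre, , 2]))), 1e-12)
  # known shift: +2 uV baseline moves the whole epoch by -2
  ep2 <- extract_epochs(rec)
  shifted <- ep2
  shifted$data[, , 2] <- shifted$data[, , 2] + 2
  expect_equal(baseline_correct(shifted)$data[, , 2],
               baseline_correct(ep2)$data[, , 2], tolerance = 1e-12)
  # idempotence
  once <- baseline_correct(ep2)
  expect_equal(baseline_correct(once)$data, once$data, tolerance = 1e-12)
})

test_that("averaging is the pointwise mean and is linear", {
  mod <- component_model(noise_rms = 3, artifact_rate = 0)
  ev <- tibble::tibble(onset_s = c(2, 4, 6), is_target = TRUE)
  rec <- synthesize_recording(ev, numeric(), mod, scaled_acq(), seed = 3,
                              duration_s = 8)
  ep <- baseline_correct(extract_epochs(rec))
  one <- average_epochs(ep, 1)
  expect_equal(one$data, ep$data[, , 1], ignore_attr = TRUE)
  # two epochs that cancel
  ep$data[, , 2] <- -ep$data[, , 1]
  two <- average_epochs(ep, c(1, 2))
  expect_true(all(abs(two$data) < 1e-12))
  # linearity
  scaled <- ep
  scaled$data <- scaled$data * 3
  expect_equal(average_epochs(scaled, c(1, 3))$data,
               3 * average_epochs(ep, c(1, 3))$data, tolerance = 1e-12)
  expect_error(average_epochs(ep, rep(FALSE, 3)), "no epochs")
})

test_that("P600 features follow the closed window and earliest-tie rule", {
  # 1000 Hz grid so the window endpoints are exact sample times
  const <- make_erp(matrix(1, 1000, 8), 1000)
  f <- p600_features(const)
  expect_equal(f$amplitude, rep(1, 8))
  expect_equal(f$latency, rep(530, 8))

  pulse <- make_erp(matrix(0, 1000, 8), 1000)
  idx600 <- which(abs(pulse$times_ms - 600) < 1e-9)
  pulse$data[idx600, ] <- 5
  expect_equal(p600_features(pulse)$latency, rep(600, 8))

  edge <- make_erp(matrix(0, 1000, 8), 1000)
  edge$data[which(abs(edge$times_ms - 750) < 1e-9), ] <- 5
  expect_equal(p600_features(edge)$latency, rep(750, 8))

  short <- make_erp(matrix(1, 300, 8), 1000)
  expect_error(p600_features(short), "window")
})

test_that("feature extraction equals a brute-force window scan on random
           waveforms", {
  set.seed(42)
  for (i in 1:1000) {
    m <- matrix(rnorm(1000 * 2), 1000, 2)
    colnames(m) <- c("P3", "O1")
    erp <- make_erp(m, 1000)
    f <- p600_features(erp)
    win <- which(erp$times_ms >= 530 & erp$times_ms <= 750)
    for (j in 1:2) {
      seg <- m[win, j]
      expect_equal(f$amplitude[j], mean(seg), tolerance = 1e-12)
      expect_identical(f$latency[j], erp$times_ms[win][which.max(seg)])
    }
  }
})
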