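test_that("admission rule is strict on both thresholds", {
  expect_true(admit_intracellular(amplitude = 2, width = 120))
  expect_false(admit_intracellular(amplitude = 0.5, width = 120))
  expect_false(admit_intracellular(amplitude = 1, width = 120)) # boundary
  expect_false(admit_intracellular(amplitude = 2, width = 50))  # boundary
  expect_true(admit_intracellular(amplitude = 0.5, width = 20,
                                  amp_min = 0.2, width_min = 10))
})

test_that("waveform averaging is the pointwise mean with a 3-window rule", {
  w <- ap_window()
  n <- length(w)
  expect_equal(average_waveforms(list(w, w, w), 10000)$samples, w)
  ws <- list(rep(0, n), rep(1, n), rep(2, n))
  expect_equal(unique(average_waveforms(ws, 10000)$samples), 1)
  # fewer than 3 windows: single best window used, flagged
  two <- average_waveforms(list(w, 0.5 * w), 10000)
  expect_false(two$averaged)
  expect_equal(two$n_averaged, 1L)
  expect_error(average_waveforms(list(w, w[-1]), 10000), "equal length")
})

test_that("averaging noisy copies shrinks residual noise by sqrt(3)", {
  w <- ap_window()
  sds <- replicate(30, {
    noisy <- purrr::map(1:3, ~ w + rnorm(length(w), 0, 0.1))
    sd(average_waveforms(noisy, 10000)$samples - w)
  })
  expect_equal(mean(sds), 0.1 / sqrt(3), tolerance = 0.05)
})

test_that("AP features of the linear template match the closed form", {
  w <- ap_window(baseline = 0, amplitude = 2, depol_time = 10, repol_len = 300)
  wf <- average_waveforms(list(w, w, w), 10000)
  f <- ap_features(wf)
  expect_equal(f$AP_amplitude, 2, tolerance = 1e-9)
  expect_equal(f$depolarization_time, 9, tolerance = 0.05)
  expect_equal(f$APD_50, 159, tolerance = 0.05)
  expect_equal(f$APD_90, 279, tolerance = 0.05)
  expect_false(f$truncated)
  expect_lt(f$APD_50, f$APD_90)
})

test_that("time features are invariant to voltage offset and positive scale", {
  w <- ap_window(baseline = 0, amplitude = 2)
  f1 <- ap_features(average_waveforms(list(w, w, w), 10000))
  w2 <- 5 * w - 70
  f2 <- ap_features(average_waveforms(list(w2, w2, w2), 10000))
  expect_equal(f2$APD_50, f1$APD_50, tolerance = 1e-9)
  expect_equal(f2$APD_90, f1$APD_90, tolerance = 1e-9)
  expect_equal(f2$depolarization_time, f1$depolarization_time, tolerance = 1e-9)
  expect_equal(f2$AP_amplitude, 5 * f1$AP_amplitude, tolerance = 1e-9)
})

test_that("unfinished repolarization yields truncated APDs", {
  w <- ap_window(amplitude = 2, depol_time = 10, repol_len = 300, post_ms = 150)
  wf <- average_waveforms(list(w, w, w), 10000)
  f <- ap_features(wf)
  expect_true(is.na(f$APD_90))
  expect_true(f$truncated)
})

test_that("half-amplitude width matches the template crossing distance", {
  w <- ap_window(amplitude = 2, depol_time = 10, repol_len = 300)
  wf <- average_waveforms(list(w, w, w), 10000)
  # crossings at 0.5*depol and depol + 0.5*repol: width = 155 ms
  expect_equal(half_amplitude_width(w, 10000, baseline = 0), 155,
               tolerance = 0.05)
})

test_that("recording-level extraction recovers the generator's analytic truth", {
  g <- gen_ap_recording(ap_spec(baseline = -70, amplitude = 2,
                                depol_time = 10, repol_len = 300))
  ex <- extract_intracellular_features(g$recording)
  expect_equal(ex$features$AP_amplitude, 2, tolerance = 1e-6)
  expect_equal(ex$features$APD_50, g$truth$apd50, tolerance = 0.05)
  expect_equal(ex$features$APD_90, g$truth$apd90, tolerance = 0.05)
  expect_equal(ex$features$depolarization_time, g$truth$depolarization_time,
               tolerance = 0.05)
  expect_equal(ex$features$n_electrodes_admitted, 1)
})

test_that("admission counts on synthetic recordings match expectation exactly", {
  # sub-threshold amplitude: no electrode admitted
  g_small <- gen_ap_recording(ap_spec(amplitude = 0.5))
  ex <- extract_intracellular_features(g_small$recording)
  expect_equal(ex$features$n_electrodes_admitted, 0)
  expect_true(is.na(ex$features$APD_50))
  # narrow spike-like waveform: width fails the 50 ms rule
  g_narrow <- gen_ap_recording(ap_spec(amplitude = 2, depol_time = 5,
                                       repol_len = 40, period = 500))
  ex2 <- extract_intracellular_features(g_narrow$recording)
  expect_equal(ex2$features$n_electrodes_admitted, 0)
})

test_that("noisy templates recover APD90 within the noise-to-slope bound", {
  # first-crossing detection under noise sigma shifts the crossing by about
  # sigma_avg / repolarization slope; here 0.0115 mV / (2/300 mV/ms) ~ 1.7 ms
  set.seed(31)
  errs <- replicate(20, {
    w <- ap_window(amplitude = 2)
    noisy <- purrr::map(1:3, ~ w + rnorm(length(w), 0, 0.02))
    f <- ap_features(average_waveforms(noisy, 10000))
    abs(f$APD_90 - 279)
  })
  expect_lt(median(errs), 3)
})
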