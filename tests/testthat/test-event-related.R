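test_that("EEG preprocessing attenuates the notch frequency by more than 20 dB", {
  fs <- 500
  t <- seq(0, 20, by = 1 / fs)
  s <- timestamped_stream("eeg", "eeg",
                          cbind(a = sin(2 * pi * 50 * t),
                                b = cos(2 * pi * 50 * t)),
                          t, fs, c("a", "b"), "uV", "eeg")
  out <- preprocess_eeg(s, vep_config())
  mid <- seq(length(t) %/% 4, 3 * length(t) %/% 4)
  # amplitude of the 50 Hz component (the 0.01 Hz high-pass leaves slow
  # start-up drift on a record this short, which is not what is measured)
  amp50 <- 2 * abs(mean(out$samples[mid, 1] *
                          exp(-2i * pi * 50 * t[mid])))
  expect_lt(amp50, 0.1)   # > 20 dB down from unit amplitude
})

test_that("common-average re-referencing zeroes the channel mean per sample", {
  fs <- 500
  t <- seq(0, 10, by = 1 / fs)
  x <- cbind(sin(2 * pi * 3 * t) + 1, cos(2 * pi * 5 * t) - 2,
             sin(2 * pi * 7 * t))
  s <- timestamped_stream("eeg", "eeg", x, t, fs, c("a", "b", "c"), "uV")
  out <- preprocess_eeg(s, vep_config())
  expect_equal(max(abs(rowMeans(out$samples))), 0, tolerance = 1e-10)
})

test_that("single-channel input skips re-referencing with a warning", {
  fs <- 500
  t <- seq(0, 10, by = 1 / fs)
  s <- timestamped_stream("eeg", "eeg", matrix(sin(t), ncol = 1), t, fs, "Oz")
  expect_warning(preprocess_eeg(s, vep_config()), "re-referencing skipped")
})

test_that("a long constant signal loses its DC offset through the high-pass edge", {
  fs <- 500
  t <- seq(0, 30, by = 1 / fs)
  s <- timestamped_stream("eeg", "eeg", cbind(rep(4, length(t)),
                                              rep(-4, length(t))),
                          t, fs, c("a", "b"))
  out <- preprocess_eeg(s, vep_config())
  expect_lt(max(abs(out$samples)), 0.5)
})

test_that("epoching equals index-arithmetic brute-force slicing", {
  fs <- 100
  t <- seq(0, 20, by = 1 / fs)
  x <- cbind(seq_along(t), -seq_along(t))
  s <- timestamped_stream("s", "emg", x, t, fs, c("p", "q"))
  locks <- c(5.003, 10.0, 14.998)
  ep <- epoch_stream(s, locks, c(-0.1, 0.2))
  expect_identical(dim(ep$data), c(3L, 31L, 2L))
  for (k in seq_along(locks)) {
    i0 <- which.min(abs(t - locks[k]))
    expect_equal(ep$data[k, , 1], x[(i0 - 10):(i0 + 20), 1])
    expect_equal(ep$data[k, , 2], x[(i0 - 10):(i0 + 20), 2])
  }
  expect_equal(ep$times, (-10:20) / fs)
})

test_that("events at the recording edge are flagged, never dropped", {
  fs <- 100
  t <- seq(0, 5, by = 1 / fs)
  s <- timestamped_stream("s", "emg", matrix(seq_along(t), ncol = 1), t, fs, "p")
  ep <- epoch_stream(s, c(0.05, 2.5), c(-0.5, 0.5))
  expect_identical(dim(ep$data)[1], 2L)
  expect_identical(ep$qc_excluded, c(TRUE, FALSE))
  expect_true(anyNA(ep$data[1, , 1]))
  expect_false(anyNA(ep$data[2, , 1]))
})

test_that("identical trials average with zero-width confidence band", {
  fs <- 100
  t <- seq(0, 60, by = 1 / fs)
  x <- sin(2 * pi * t)
  s <- timestamped_stream("s", "eeg", matrix(x, ncol = 1), t, fs, "a")
  ep <- epoch_stream(s, c(10, 20, 30), c(-0.5, 0.5), baseline = c(-0.5, -0.1))
  ev <- detrend_baseline_average(ep)
  expect_equal(max(ev$ci_high - ev$ci_low), 0, tolerance = 1e-10)
  expect_identical(ev$n_trials, 3L)
})

test_that("the baseline-window mean of every evoked output is zero", {
  set.seed(14)
  fs <- 100
  t <- seq(0, 100, by = 1 / fs)
  s <- timestamped_stream("s", "eeg",
                          matrix(rnorm(length(t)) + 0.3 * t / 100, ncol = 1),
                          t, fs, "a")
  ep <- epoch_stream(s, seq(10, 90, by = 5), c(-0.5, 0.4),
                     baseline = c(-0.5, -0.1))
  for (avg in list(detrend_baseline_average(ep), baseline_average(ep))) {
    bsel <- avg$times >= -0.5 & avg$times <= -0.1
    # every corrected trial and hence the mean has zero baseline mean
    trial_means <- apply(avg$trials[, bsel, 1], 1, mean)
    expect_equal(max(abs(trial_means)), 0, tolerance = 1e-10)
    expect_equal(mean(avg$mean[bsel, 1]), 0, tolerance = 1e-10)
  }
})

test_that("the 95% confidence band has near-nominal coverage", {
  set.seed(99)
  fs <- 50; n_trials <- 40
  t <- seq(0, 400, by = 1 / fs)
  hits <- replicate(400, {
    x <- rnorm(length(t))
    s <- timestamped_stream("s", "eeg", matrix(x, ncol = 1), t, fs, "a")
    locks <- seq(20, 20 + (n_trials - 1) * 9.7, by = 9.7)
    ep <- epoch_stream(s, locks, c(-0.1, 0.1), baseline = c(-0.1, -0.02))
    ev <- detrend_baseline_average(ep)
    i <- which.min(abs(ev$times - 0.08))
    ev$ci_low[i, 1] <= 0 && ev$ci_high[i, 1] >= 0
  })
  expect_gt(mean(hits), 0.90)
  expect_lt(mean(hits), 0.99)
})

test_that("template-only evoked recovers template latencies and amplitudes", {
  b <- small_checkerboard(seed = 17, eeg_noise_rms = 0)
  pk <- vep_pipeline(b)$peaks
  expect_lt(abs(pk$latency[pk$label == "N75"] - 0.065), 2.1 / 500)
  expect_lt(abs(pk$latency[pk$label == "P100"] - 0.090), 2.1 / 500)
  expect_equal(pk$amplitude[pk$label == "N75"], -5.39, tolerance = 0.15)
  expect_equal(pk$amplitude[pk$label == "P100"], 9.15, tolerance = 0.25)
})

test_that("a flat evoked is flagged degenerate", {
  ev <- list(times = seq(-0.5, 0.4, by = 0.002),
             mean = matrix(0, 451, 1), channel_labels = "Oz")
  pk <- find_vep_peaks(ev, vep_config())
  expect_true(all(pk$degenerate))
  expect_equal(pk$amplitude, c(0, 0))
  expect_equal(pk$latency, c(0.05, 0.07))   # window starts
})

test_that("two-script jitter smears the averaged P100 by more than 20%", {
  single <- small_checkerboard(seed = 23)
  double <- small_checkerboard(seed = 23, mode = "two_script")
  a1 <- vep_pipeline(single)$peaks$amplitude[2]
  a2 <- suppressWarnings(vep_pipeline(double))$peaks$amplitude[2]
  expect_lt(a2, 0.8 * a1)
})

test_that("EMG processing follows DC-removal, rectification, moving average", {
  fs <- 1000
  t <- seq(0, 30, by = 1 / fs)
  const <- timestamped_stream("emg", "emg", matrix(5, length(t), 1), t, fs, "ch")
  r <- emg_pipeline(const, 15, emg_config())
  expect_equal(max(abs(r$evoked$mean)), 0)
  # moving average of a unit impulse = 1/100 across 100 samples
  x <- rep(0, length(t)); x[15000] <- 1
  imp <- timestamped_stream("emg", "emg", matrix(x, ncol = 1), t, fs, "ch")
  r2 <- emg_pipeline(imp, 15, emg_config())
  # DC removal shifts the flat part by ~1/n, hence the loose tolerance
  y <- r2$epochs$data[1, , 1]
  expect_equal(max(y), 1 / 100, tolerance = 1e-2)
  expect_identical(sum(y > 1e-3), 100L)
})
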