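test_that("the zero-phase low-pass is identity on DC and symmetric on impulses", {
  expect_equal(lowpass_zero_phase(rep(2.5, 500), fs = 1000), rep(2.5, 500),
               tolerance = 1e-9)
  # impulse response symmetric about the impulse (zero phase)
  x <- rep(0, 1001); x[501] <- 1
  y <- lowpass_zero_phase(x, fs = 1000)
  expect_lt(max(abs(y[501 + 1:200] - y[501 - 1:200])), 1e-9)
})

test_that("sine attenuation matches the squared one-pass Butterworth magnitude", {
  fs <- 1000; f0 <- 50
  t <- seq(0, 4, by = 1 / fs)
  y <- lowpass_zero_phase(sin(2 * pi * f0 * t), fs = fs, cutoff_hz = 5)
  # analytic |H|^2 for an order-2 Butterworth applied forward and backward
  gain2 <- 1 / (1 + (f0 / 5)^4)
  mid <- y[(length(y) %/% 4):(3 * length(y) %/% 4)]
  expect_equal(max(abs(mid)), gain2, tolerance = 0.05)
})

test_that("combined_derivative equals a per-sample brute-force evaluation", {
  expect_equal(combined_derivative(rep(3, 10), rep(-2, 10)), rep(0, 9))
  # AP advancing 1 mm per sample, ML flat -> identically 1
  expect_equal(combined_derivative(1:20, rep(0, 20)), rep(1, 19))
  set.seed(2)
  ap <- cumsum(rnorm(50)); ml <- cumsum(rnorm(50))
  brute <- vapply(seq_len(49), function(i) {
    sqrt((ap[i + 1] - ap[i])^2 + (ml[i + 1] - ml[i])^2)
  }, numeric(1))
  expect_equal(combined_derivative(ap, ml), brute)
  expect_error(combined_derivative(1:5, 1:4), "equal length")
})

test_that("detect_onset applies the crossing/local-minimum rule exactly", {
  cfg <- cop_onset_config()
  # the worked example: crossing at the 7th sample, local minima at the
  # 3rd (0.01) and 5th (0.02) samples, the 5th is nearest -> onset there
  c1 <- c(0.01, 0.02, 0.01, 0.03, 0.02, 0.20, 0.50)
  r <- detect_onset(c1, cfg, fs = 1000)
  expect_identical(r$index, 5L)
  expect_identical(r$crossing_index, 7L)
  expect_identical(r$reason, "ok")

  expect_identical(detect_onset(rep(0.1, 20), cfg, fs = 1000)$reason,
                   "no_crossing")
  # crossing but the only local minimum (0.08) exceeds 0.05
  r3 <- detect_onset(c(0.10, 0.08, 0.10, 0.50), cfg, fs = 1000)
  expect_identical(r3$reason, "no_local_min")
  expect_true(is.na(r3$index))
})

test_that("equidistant local minima resolve to the earlier one", {
  # minima at indices 2 and 6 (values 0.01), crossing at 4
  cc <- c(0.03, 0.01, 0.03, 0.50, 0.03, 0.01, 0.03)
  r <- detect_onset(cc, cop_onset_config(), fs = 1000)
  expect_identical(r$index, 2L)
})

test_that("a plateau counts once, at its first sample", {
  cc <- c(0.04, 0.02, 0.02, 0.02, 0.04, 0.06, 0.50)
  r <- detect_onset(cc, cop_onset_config(), fs = 1000)
  expect_identical(r$index, 2L)
})

test_that("the search radius bounds the minimum search", {
  cfg <- cop_onset_config(search_radius = 0.002)   # 2 samples at 1000 Hz
  cc <- c(0.01, 0.06, 0.06, 0.06, 0.06, 0.50)
  expect_identical(detect_onset(cc, cfg, fs = 1000)$reason, "no_local_min")
})

test_that("qc flags baseline excursions and missing onsets; manual lists override", {
  cfg <- cop_onset_config()
  wavy <- 0.02 + 0.01 * sin(2 * pi * (1:3000) / 400)
  clean <- c(wavy, seq(0.03, 0.6, length.out = 500))
  dirty <- clean; dirty[500:600] <- 0.2   # injected baseline step
  flat <- rep(0.01, 3500)
  trials <- list(clean, dirty, flat)
  dets <- lapply(trials, detect_onset, cfg = cfg, fs = 1000)
  qc <- qc_trials(trials, dets, cfg, fs = 1000)
  expect_identical(qc$flagged, c(FALSE, TRUE, TRUE))
  expect_identical(qc$reason[2:3], c("baseline_excursion", "no_crossing"))
  qc2 <- qc_trials(trials, dets, cfg, fs = 1000,
                   manual_exclude = 1, manual_include = 2)
  expect_identical(qc2$excluded, c(TRUE, FALSE, TRUE))
})

test_that("planted onsets are recovered within 15 ms and precede the crossing", {
  onsets <- 12 + (0:9) * 25
  s <- synth_cop(onsets, seed = 42, t_range = c(0, 260))
  det <- detect_cop_onsets(s, trial_starts = onsets - 12)
  got <- vapply(det$detections, `[[`, numeric(1), "time")
  expect_identical(length(got), 10L)
  expect_true(all(abs(got - onsets) <= 0.015))
  crossings <- vapply(seq_along(det$detections), function(k) {
    d <- det$detections[[k]]
    d$crossing_index - d$index
  }, numeric(1))
  expect_true(all(crossings > 0))   # onset precedes the threshold crossing
  expect_true(all(!det$qc$flagged))
})

test_that("EMG bursts precede the detected kinetic onset in every trial", {
  b <- small_start_to_go(seed = 3)
  e <- emg_overview(b)
  tt <- e$evoked$times
  base <- mean(e$evoked$mean[tt < -2 & tt > -4])
  d <- e$epochs$data[, , 1]
  burst_start <- apply(d, 1, function(y) tt[which(y > 5 * base)[1]])
  expect_true(all(is.finite(burst_start)))
  expect_true(all(burst_start < 0))
})
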