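test_that("identical code sequences pair one-to-one", {
  a <- marker_events(c(1L, 2L, 3L), c(1, 2, 3), "x")
  b <- marker_events(c(1L, 2L, 3L), c(11, 12, 13), "y")
  p <- match_marker_sequences(a, b)
  expect_equal(p[, "a"], 1:3, ignore_attr = TRUE)
  expect_equal(p[, "b"], 1:3, ignore_attr = TRUE)
})

test_that("a missing event leaves the longest common subsequence", {
  a <- marker_events(c(5L, 9L, 5L, 7L), c(1, 2, 3, 4), "x")
  b <- marker_events(c(5L, 5L, 7L), c(11, 13, 14), "y")   # second event lost
  p <- match_marker_sequences(a, b)
  expect_identical(nrow(p), 3L)
  expect_identical(a$code[p[, "a"]], b$code[p[, "b"]])
})

test_that("disjoint code sequences cannot be paired", {
  a <- marker_events(c(1L, 1L), c(1, 2), "x")
  b <- marker_events(c(2L, 2L), c(1, 2), "y")
  expect_error(match_marker_sequences(a, b), "fewer than 2")
})

test_that("offset and drift are recovered exactly from exact affine data", {
  t_true <- seq(0, 300, length.out = 50)
  t_local <- 10 + (1 + 50e-6) * t_true
  m <- fit_clock_mapping(t_true, t_local, "true", "dev")
  expect_equal(m$offset_a, 10, tolerance = 1e-9)
  expect_equal(m$rate_b, 1 + 50e-6, tolerance = 1e-12)
  expect_lt(m$residual_rms, 1e-9)
  expect_identical(m$n_pairs, 50L)
})

test_that("identical clocks fit to the identity mapping", {
  t <- c(0, 10, 20)
  m <- fit_clock_mapping(t, t)
  expect_equal(m$offset_a, 0)
  expect_equal(m$rate_b, 1)
})

test_that("degenerate pairs are rejected", {
  expect_error(fit_clock_mapping(c(5, 5, 5), c(1, 2, 3)), "degenerate")
  expect_error(fit_clock_mapping(1, 2), "at least 2")
})

test_that("timestamp jitter appears as residual rms of matching size", {
  set.seed(21)
  rms <- replicate(20, {
    t_true <- seq(0, 300, length.out = 50)
    t_local <- 3 + (1 + 20e-6) * t_true + rnorm(50, 0, 1e-3)
    fit_clock_mapping(t_true, t_local)$residual_rms
  })
  expect_gt(mean(rms), 0.7e-3)
  expect_lt(mean(rms), 1.3e-3)
})

test_that("offset/drift recovery holds across 100 random clock configurations", {
  set.seed(31)
  for (k in 1:100) {
    off <- runif(1, -100, 100)
    drift <- runif(1, -200, 200)
    t_true <- sort(runif(20, 0, 600))
    m <- fit_clock_mapping(t_true, off + (1 + drift * 1e-6) * t_true)
    expect_equal(m$offset_a, off, tolerance = 1e-6)
    expect_equal((m$rate_b - 1) * 1e6, drift, tolerance = 1e-3)
  }
})

test_that("the affine fit agrees with a brute-force grid search", {
  set.seed(8)
  t_from <- sort(runif(8, 0, 100))
  t_to <- 2.5 + 1.0004 * t_from + rnorm(8, 0, 0.01)
  m <- fit_clock_mapping(t_from, t_to)
  # independent oracle: exhaustive grid around the truth
  offs <- seq(2.3, 2.7, by = 0.0005)
  rates <- seq(0.999, 1.002, by = 0.5e-5)
  sse <- outer(offs, rates, Vectorize(function(a, b) {
    sum((t_to - a - b * t_from)^2)
  }))
  best <- arrayInd(which.min(sse), dim(sse))
  expect_equal(m$offset_a, offs[best[1]], tolerance = 1e-3)
  expect_equal(m$rate_b, rates[best[2]], tolerance = 1e-4)
})

test_that("mappings apply, invert, and round-trip", {
  s <- timestamped_stream("x", "emg", matrix(0, 10, 1),
                          seq(0, by = 0.001, length.out = 10), 1000, "ch",
                          clock_id = "a")
  ident <- fit_clock_mapping(c(0, 1), c(0, 1), "a", "a")
  expect_equal(apply_mapping(s, ident)$timestamps, s$timestamps)
  m <- fit_clock_mapping(c(0, 100), 7 + 1.0001 * c(0, 100), "a", "b")
  rt <- apply_mapping(apply_mapping(s, m), invert_mapping(m))
  expect_equal(rt$timestamps, s$timestamps, tolerance = 1e-12)
  expect_identical(apply_mapping(s, m)$clock_id, "b")
})

test_that("single-script sessions report a constant delay near the projector latency", {
  b <- small_checkerboard(seed = 6)
  r <- jitter_pipeline(b, constant_display_delay = 0)
  expect_false(r$is_jittered)
  expect_equal(r$mean, 0.05, tolerance = 1 / 60)
  expect_lt(r$range, r$jitter_threshold)
})

test_that("two-script sessions are flagged as jittered", {
  b <- small_checkerboard(seed = 6, mode = "two_script")
  r <- jitter_pipeline(b)
  expect_true(r$is_jittered)
  expect_gt(r$range, 1 / 120)
  # net of the projector constant, delays live in the configured envelope
  expect_true(all(r$delays >= 0.012 - 2e-3 & r$delays <= 0.056 + 2e-3))
})

test_that("a zero-delay chain reports zero delays", {
  cmd <- marker_events(c(1L, 1L, 1L), c(1, 2, 3), "k")
  dec <- marker_events(c(1L, 1L, 1L), c(1, 2, 3), "k", "photodiode_decoded")
  r <- delay_report(cmd, dec)
  expect_equal(r$delays, c(0, 0, 0))
  expect_false(r$is_jittered)
})

test_that("locking uses decoded photodiode times, with an audit trail", {
  dec <- marker_events(c(1L, 1L), c(1, 2), "k", "photodiode_decoded")
  lock <- compensate_display_delay(dec)
  expect_equal(lock$time, dec$time)
  expect_match(attr(lock, "audit"), "photodiode-decoded")
  cmd <- marker_events(1L, 1, "k", "command")
  expect_warning(compensate_display_delay(cmd), "NOT compensated")
})

test_that("locking to command times instead shifts the VEP latency by the projector delay", {
  b <- small_checkerboard(seed = 9, eeg_noise_rms = 0)
  cfg <- vep_config()
  res <- vep_pipeline(b, cfg)
  # same epoching but locked to command markers on the EEG clock
  cmd <- b$events[b$events$clock_id == "eeg" & b$events$source == "command", ]
  pre <- suppressWarnings(preprocess_eeg(b$streams$eeg, cfg))
  ep <- epoch_stream(pre, cmd, cfg$epoch_window, baseline = cfg$baseline)
  pk <- find_vep_peaks(detrend_baseline_average(ep), cfg)
  shift <- pk$latency[2] - res$peaks$latency[2]
  expect_lt(abs(shift - b$metadata$chain$projector_delay), 2.1 / 500)
})
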