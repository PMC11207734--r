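test_that("visual_angle matches direct trigonometric evaluation", {
  # 1.4 cm fixation dot at 2.5 m
  expect_equal(round(visual_angle(0.014, 2.5), 2), 0.32)
  expect_identical(visual_angle(0, 2.5), 0)
  # independent evaluation of 2*atan(x/(2d)) for a 6 cm tile
  expect_equal(visual_angle(0.06, 2.5), 2 * atan2(0.03, 2.5) * 180 / pi)
  expect_error(visual_angle(0.01, 0), "positive")
})

test_that("checkerboard schedule has the right count and spacing", {
  ev <- schedule_checkerboard(schedule_config(stimulation_phase = 2))
  expect_identical(nrow(ev), 1L)
  ev <- schedule_checkerboard(schedule_config(reversal_rate = 2,
                                              stimulation_phase = 10))
  expect_identical(nrow(ev), 20L)
  expect_equal(unique(diff(ev$time)), 0.5)
  expect_equal(ev$time[1], 35)
})

test_that("start-to-go schedule is reproducible and respects the wait range", {
  cfg <- schedule_config(n_cycles = 10)
  s1 <- schedule_start_to_go(cfg, seed = 3)
  s2 <- schedule_start_to_go(cfg, seed = 3)
  expect_identical(s1, s2)
  waits <- s1$onsets - s1$cycle_starts - cfg$stand_duration
  expect_true(all(waits >= 5 & waits <= 10))
  # degenerate range -> deterministic onsets
  d <- schedule_start_to_go(schedule_config(n_cycles = 4,
                                            wait_range = c(5, 5)), seed = 9)
  expect_equal(d$onsets, d$cycle_starts + 15 + 5)
})

test_that("wait draws are uniform on the configured range", {
  s <- schedule_start_to_go(schedule_config(n_cycles = 10000), seed = 123)
  waits <- s$onsets - s$cycle_starts - 15
  ks <- suppressWarnings(stats::ks.test(waits, "punif", 5, 10))
  expect_gt(ks$p.value, 0.01)
})

test_that("the display chain quantizes commands up to frame boundaries", {
  chain0 <- display_chain_config(projector_delay = 0)
  # command exactly on a frame boundary keeps its frame
  r <- render_display_chain(c(1, 2 + 1 / 60), chain0, seed = 1)
  expect_equal(r$display_times, c(1, 2 + 1 / 60))
  expect_equal(r$blink_times, r$display_times)
  # off-boundary commands land on the next boundary, plus projector delay
  chain <- display_chain_config(projector_delay = 0.05)
  tcmd <- c(0.001, 0.9, 1.23456)
  r2 <- render_display_chain(tcmd, chain, seed = 1)
  expect_equal(r2$display_times, ceiling(tcmd * 60) / 60 + 0.05)
  expect_error(render_display_chain(c(2, 1), chain), "sorted")
})

test_that("two-script blink delays stay in the envelope and spread beyond a frame", {
  chain <- display_chain_config(mode = "two_script")
  cmd <- seq(10, 248, by = 2)   # 120 events
  r <- render_display_chain(cmd, chain, seed = 42)
  d <- r$blink_times - r$display_times
  expect_true(all(d >= 0.012 - 1 / 60 & d <= 0.056 + 1 / 60))
  expect_gt(max(d) - min(d), 1 / 60)
})

test_that("a single code-255 blink gives one contiguous high segment", {
  cfg <- codec_config()
  ev <- marker_events(255L, 0.5, "kinetics")
  s <- synth_photodiode(ev, cfg, noise_sd = 0, seed = 1)
  hi <- s$samples[, 1] > 0.5
  runs <- rle(hi)
  expect_identical(sum(runs$values), 1L)   # exactly one high run
  # start bit + 8 high data bits = 9 bits of 2 frames each
  expect_equal(runs$lengths[runs$values] / 1000, 9 * 2 / 60, tolerance = 0.01)
})

test_that("zero blink events give pure noise around the low level", {
  s <- synth_photodiode(marker_events(), codec_config(), noise_sd = 0.05,
                        seed = 2, t_range = c(0, 2))
  expect_lt(max(abs(s$samples[, 1])), 0.3)
  expect_equal(mean(s$samples[, 1]), 0, tolerance = 0.01)
})

test_that("noise-free EEG places the response at display time plus delays", {
  tmpl <- vep_template(data.frame(label = "X", latency = 0.1, amplitude = 1,
                                  width = 0.01))
  s <- synth_eeg(5, tmpl, noise_rms = 0, acquisition_delay = 0.01,
                 clock = clock_model("eeg"), seed = 1, t_range = c(0, 10),
                 calibrate = FALSE)
  expect_equal(s$timestamps[which.max(s$samples[, 1])], 5 + 0.01 + 0.1,
               tolerance = 1 / 500)
})

test_that("with zero sway and noise the combined derivative is zero before movement", {
  sway <- cop_sway_params(sway_sd_mm = 0, noise_sd_mm = 0)
  s <- synth_cop(10, sway, seed = 1, t_range = c(0, 20))
  cb <- combined_derivative(s$samples[, "AP"], s$samples[, "ML"])
  tt <- s$timestamps[-1]
  move_start <- 10 - sway$apa_gap_s / 2 - sway$apa_dur_s
  expect_true(all(cb[tt < move_start - 0.01] == 0))
  expect_gt(max(cb[tt > 10]), 0.3)
})

test_that("doubling the step amplitude moves the detected onset < 10 ms", {
  base <- cop_sway_params()
  dbl <- cop_sway_params(step_amp_mm = 2 * base$step_amp_mm)
  t1 <- detect_cop_onsets(synth_cop(15, base, seed = 4, t_range = c(0, 30)),
                          trial_starts = 0)$onsets$time
  t2 <- detect_cop_onsets(synth_cop(15, dbl, seed = 4, t_range = c(0, 30)),
                          trial_starts = 0)$onsets$time
  expect_lt(abs(t1 - t2), 0.010)
})

test_that("noise-free EMG bursts start exactly lead seconds before onset", {
  s <- synth_emg(20, lead = 0.120, baseline_sd = 0, seed = 1,
                 t_range = c(0, 40))
  t_first <- s$timestamps[which(abs(s$samples[, 1]) > 0)[1]]
  expect_equal(t_first, 20 - 0.120, tolerance = 2e-3)
  s0 <- synth_emg(20, lead = 0, baseline_sd = 0, seed = 1, t_range = c(0, 40))
  expect_equal(s0$timestamps[which(abs(s0$samples[, 1]) > 0)[1]], 20,
               tolerance = 2e-3)
})

test_that("the forward mBLL model inverts exactly on noise-free data", {
  geom <- fnirs_geometry()
  fn <- synth_fnirs(c(30, 70), hrf_params(), geom, rho = 0.7,
                    noise_od = 0, seed = 5, t_range = c(0, 110))
  hemo <- intensities_to_hemoglobin(fn$fnirs_760, fn$fnirs_850, geom,
                                    distances_cm = unlist(fn$montage$distances_cm))
  truth <- fn$truth
  for (ch in c("L1", "L2", "S1")) {
    j <- match(ch, hemo$hbo$channel_labels)
    # OD is computed against the mean intensity, so recovery is up to a
    # per-channel constant: compare after centering
    err <- (hemo$hbo$samples[, j] - mean(hemo$hbo$samples[, j])) -
      (truth$hbo[[ch]] - mean(truth$hbo[[ch]]))
    expect_lt(max(abs(err)), 1e-6)
  }
})

test_that("a zero-amplitude response with no systemic signal gives flat intensities", {
  fn <- synth_fnirs(30, hrf_params(amplitude = 0, dip_depth = 0),
                    systemic_amp = c(0, 0, 0), noise_od = 0, seed = 1,
                    t_range = c(0, 60))
  expect_equal(diff(range(fn$fnirs_760$samples)), 0, tolerance = 1e-12)
})

test_that("a montage without a short channel is rejected", {
  geom <- fnirs_geometry()
  geom$short_distance <- 0
  expect_error(synth_fnirs(30, geometry = geom, t_range = c(0, 60)),
               "short channel")
})

test_that("identical (config, seed) produce identical bundles", {
  b1 <- small_checkerboard(seed = 12)
  b2 <- small_checkerboard(seed = 12)
  expect_identical(b1, b2)
  b3 <- small_checkerboard(seed = 13)
  expect_false(identical(b1$streams$eeg$samples, b3$streams$eeg$samples))
})

test_that("session bundles carry the ground truth the analyses need", {
  b <- small_start_to_go(seed = 2)
  gt <- b$metadata$ground_truth
  expect_identical(length(gt$true_onsets), 6L)
  expect_true(all(c("command_times", "display_times", "blink_times",
                    "montage", "emg_lead") %in% names(gt)))
  expect_identical(length(validate_bundle(b)), 0L)
})
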