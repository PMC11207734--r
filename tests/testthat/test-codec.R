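test_that("encode_byte frames match the start/LSB-first/stop convention", {
  cfg <- codec_config()
  # code 0: high only during the start bit
  f0 <- encode_byte(0, 0, cfg)
  expect_identical(nrow(f0), 20L)
  expect_identical(f0$state, rep(c(1L, rep(0L, 9)), each = 2))
  # code 255: start + 8 data bits high, stop low
  f255 <- encode_byte(255, 0, cfg)
  expect_identical(f255$state, rep(c(rep(1L, 9), 0L), each = 2))
  # code 165 = 0b10100101 -> start, 1,0,1,0,0,1,0,1 (LSB first), stop
  f165 <- encode_byte(165, 0, cfg)
  expect_identical(f165$state[seq(1, 20, by = 2)],
                   c(1L, 1L, 0L, 1L, 0L, 0L, 1L, 0L, 1L, 0L))
  expect_equal(diff(f0$frame_time), rep(1 / 60, 19))
  expect_error(encode_byte(256, 0, cfg), "0..255")
  expect_error(encode_byte(-1, 0, cfg), "0..255")
})

test_that("the Schmitt trigger has true hysteresis", {
  # ramp up through both thresholds, dip into the band, ramp down
  x <- c(seq(0, 1, length.out = 50),        # rises: one rising edge
         rep(0.5, 20),                      # inside band: state held high
         seq(1, 0, length.out = 50))        # falls below 0.4: goes low
  s <- timestamped_stream("pd", "photodiode_analog", matrix(x, ncol = 1),
                          seq_along(x) / 1000, 1000, "pd", "V", "kinetics")
  d <- digitize_schmitt(s, codec_config())
  st <- d$samples[, 1]
  edges_up <- sum(diff(st) == 1)
  expect_identical(edges_up, 1L)           # no retrigger inside the band
  expect_true(all(st[51:70] == 1))         # held through the 0.5 V dip
  expect_identical(st[1], 0)
  expect_identical(st[length(st)], 0)
})

test_that("noise below the hysteresis band never triggers; warning on all-low", {
  set.seed(11)
  x <- rnorm(5000, 0, 0.05)
  s <- timestamped_stream("pd", "photodiode_analog", matrix(x, ncol = 1),
                          seq_along(x) / 1000, 1000, "pd", "V", "kinetics")
  expect_warning(d <- digitize_schmitt(s, codec_config()), "all-low")
  expect_true(all(d$samples[, 1] == 0))
})

test_that("raising schmitt_high never increases the number of rising edges", {
  set.seed(7)
  ev <- marker_events(code = c(20L, 200L), time = c(0.5, 1.2),
                      clock_id = "kinetics")
  s <- synth_photodiode(ev, codec_config(), noise_sd = 0.15, seed = 3)
  edges_at <- function(hi) {
    cfg <- codec_config(schmitt_high = hi, schmitt_low = 0.3)
    sum(diff(digitize_schmitt(s, cfg)$samples[, 1]) == 1)
  }
  counts <- vapply(c(0.45, 0.55, 0.65, 0.75, 0.85), edges_at, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("encode->synthesize->digitize->decode is the identity over all 256 codes", {
  cfg <- codec_config()
  byte_dur <- 10 * cfg$bit_frames / cfg$frame_rate
  times <- (seq_len(256) - 1) * (byte_dur + 0.05) + 0.1
  ev <- marker_events(code = 0:255, time = times, clock_id = "kinetics")
  s <- synth_photodiode(ev, cfg, noise_sd = 0, seed = 1)
  dec <- decode_events(digitize_schmitt(s, cfg), cfg)
  expect_identical(dec$code, 0:255)
  expect_identical(dec$source, rep("photodiode_decoded", 256))
  # event time = start-bit rising edge, within one sample of the blink time
  expect_lt(max(abs(dec$time - times)), 1 / 1000 + 1e-12)
})

test_that("round-trip identity holds at one and three frames per bit", {
  for (bf in c(1L, 3L)) {
    cfg <- codec_config(bit_frames = bf)
    byte_dur <- 10 * bf / cfg$frame_rate
    codes <- c(0L, 1L, 85L, 170L, 254L, 255L)
    ev <- marker_events(code = codes,
                        time = (seq_along(codes) - 1) * (byte_dur + 0.05) + 0.1,
                        clock_id = "kinetics")
    s <- synth_photodiode(ev, cfg, noise_sd = 0, seed = 1)
    dec <- decode_events(digitize_schmitt(s, cfg), cfg)
    expect_identical(dec$code, codes)
  }
})

test_that("noisy digitization moves edges by at most one sample", {
  cfg <- codec_config()
  ev <- marker_events(code = 37L, time = 0.3, clock_id = "kinetics")
  clean <- digitize_schmitt(synth_photodiode(ev, cfg, noise_sd = 0, seed = 5),
                            cfg)
  noisy <- digitize_schmitt(synth_photodiode(ev, cfg, noise_sd = 0.1, seed = 5),
                            cfg)
  e1 <- which(diff(clean$samples[, 1]) != 0)
  e2 <- which(diff(noisy$samples[, 1]) != 0)
  expect_identical(length(e1), length(e2))
  expect_lte(max(abs(e1 - e2)), 1L)
})

test_that("framing violations are dropped and logged; empty traces decode to nothing", {
  cfg <- codec_config()
  ev <- marker_events(code = 9L, time = 0.2, clock_id = "kinetics")
  d <- digitize_schmitt(synth_photodiode(ev, cfg, noise_sd = 0, seed = 1), cfg)
  # force the stop bit high: samples in the last bit slot of the byte
  stop_lo <- 0.2 + 9 * (cfg$bit_frames / cfg$frame_rate)
  stop_hi <- 0.2 + 10 * (cfg$bit_frames / cfg$frame_rate)
  bad <- d
  sel <- bad$timestamps >= stop_lo & bad$timestamps < stop_hi
  bad$samples[sel, 1] <- 1
  dec <- decode_events(bad, cfg)
  expect_identical(nrow(dec), 0L)
  expect_match(attr(dec, "decode_log"), "stop-bit", all = FALSE)

  lowt <- timestamped_stream("pd", "photodiode_digital",
                             matrix(0, 500, 1), seq_len(500) / 1000,
                             1000, "pd", "binary", "kinetics")
  expect_identical(nrow(decode_events(lowt, cfg)), 0L)
})

test_that("overlapping byte frames are rejected with the colliding times", {
  cfg <- codec_config()
  ev <- marker_events(code = c(1L, 2L), time = c(0.1, 0.2),
                      clock_id = "kinetics")
  expect_error(synth_photodiode(ev, cfg), "collide")
})
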