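#' Photodiode byte-codec configuration
#'
#' Event codes are transmitted on screen as a blinking dot: one byte per
#' event, framed as 1 start bit (high), 8 data bits LSB-first, and 1 stop
#' bit (low).  Each bit occupies `bit_frames` display frames, so a byte
#' lasts `10 * bit_frames / frame_rate` seconds.  The photodiode voltage is
#' digitized by a Schmitt trigger with hysteresis thresholds
#' (`schmitt_low`, `schmitt_high`).
#'
#' The framing itself (start/stop bits, LSB-first, two frames per bit) is a
#' package convention: start/stop framing makes decoding self-synchronizing
#' and two frames per bit tolerate a dropped frame.  All parameters are
#' configurable so an alternative framing needs no code change.
#'
#' @param frame_rate display frame rate in Hz (default 60).
#' @param bit_frames frames per bit (default 2).
#' @param level_high,level_low analog photodiode levels in volts.
#' @param schmitt_high,schmitt_low Schmitt-trigger thresholds in volts;
#'   `schmitt_low < schmitt_high`.
#' @return list of class `codec_config`.
#' @export
codec_config <- function(frame_rate = 60, bit_frames = 2,
                         level_high = 1.0, level_low = 0.0,
                         schmitt_high = 0.6, schmitt_low = 0.4) {
  stopifnot(schmitt_low < schmitt_high, bit_frames >= 1, frame_rate > 0)
  structure(list(frame_rate = frame_rate, bit_frames = bit_frames,
                 level_high = level_high, level_low = level_low,
                 schmitt_high = schmitt_high, schmitt_low = schmitt_low),
            class = "codec_config")
}

codec_bit_duration <- function(cfg) cfg$bit_frames / cfg$frame_rate
codec_byte_duration <- function(cfg) 10 * codec_bit_duration(cfg)

codec_bits <- function(code) {
  c(1L, as.integer(bitwAnd(bitwShiftR(as.integer(code), 0:7), 1L)), 0L)
}

#' Encode an event byte as per-frame blink states
#'
#' @param code integer 0-255.
#' @param t_start time of the first frame in seconds.
#' @param cfg a [codec_config].
#' @return data frame with `frame_time` and binary `state`, one row per
#'   display frame (`10 * bit_frames` rows).
#' @examples
#' encode_byte(165, 0, codec_config())  # start, LSB-first 1,0,1,0,0,1,0,1, stop
#' @export
encode_byte <- function(code, t_start, cfg = codec_config()) {
  code <- as.integer(code)
  if (is.na(code) || code < 0L || code > 255L) {
    stop("code must be an integer in 0..255", call. = FALSE)
  }
  bits <- codec_bits(code)
  n_frames <- 10L * cfg$bit_frames
  data.frame(
    frame_time = t_start + (seq_len(n_frames) - 1L) / cfg$frame_rate,
    state = rep(bits, each = cfg$bit_frames)
  )
}

#' Schmitt-trigger digitization of an analog photodiode trace
#'
#' Classic comparator with hysteresis: the output goes high once the input
#' exceeds `schmitt_high` and stays high until the input falls below
#' `schmitt_low`; samples inside the hysteresis band never change the
#' state.  Output timestamps equal the input timestamps.
#'
#' @param analog single-channel `photodiode_analog` [timestamped_stream].
#' @param cfg a [codec_config].
#' @return binary `photodiode_digital` [timestamped_stream].
#' @export
digitize_schmitt <- function(analog, cfg = codec_config()) {
  if (ncol(analog$samples) != 1L) {
    stop("digitize_schmitt expects a single-channel stream", call. = FALSE)
  }
  x <- analog$samples[, 1]
  if (length(x) && max(x) < cfg$schmitt_high) {
    warning("signal never exceeds schmitt_high (", cfg$schmitt_high,
            " V); output is all-low", call. = FALSE)
  }
  state <- rep(NA_real_, length(x))
  state[x > cfg$schmitt_high] <- 1
  state[x < cfg$schmitt_low] <- 0
  state <- zoo::na.locf(state, na.rm = FALSE)
  state[is.na(state)] <- 0
  timestamped_stream(
    name = paste0(analog$name, "_digital"),
    modality = "photodiode_digital",
    samples = matrix(state, ncol = 1),
    timestamps = analog$timestamps,
    nominal_rate = analog$nominal_rate,
    channel_labels = "photodiode",
    units = "binary",
    clock_id = analog$clock_id
  )
}

#' Decode byte events from a digital photodiode trace
#'
#' Scans for start bits (a rising edge followed by a high level for at
#' least half a bit duration), samples each of the ten bits at its
#' temporal midpoint, reconstructs the byte LSB-first, and validates the
#' stop bit.  The event time is the timestamp of the start-bit rising edge
#' -- the instant a hardware trigger would latch, which carries the full
#' projection delay and is therefore what downstream analyses lock to.
#'
#' Framing violations (stop bit high) and truncated trailing bytes are
#' dropped and reported in the `decode_log` attribute of the result.
#'
#' @param digital binary [timestamped_stream] from [digitize_schmitt()].
#' @param cfg a [codec_config].
#' @return [marker_events] with `source = "photodiode_decoded"`; attribute
#'   `decode_log` lists dropped candidates.
#' @export
decode_events <- function(digital, cfg = codec_config()) {
  x <- as.numeric(digital$samples[, 1] > 0.5)
  t <- digital$timestamps
  n <- length(x)
  bit_dur <- codec_bit_duration(cfg)
  log <- character()
  codes <- integer()
  times <- numeric()
  edges <- which(diff(c(0, x)) == 1)
  next_allowed <- -Inf
  for (i in edges) {
    if (t[i] < next_allowed) next
    # start-bit plausibility: high for at least half a bit
    half_idx <- which(t >= t[i] & t <= t[i] + 0.5 * bit_dur)
    if (!length(half_idx) || any(x[half_idx] < 0.5)) next
    mids <- t[i] + (0:9 + 0.5) * bit_dur
    if (mids[10] > t[n]) {
      log <- c(log, sprintf("truncated byte at t=%.6f s", t[i]))
      break
    }
    idx <- findInterval(mids, t)
    # nearest sample to each midpoint
    idx <- ifelse(idx < n & (mids - t[idx]) > (t[pmin(idx + 1L, n)] - mids),
                  idx + 1L, idx)
    bits <- x[idx]
    if (bits[1] < 0.5) next
    if (bits[10] > 0.5) {
      log <- c(log, sprintf("stop-bit violation at t=%.6f s", t[i]))
      next_allowed <- t[i] + 10 * bit_dur
      next
    }
    codes <- c(codes, sum(as.integer(bits[2:9] > 0.5) * 2L^(0:7)))
    times <- c(times, t[i])
    next_allowed <- t[i] + 10 * bit_dur
  }
  ev <- marker_events(code = codes, time = times,
                      clock_id = digital$clock_id,
                      source = "photodiode_decoded")
  attr(ev, "decode_log") <- log
  ev
}
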