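# Acquisition simulator: synthetic sessions with ground truth.

#' Visual angle subtended by an extent at a viewing distance
#'
#' @param extent physical extent in meters.
#' @param distance viewing distance in meters; must be positive.
#' @return angle in degrees: `2 * atan(extent / (2 * distance))`.
#' @examples
#' visual_angle(0.014, 2.5)  # 1.4 cm fixation dot at 2.5 m -> 0.32 degrees
#' @export
visual_angle <- function(extent, distance) {
  if (any(distance <= 0)) stop("distance must be positive", call. = FALSE)
  if (any(extent < 0)) stop("extent must be non-negative", call. = FALSE)
  2 * atan(extent / (2 * distance)) * 180 / pi
}

#' Checkerboard reversal schedule
#'
#' Reversal commands at `rest_before + k / reversal_rate`,
#' `k = 0 .. reversal_rate * stimulation_phase - 1`; with defaults this is
#' 120 stimulations over four minutes at 0.5 Hz.
#'
#' @param cfg a [schedule_config].
#' @param code byte code attached to each reversal command.
#' @return [marker_events] on the `"control"` clock, `source = "command"`.
#' @export
schedule_checkerboard <- function(cfg = schedule_config(), code = 1L) {
  n <- round(cfg$reversal_rate * cfg$stimulation_phase)
  marker_events(code = rep(code, n),
                time = cfg$rest_before + (seq_len(n) - 1) / cfg$reversal_rate,
                clock_id = "control", source = "command")
}

#' Start-to-go trial schedule
#'
#' Each cycle: stand for `stand_duration`, wait an additional
#' `U(wait_range)` seconds, then initiate the step; `post_duration` seconds
#' follow before the next cycle starts.
#'
#' @param cfg a [schedule_config].
#' @param seed RNG seed for the wait draws.
#' @return list with `cycle_starts`, `onsets` (true movement-onset times in
#'   seconds), and `cycle_duration`.
#' @export
schedule_start_to_go <- function(cfg = schedule_config(), seed = 1) {
  cycle_dur <- cfg$stand_duration + cfg$wait_range[2] + cfg$post_duration
  starts <- (seq_len(cfg$n_cycles) - 1) * cycle_dur
  waits <- with_seed(seed, stats::runif(cfg$n_cycles, cfg$wait_range[1],
                                        cfg$wait_range[2]))
  list(cycle_starts = starts,
       onsets = starts + cfg$stand_duration + waits,
       cycle_duration = cycle_dur)
}

#' Render stimulation commands through the display chain
#'
#' A command is quantized up to the next frame boundary (a command exactly
#' on a boundary keeps its frame) and delayed by the projector latency to
#' give the true on-screen display time.  In `single_script` mode the
#' photodiode blink shares the stimulus frame, so blink time equals display
#' time.  In `two_script` mode the blink follows the stimulus by a draw
#' from the configured delay envelope.
#'
#' @param command_times numeric vector of command times (s, sorted).
#' @param chain a [display_chain_config].
#' @param seed RNG seed for the two-script delay draws.
#' @return list with `display_times` and `blink_times`.
#' @export
render_display_chain <- function(command_times, chain = display_chain_config(),
                                 seed = 1) {
  if (is.unsorted(command_times)) {
    stop("command times must be sorted", call. = FALSE)
  }
  fr <- chain$frame_rate
  display <- ceiling(command_times * fr - 1e-9) / fr + chain$projector_delay
  blink <- if (chain$mode == "two_script") {
    display + with_seed(seed, stats::runif(length(display),
                                           chain$two_script_delay[1],
                                           chain$two_script_delay[2]))
  } else {
    display
  }
  list(display_times = display, blink_times = blink)
}

#' Synthesize an analog photodiode trace carrying byte blinks
#'
#' Each blink event is encoded as a start/data/stop frame pattern
#' ([encode_byte()]); the analog level is high during high frames and low
#' otherwise, plus Gaussian sensor noise.  Samples are taken on a uniform
#' true-time grid and stamped on the given clock (by convention the
#' kinetics clock, whose analog input records the photodiode).
#'
#' @param blink_events [marker_events] giving blink start times (true time)
#'   and codes.
#' @param codec a [codec_config].
#' @param noise_sd Gaussian noise standard deviation in volts.
#' @param seed RNG seed.
#' @param fs sampling rate in Hz (default 1000).
#' @param clock [clock_model] used to stamp the samples.
#' @param t_range length-2 recording span in true time; defaults to the
#'   events padded by one byte duration.
#' @return `photodiode_analog` [timestamped_stream].
#' @export
synth_photodiode <- function(blink_events, codec = codec_config(),
                             noise_sd = 0.05, seed = 1, fs = 1000,
                             clock = clock_model("kinetics"),
                             t_range = NULL) {
  byte_dur <- codec_byte_duration(codec)
  tt <- blink_events$time
  if (length(tt) >= 2L && any(diff(tt) < byte_dur)) {
    i <- which(diff(tt) < byte_dur)
    stop("blink events collide within one byte duration at t = ",
         paste(sprintf("%.3f", tt[i]), collapse = ", "), call. = FALSE)
  }
  if (is.null(t_range)) {
    t_range <- if (length(tt)) c(min(tt) - byte_dur, max(tt) + 2 * byte_dur)
               else c(0, 1)
  }
  t_true <- seq(t_range[1], t_range[2], by = 1 / fs)
  x <- with_seed(seed, stats::rnorm(length(t_true), codec$level_low, noise_sd))
  frame_dur <- 1 / codec$frame_rate
  t0g <- t_true[1]
  for (k in seq_along(tt)) {
    frames <- encode_byte(blink_events$code[k], tt[k], codec)
    hi <- frames[frames$state == 1L, "frame_time"]
    for (ft in hi) {
      i0 <- 1L + ceiling((ft - t0g) * fs - 1e-9)
      i1 <- 1L + floor((ft + frame_dur - t0g) * fs - 1e-9)
      if ((t0g + (i1 - 1L) / fs) >= ft + frame_dur) i1 <- i1 - 1L
      i0 <- max(i0, 1L); i1 <- min(i1, length(x))
      if (i1 >= i0) {
        x[i0:i1] <- x[i0:i1] + (codec$level_high - codec$level_low)
      }
    }
  }
  timestamped_stream(
    name = "photodiode", modality = "photodiode_analog",
    samples = matrix(x, ncol = 1), timestamps = clock_local(clock, t_true),
    nominal_rate = fs, channel_labels = "photodiode", units = "V",
    clock_id = clock$clock_id
  )
}

# Sum Gaussian template bumps at the given peak times into x (true grid).
add_bumps <- function(x, t_true, peak_times, amplitude, fwhm) {
  sd <- fwhm / (2 * sqrt(2 * log(2)))
  dt <- t_true[2] - t_true[1]
  for (tp in peak_times) {
    i0 <- max(1L, floor((tp - 5 * sd - t_true[1]) / dt))
    i1 <- min(length(x), ceiling((tp + 5 * sd - t_true[1]) / dt))
    if (i1 < i0) next
    idx <- i0:i1
    x[idx] <- x[idx] + amplitude * exp(-((t_true[idx] - tp)^2) / (2 * sd^2))
  }
  x
}

# Adjust the injected component parameters so the band-passed, notched,
# epoched and averaged response reproduces the template's nominal peak
# latencies and amplitudes.  The template describes the response as the
# standard pipeline measures it (reported peak values are always
# post-filter); the injected cortical bumps must therefore be
# pre-compensated for the analysis filters.
calibrate_vep_components <- function(comp, fs, bandpass = c(0.01, 40),
                                     notch = 50, n_iter = 6) {
  inj <- comp
  measure <- function(inj) {
    tt <- seq(0, 6, by = 1 / fs)
    x <- rep(0, length(tt))
    for (j in seq_len(nrow(inj))) {
      x <- add_bumps(x, tt, 3 + inj$latency[j], inj$amplitude[j],
                     inj$width[j])
    }
    y <- bandpass_zero_phase(x, fs, bandpass[1], bandpass[2])
    if (!is.null(notch) && notch < fs / 2) y <- notch_zero_phase(y, fs, notch)
    out <- comp
    for (j in seq_len(nrow(comp))) {
      sel <- which(tt >= 3 + comp$latency[j] - 0.02 &
                   tt <= 3 + comp$latency[j] + 0.02)
      i <- sel[if (comp$amplitude[j] >= 0) which.max(y[sel])
               else which.min(y[sel])]
      # quadratic vertex interpolation around the sampled peak
      if (i > 1L && i < length(y)) {
        d <- (y[i - 1L] - y[i + 1L]) / (2 * (y[i - 1L] - 2 * y[i] + y[i + 1L]))
        out$latency[j] <- tt[i] + d / fs - 3
        out$amplitude[j] <- y[i] - 0.25 * (y[i - 1L] - y[i + 1L]) * d
      } else {
        out$latency[j] <- tt[i] - 3
        out$amplitude[j] <- y[i]
      }
    }
    out
  }
  for (it in seq_len(n_iter)) {
    got <- measure(inj)
    inj$latency <- inj$latency + (comp$latency - got$latency)
    inj$amplitude <- inj$amplitude * (comp$amplitude / got$amplitude)
  }
  inj
}

#' Synthesize an occipital EEG trace with visually evoked responses
#'
#' Background activity is 1/f-shaped noise; each stimulus adds the
#' template's Gaussian components peaking at
#' `display_time + acquisition_delay + component latency`.  The default
#' noise level gives a single-trial peak signal-to-noise ratio of about
#' 0.3 (9.15 uV P100 against 30 uV RMS background), so averaging across
#' trials is required to see the response.
#'
#' The template specifies the response as the standard analysis pipeline
#' reports it.  With `calibrate = TRUE` (default) the injected bumps are
#' pre-compensated for the analysis band-pass and notch
#' ([calibrate_vep_components]), so the noise-free pipeline recovers the
#' template's nominal latencies and amplitudes rather than their filtered
#' attenuations.
#'
#' @param display_times true stimulus display times in seconds.
#' @param template a [vep_template].
#' @param fs sampling rate in Hz (default 500).
#' @param noise_rms background RMS amplitude in uV (default 30).
#' @param acquisition_delay constant acquisition-chain delay in seconds.
#' @param clock [clock_model] for the EEG device.
#' @param seed RNG seed.
#' @param t_range recording span in true time.
#' @param calibrate pre-compensate the injected components for the
#'   analysis filters (see Details).
#' @param analysis_bandpass,analysis_notch the filter settings the
#'   calibration assumes downstream.
#' @return single-channel (`Oz`) `eeg` [timestamped_stream].
#' @export
synth_eeg <- function(display_times, template = vep_template(), fs = 500,
                      noise_rms = 30, acquisition_delay = 0.010,
                      clock = clock_model("eeg"), seed = 1,
                      t_range = NULL, calibrate = TRUE,
                      analysis_bandpass = c(0.01, 40), analysis_notch = 50) {
  if (is.null(t_range)) {
    t_range <- c(min(display_times) - 5, max(display_times) + 5)
  }
  t_true <- seq(t_range[1], t_range[2], by = 1 / fs)
  x <- with_seed(seed, pink_noise(length(t_true), fs, sd = noise_rms))
  comp <- template$components
  if (calibrate) {
    comp <- calibrate_vep_components(comp, fs, analysis_bandpass,
                                     analysis_notch)
  }
  for (j in seq_len(nrow(comp))) {
    x <- add_bumps(x, t_true,
                   display_times + acquisition_delay + comp$latency[j],
                   comp$amplitude[j], comp$width[j])
  }
  timestamped_stream(
    name = "eeg", modality = "eeg", samples = matrix(x, ncol = 1),
    timestamps = clock_local(clock, t_true), nominal_rate = fs,
    channel_labels = "Oz", units = "uV", clock_id = clock$clock_id
  )
}

#' Default parameters of the synthetic center-of-pressure generator
#'
#' Units: the COP position is in millimeters at 1000 Hz, so the combined
#' first-difference statistic used by the onset detector is in mm per
#' sample; the detector's 0.3 / 0.05 thresholds are calibrated to this
#' convention.  Quiet-stance sway is band-limited below `sway_f_max`.
#' Each step is preceded by an anticipatory postural adjustment: the COP
#' shifts backward (and laterally) over `apa_dur_s` seconds, pauses
#' motionless for `apa_gap_s` seconds -- the true onset is the center of
#' that pause -- and then the anteroposterior trace rises sigmoidally by
#' `step_amp_mm` over `rise_s` seconds, returning after the walk-back.
#' The velocity dip between the adjustment and the execution phase is the
#' physical feature the local-minimum onset rule keys on.
#'
#' @param sway_sd_mm quiet-stance sway standard deviation, mm.
#' @param sway_f_max sway band limit, Hz.
#' @param ml_ratio mediolateral-to-anteroposterior sway ratio.
#' @param step_amp_mm step excursion amplitude, mm.
#' @param rise_s sigmoidal rise time of the excursion, s.
#' @param apa_amp_mm,apa_dur_s amplitude (mm) and duration (s) of the
#'   anticipatory shift.
#' @param apa_gap_s duration of the motionless pause separating the end of
#'   the anticipatory shift from the start of the step rise.  The true
#'   onset is the center of this pause; because the pause is wider than
#'   the onset detector's smoothing kernel, the post-filter velocity
#'   minimum stays pinned there regardless of the step amplitude.
#' @param noise_sd_mm white measurement noise on the plates, mm.
#' @param return_after_s,return_dur_s timing of the return excursion, s.
#' @return list of class `cop_sway_params`.
#' @export
cop_sway_params <- function(sway_sd_mm = 2, sway_f_max = 1, ml_ratio = 0.6,
                            step_amp_mm = 150, rise_s = 0.5,
                            apa_amp_mm = 24, apa_dur_s = 0.25,
                            apa_gap_s = 0.08,
                            noise_sd_mm = 0.02,
                            return_after_s = 4, return_dur_s = 2) {
  structure(list(sway_sd_mm = sway_sd_mm, sway_f_max = sway_f_max,
                 ml_ratio = ml_ratio, step_amp_mm = step_amp_mm,
                 rise_s = rise_s, apa_amp_mm = apa_amp_mm,
                 apa_dur_s = apa_dur_s, apa_gap_s = apa_gap_s,
                 noise_sd_mm = noise_sd_mm,
                 return_after_s = return_after_s,
                 return_dur_s = return_dur_s),
            class = "cop_sway_params")
}

#' Synthesize a center-of-pressure trace with planted step onsets
#'
#' @param onset_times true movement-onset times in seconds.
#' @param sway a [cop_sway_params].
#' @param fs sampling rate in Hz (default 1000).
#' @param clock [clock_model] for the kinetics system.
#' @param seed RNG seed.
#' @param t_range recording span in true time.
#' @return two-channel (`AP`, `ML`) `cop` [timestamped_stream] in mm; the
#'   true onsets travel in the stream's `"true_onsets"` attribute.
#' @export
synth_cop <- function(onset_times, sway = cop_sway_params(), fs = 1000,
                      clock = clock_model("kinetics"), seed = 1,
                      t_range = NULL) {
  if (is.null(t_range)) {
    t_range <- c(min(onset_times) - 10, max(onset_times) + 15)
  }
  t_true <- seq(t_range[1], t_range[2], by = 1 / fs)
  n <- length(t_true)
  res <- with_seed(seed, {
    list(ap = lowband_noise(n, fs, sd = sway$sway_sd_mm, f_max = sway$sway_f_max),
         ml = lowband_noise(n, fs, sd = sway$sway_sd_mm * sway$ml_ratio,
                            f_max = sway$sway_f_max),
         nap = stats::rnorm(n, 0, sway$noise_sd_mm),
         nml = stats::rnorm(n, 0, sway$noise_sd_mm))
  })
  step_ap <- rep(0, n)
  step_ml <- rep(0, n)
  # The half-cosine anticipatory shift ends half a pause before the true
  # onset and the step rise begins half a pause after it, so the COP is
  # genuinely motionless in a window centered on the onset.  The pause is
  # wider than the detector's 5 Hz smoothing kernel, which pins the
  # post-filter velocity minimum to the pause center whatever the step
  # amplitude.  The mediolateral components share the same timing.
  ml_coef <- 0.4
  half_gap <- sway$apa_gap_s / 2
  t0g <- t_true[1]
  # postural sway fades out around the stillness pause (cosine edges over
  # `edge` seconds) and resumes afterwards: quiet stance sway is an active
  # balancing process that stops while the stance is frozen for the step
  env <- rep(1, n)
  edge <- 0.15
  floorv <- 0.05
  for (on in onset_times) {
    lo <- on - half_gap - edge
    hi <- on + half_gap + edge
    i0 <- max(1L, 1L + floor((lo - t0g) * fs))
    i1 <- min(n, 1L + ceiling((hi - t0g) * fs))
    idx <- i0:i1
    tl <- t_true[idx]
    w <- pmax((lo + edge - tl) / edge, (tl - hi + edge) / edge, 0)
    w <- pmin(w, 1)
    g <- floorv + (1 - floorv) * (1 - cos(pi * w)) / 2
    env[idx] <- pmin(env[idx], g)
  }
  for (on in onset_times) {
    i0 <- max(1L, 1L + floor((on - half_gap - sway$apa_dur_s - 0.1 - t0g) * fs))
    i1 <- min(n, 1L + ceiling((on + sway$return_after_s + sway$return_dur_s +
                                 0.1 - t0g) * fs))
    idx <- i0:i1
    tl <- t_true[idx]
    u <- pmin(pmax((tl - (on - half_gap - sway$apa_dur_s)) / sway$apa_dur_s,
                   0), 1)
    apa <- (1 - cos(pi * u)) / 2
    rel <- smoothstep((tl - on - sway$return_after_s) / sway$return_dur_s)
    s <- smoothstep((tl - (on + half_gap)) / sway$rise_s) - rel
    step_ap[idx] <- step_ap[idx] - sway$apa_amp_mm * (apa - rel) +
      sway$step_amp_mm * s
    step_ml[idx] <- step_ml[idx] + ml_coef * sway$apa_amp_mm * (apa - rel) +
      ml_coef * sway$step_amp_mm * s
  }
  ap <- res$ap * env + step_ap + res$nap
  ml <- res$ml * env + step_ml + res$nml
  out <- timestamped_stream(
    name = "cop", modality = "cop", samples = cbind(AP = ap, ML = ml),
    timestamps = clock_local(clock, t_true), nominal_rate = fs,
    channel_labels = c("AP", "ML"), units = "mm", clock_id = clock$clock_id
  )
  attr(out, "true_onsets") <- onset_times
  out
}

#' Synthesize a tibialis-anterior EMG trace
#'
#' Baseline sensor noise plus an amplitude-modulated band-limited burst
#' starting `lead` seconds before each movement onset (the muscle activates
#' before the step is visible in the ground reaction forces).
#'
#' @param onset_times true kinetic onset times, seconds.
#' @param lead burst lead relative to the kinetic onset, seconds.
#' @param fs sampling rate in Hz (default 1000).
#' @param burst_amp,baseline_sd burst envelope amplitude and baseline noise
#'   standard deviation, mV.
#' @param burst_dur burst duration in seconds.
#' @param clock [clock_model].
#' @param seed RNG seed.
#' @param t_range recording span in true time.
#' @return single-channel `emg` [timestamped_stream] in mV.
#' @export
synth_emg <- function(onset_times, lead = 0.120, fs = 1000,
                      burst_amp = 0.25, baseline_sd = 0.01, burst_dur = 1.0,
                      clock = clock_model("kinetics"), seed = 1,
                      t_range = NULL) {
  if (is.null(t_range)) {
    t_range <- c(min(onset_times) - 10, max(onset_times) + 15)
  }
  t_true <- seq(t_range[1], t_range[2], by = 1 / fs)
  n <- length(t_true)
  res <- with_seed(seed, {
    list(base = stats::rnorm(n, 0, baseline_sd),
         carrier = band_noise(n, fs, sd = 1, f_min = 30, f_max = 200))
  })
  envl <- rep(0, n)
  t0g <- t_true[1]
  for (on in onset_times) {
    t0 <- on - lead
    i0 <- max(1L, 1L + floor((t0 - 0.05 - t0g) * fs))
    i1 <- min(n, 1L + ceiling((t0 + burst_dur + 0.3 - t0g) * fs))
    idx <- i0:i1
    e <- smoothstep((t_true[idx] - t0) / 0.03) -
      smoothstep((t_true[idx] - t0 - burst_dur) / 0.2)
    envl[idx] <- pmax(envl[idx], e)
  }
  x <- res$base + burst_amp * envl * res$carrier
  timestamped_stream(
    name = "emg", modality = "emg", samples = matrix(x, ncol = 1),
    timestamps = clock_local(clock, t_true), nominal_rate = fs,
    channel_labels = "TA_right", units = "mV", clock_id = clock$clock_id
  )
}

# Composite hemodynamic impulse response evaluated at times t (s), peak
# normalized to 1 at exactly `peak_time` via a small time warp.
hrf_shape <- function(t, hrf = hrf_params()) {
  raw <- function(tt) {
    main <- stats::dgamma(tt, shape = 6, scale = hrf$peak_time / 5)
    main <- main / stats::dgamma(hrf$peak_time, shape = 6,
                                 scale = hrf$peak_time / 5)
    u_peak <- hrf$peak_time + 4
    under <- stats::dgamma(tt, shape = 12, scale = u_peak / 11)
    under <- under / stats::dgamma(u_peak, shape = 12, scale = u_peak / 11)
    dip <- exp(-((tt - hrf$dip_time)^2) / (2 * 0.45^2))
    main - hrf$undershoot_ratio * under -
      (hrf$dip_depth / max(hrf$amplitude, 1e-12)) * dip
  }
  grid <- seq(0, hrf$return_time + 10, by = 0.01)
  v <- raw(grid)
  p <- grid[which.max(v)]
  warped <- raw(pmax(t, 0) * (p / hrf$peak_time)) / max(v)
  warped[t <= 0] <- 0
  warped
}

#' fNIRS molar extinction coefficients and montage geometry
#'
#' Tabulated molar extinction coefficients (1/cm per mol/l) of oxygenated
#' and deoxygenated hemoglobin at 760 and 850 nm (compiled tabulations of
#' Gratzer's spectra, as used by standard fNIRS toolchains), differential
#' pathlength factor, and source-detector distances for long (~3 cm,
#' cortical) and short (~1 cm, scalp) channels.
#'
#' @param wavelengths two wavelengths in nm.
#' @param extinction 2x2 matrix, rows = wavelengths, columns = (HbO2, HbR).
#' @param dpf differential pathlength factor (applies to both wavelengths).
#' @param long_distance,short_distance source-detector separations in cm.
#' @return list of class `fnirs_geometry`.
#' @export
fnirs_geometry <- function(wavelengths = c(760, 850),
                           extinction = matrix(
                             c(1486.5865, 3843.707,
                               2526.391, 1798.643),
                             nrow = 2, byrow = TRUE,
                             dimnames = list(c("760", "850"),
                                             c("HbO2", "HbR"))),
                           dpf = 6.0, long_distance = 3.0,
                           short_distance = 1.0) {
  stopifnot(length(wavelengths) == 2L, nrow(extinction) == 2L,
            abs(det(extinction)) > 0, long_distance > 0, short_distance > 0)
  structure(list(wavelengths = wavelengths, extinction = extinction,
                 dpf = dpf, long_distance = long_distance,
                 short_distance = short_distance),
            class = "fnirs_geometry")
}

#' Synthesize dual-wavelength fNIRS intensity streams
#'
#' Ground-truth concentration changes (the hemodynamic response at each
#' onset; deoxygenated hemoglobin at -1/3 amplitude delayed by 1 s) plus
#' systemic oscillations (Mayer waves at 0.1 Hz, respiration at 0.25 Hz,
#' cardiac at 1 Hz) are forward-modeled to optical intensities with the
#' same modified Beer-Lambert law the analysis inverts.  The systemic
#' component enters the short channel fully and the long channels with
#' weight `rho`.
#'
#' @param onset_times true movement onsets, seconds.
#' @param hrf an [hrf_params].
#' @param geometry an [fnirs_geometry]; a short channel is required, the
#'   correction stage depends on it.
#' @param fs sampling rate in Hz (default 10).
#' @param rho systemic weight in long channels (default 0.7).
#' @param systemic_amp amplitudes (uM) of the 0.1 / 0.25 / 1 Hz systemic
#'   oscillations.
#' @param noise_od optical-density measurement noise standard deviation.
#' @param clock [clock_model].
#' @param seed RNG seed.
#' @param t_range recording span in true time.
#' @return list of two `fnirs_intensity` streams (`fnirs_760`,
#'   `fnirs_850`), each with channels `L1`, `L2` (long) and `S1` (short),
#'   plus `truth` (ground-truth concentration changes) and `montage`.
#' @export
synth_fnirs <- function(onset_times, hrf = hrf_params(),
                        geometry = fnirs_geometry(), fs = 10, rho = 0.7,
                        systemic_amp = c(0.3, 0.2, 0.15), noise_od = 5e-4,
                        clock = clock_model("fnirs"), seed = 1,
                        t_range = NULL) {
  if (is.null(geometry$short_distance) || geometry$short_distance <= 0) {
    stop("montage without a short channel: short-channel correction requires one",
         call. = FALSE)
  }
  if (is.null(t_range)) {
    t_range <- c(min(onset_times) - 20, max(onset_times) + 25)
  }
  t_true <- seq(t_range[1], t_range[2], by = 1 / fs)
  n <- length(t_true)
  hbo_task <- rep(0, n)
  for (on in onset_times) {
    hbo_task <- hbo_task + hrf$amplitude * hrf_shape(t_true - on, hrf)
  }
  hbr_task <- rep(0, n)
  for (on in onset_times) {
    hbr_task <- hbr_task - (hrf$amplitude / 3) * hrf_shape(t_true - on - 1, hrf)
  }
  sysf <- c(0.1, 0.25, 1.0)
  res <- with_seed(seed, {
    ph <- stats::runif(3, 0, 2 * pi)
    list(sys = Reduce(`+`, lapply(1:3, function(i) {
           systemic_amp[i] * sin(2 * pi * sysf[i] * t_true + ph[i])
         })),
         od_noise = matrix(stats::rnorm(n * 6, 0, noise_od), ncol = 6))
  })
  sys <- res$sys
  # chromophore concentration changes per channel, uM
  hbo <- list(L1 = hbo_task + rho * sys, L2 = hbo_task + rho * sys,
              S1 = sys)
  hbr <- list(L1 = hbr_task + 0.25 * rho * sys, L2 = hbr_task + 0.25 * rho * sys,
              S1 = 0.25 * sys)
  dists <- c(L1 = geometry$long_distance, L2 = geometry$long_distance,
             S1 = geometry$short_distance)
  streams <- list()
  for (w in 1:2) {
    inten <- sapply(seq_along(hbo), function(ch) {
      L <- dists[ch] * geometry$dpf
      od <- (geometry$extinction[w, "HbO2"] * hbo[[ch]] +
             geometry$extinction[w, "HbR"] * hbr[[ch]]) * 1e-6 * L
      od <- od + res$od_noise[, (w - 1) * 3 + ch]
      10^(-od)   # I0 = 1; OD is relative to the mean anyway
    })
    colnames(inten) <- names(hbo)
    streams[[w]] <- timestamped_stream(
      name = paste0("fnirs_", geometry$wavelengths[w]),
      modality = "fnirs_intensity", samples = inten,
      timestamps = clock_local(clock, t_true), nominal_rate = fs,
      channel_labels = names(hbo), units = "a.u.",
      clock_id = clock$clock_id
    )
  }
  names(streams) <- paste0("fnirs_", geometry$wavelengths)
  montage <- list(long_channels = c("L1", "L2"), short_channels = "S1",
                  nearest_short = c(L1 = "S1", L2 = "S1"),
                  distances_cm = as.list(dists))
  c(streams,
    list(truth = list(t_true = t_true, hbo = hbo, hbr = hbr, systemic = sys),
         montage = montage))
}

default_session_clocks <- function() {
  list(control = clock_model("control"),
       kinetics = clock_model("kinetics"),
       eeg = clock_model("eeg", offset = 12.3, drift = 40),
       fnirs = clock_model("fnirs", offset = -4.56, drift = -25))
}

#' Simulate a complete acquisition session
#'
#' Composes the task schedule, display chain, photodiode codec, and the
#' per-modality generators into one [stream_bundle] with full ground truth
#' in the metadata (true display times, blink times, movement onsets, and
#' clock parameters).  Identical `(configs, seed)` give identical bundles.
#'
#' Command markers are recorded on the control clock and, as the streaming
#' middleware would distribute them, re-stamped on every acquisition clock;
#' the EEG-side copies carry the constant acquisition-chain delay, which is
#' common to the EEG samples and its trigger path and therefore cancels in
#' event-locked analysis.
#'
#' @param task `"checkerboard"` or `"start_to_go"`.
#' @param seed integer seed; all randomness in the session derives from it.
#' @param schedule a [schedule_config].
#' @param chain a [display_chain_config].
#' @param template a [vep_template] (checkerboard task).
#' @param hrf an [hrf_params] (start-to-go task).
#' @param sway a [cop_sway_params] (start-to-go task).
#' @param codec a [codec_config].
#' @param geometry an [fnirs_geometry] (start-to-go task).
#' @param clocks named list of [clock_model]s for `control`, `kinetics`,
#'   `eeg`, `fnirs`.
#' @param eeg_noise_rms EEG background RMS, uV.
#' @param photodiode_noise_sd photodiode sensor noise, V.
#' @return a [stream_bundle].
#' @examples
#' \donttest{
#' b <- simulate_session("checkerboard", seed = 1,
#'                       schedule = schedule_config(stimulation_phase = 20))
#' b
#' }
#' @export
simulate_session <- function(task = c("checkerboard", "start_to_go"),
                             seed = 1,
                             schedule = schedule_config(),
                             chain = display_chain_config(),
                             template = vep_template(),
                             hrf = hrf_params(),
                             sway = cop_sway_params(),
                             codec = codec_config(),
                             geometry = fnirs_geometry(),
                             clocks = default_session_clocks(),
                             eeg_noise_rms = 30,
                             photodiode_noise_sd = 0.05) {
  task <- match.arg(task)
  seed <- as.integer(seed)
  sub_seed <- function(k) as.integer((as.numeric(seed) * 131 + k) %% 2147483647)
  if (task == "checkerboard") {
    cmd <- schedule_checkerboard(schedule, code = 1L)
    total <- schedule$rest_before + schedule$stimulation_phase +
      schedule$rest_after
    rend <- render_display_chain(cmd$time, chain, seed = sub_seed(1L))
    blink_ev <- marker_events(code = cmd$code, time = rend$blink_times,
                              clock_id = "true", source = "command")
    pd <- synth_photodiode(blink_ev, codec, noise_sd = photodiode_noise_sd,
                           seed = sub_seed(2L), fs = 1000,
                           clock = clocks$kinetics, t_range = c(0, total))
    eeg <- synth_eeg(rend$display_times, template, fs = 500,
                     noise_rms = eeg_noise_rms,
                     acquisition_delay = chain$acquisition_delay_eeg,
                     clock = clocks$eeg, seed = sub_seed(3L),
                     t_range = c(0, total))
    events <- rbind(
      cmd,
      marker_events(cmd$code, clock_local(clocks$kinetics, cmd$time),
                    "kinetics", "command"),
      marker_events(cmd$code,
                    clock_local(clocks$eeg,
                                cmd$time + chain$acquisition_delay_eeg),
                    "eeg", "command")
    )
    class(events) <- c("marker_events", "data.frame")
    truth <- list(task = task, seed = seed,
                  command_times = cmd$time,
                  display_times = rend$display_times,
                  blink_times = rend$blink_times,
                  mode = chain$mode)
    streams <- list(pd, eeg)
  } else {
    sched <- schedule_start_to_go(schedule, seed = sub_seed(1L))
    total <- schedule$n_cycles * sched$cycle_duration
    cmd <- marker_events(code = 2L, time = sched$cycle_starts,
                         clock_id = "control", source = "command")
    rend <- render_display_chain(cmd$time, chain, seed = sub_seed(2L))
    blink_ev <- marker_events(code = cmd$code, time = rend$blink_times,
                              clock_id = "true", source = "command")
    pd <- synth_photodiode(blink_ev, codec, noise_sd = photodiode_noise_sd,
                           seed = sub_seed(3L), fs = 1000,
                           clock = clocks$kinetics, t_range = c(0, total))
    cop <- synth_cop(sched$onsets, sway, fs = 1000, clock = clocks$kinetics,
                     seed = sub_seed(4L), t_range = c(0, total))
    emg <- synth_emg(sched$onsets, lead = schedule$emg_lead, fs = 1000,
                     clock = clocks$kinetics, seed = sub_seed(5L),
                     t_range = c(0, total))
    fn <- synth_fnirs(sched$onsets, hrf, geometry, fs = 10,
                      clock = clocks$fnirs, seed = sub_seed(6L),
                      t_range = c(0, total))
    events <- rbind(
      cmd,
      marker_events(cmd$code, clock_local(clocks$kinetics, cmd$time),
                    "kinetics", "command"),
      marker_events(cmd$code, clock_local(clocks$fnirs, cmd$time),
                    "fnirs", "command")
    )
    class(events) <- c("marker_events", "data.frame")
    truth <- list(task = task, seed = seed,
                  command_times = cmd$time,
                  display_times = rend$display_times,
                  blink_times = rend$blink_times,
                  mode = chain$mode,
                  true_onsets = sched$onsets,
                  emg_lead = schedule$emg_lead,
                  montage = fn$montage)
    streams <- list(pd, cop, emg,
                    fn[[paste0("fnirs_", geometry$wavelengths[1])]],
                    fn[[paste0("fnirs_", geometry$wavelengths[2])]])
  }
  clock_meta <- lapply(clocks, function(cm) {
    list(offset = cm$offset, drift = cm$drift, jitter_sd = cm$jitter_sd)
  })
  stream_bundle(
    streams, events,
    metadata = list(
      task = task, seed = seed,
      clocks = c("control", "true",
                 vapply(clocks, `[[`, character(1), "clock_id")),
      clock_models = clock_meta,
      chain = unclass(chain),
      ground_truth = truth
    )
  )
}
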