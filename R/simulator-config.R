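# Configuration objects for the acquisition simulator.

#' Local clock model
#'
#' Each acquisition device stamps its samples on its own clock, modeled as
#' an affine map of true time plus optional white timestamp jitter:
#' `local = offset + (1 + drift * 1e-6) * true + N(0, jitter_sd)`.
#'
#' @param clock_id clock label.
#' @param offset clock offset in seconds.
#' @param drift clock drift in parts per million; `|drift| < 1000`.
#' @param jitter_sd per-timestamp white jitter standard deviation (s).
#' @return list of class `clock_model`.
#' @export
clock_model <- function(clock_id, offset = 0, drift = 0, jitter_sd = 0) {
  stopifnot(abs(drift) < 1000, jitter_sd >= 0)
  structure(list(clock_id = clock_id, offset = offset, drift = drift,
                 jitter_sd = jitter_sd),
            class = "clock_model")
}

# true time -> local clock reading (deterministic part)
clock_local <- function(cm, t_true) {
  cm$offset + (1 + cm$drift * 1e-6) * t_true
}

# local clock reading -> true time
clock_true <- function(cm, t_local) {
  (t_local - cm$offset) / (1 + cm$drift * 1e-6)
}

#' Display-chain configuration
#'
#' Models the path from a stimulation command to light on the projection
#' screen.  The control script runs at `script_rate` but output is tied to
#' frame generation at `frame_rate`; a command is therefore quantized up to
#' the next frame boundary and then delayed by the fixed `projector_delay`.
#' In the correct `single_script` mode the photodiode blink is drawn by the
#' same script in the same frame as the stimulus, so blink and stimulus
#' appear simultaneously.  In the faulty `two_script` mode the blink is
#' issued by a second, event-chained script and appears a variable
#' `two_script_delay` (default 12-56 ms envelope) after the stimulus.
#'
#' @param script_rate control-script execution rate in Hz (default 300).
#' @param frame_rate display frame rate in Hz (default 60).
#' @param projector_delay fixed projection latency in seconds (default 0.050).
#' @param mode `"single_script"` or `"two_script"`.
#' @param two_script_delay length-2 range (s) of the blink-after-stimulus
#'   delay envelope in two-script mode; default `c(0.012, 0.056)`.
#' @param acquisition_delay_eeg constant delay (s) of the EEG acquisition
#'   chain relative to true time (default 0.010).
#' @return list of class `display_chain_config`.
#' @export
display_chain_config <- function(script_rate = 300, frame_rate = 60,
                                 projector_delay = 0.050,
                                 mode = c("single_script", "two_script"),
                                 two_script_delay = c(0.012, 0.056),
                                 acquisition_delay_eeg = 0.010) {
  mode <- match.arg(mode)
  stopifnot(script_rate >= frame_rate, frame_rate > 0,
            length(two_script_delay) == 2L, all(two_script_delay >= 0),
            diff(two_script_delay) >= 0)
  structure(list(script_rate = script_rate, frame_rate = frame_rate,
                 projector_delay = projector_delay, mode = mode,
                 two_script_delay = two_script_delay,
                 acquisition_delay_eeg = acquisition_delay_eeg),
            class = "display_chain_config")
}

#' Visually evoked potential template
#'
#' Each component is a Gaussian bump described by its peak latency relative
#' to the stimulus marker, its peak amplitude, and its full width at half
#' maximum.  Defaults reproduce a typical occipital pattern-reversal
#' response: N75 at 65 ms / -5.39 uV and P100 at 90 ms / 9.15 uV.  FWHM
#' widths of 10 and 12 ms keep the two lobes fully separate.
#'
#' @param components data frame with columns `latency` (s), `amplitude`
#'   (uV), `width` (s, FWHM).
#' @return list of class `vep_template`.
#' @export
vep_template <- function(components = data.frame(
                           label = c("N75", "P100"),
                           latency = c(0.065, 0.090),
                           amplitude = c(-5.39, 9.15),
                           width = c(0.010, 0.012))) {
  stopifnot(all(components$width > 0))
  structure(list(components = components), class = "vep_template")
}

#' Canonical hemodynamic response parameters
#'
#' The response is an initial dip in oxygenated hemoglobin within 1-2 s of
#' movement onset, a positive lobe peaking near `peak_time`, a late
#' undershoot, and a return to baseline by `return_time`.  The composite
#' shape is built from gamma-density lobes plus a Gaussian dip and is
#' time-warped so its numerical maximum falls exactly at `peak_time` with
#' value `amplitude`.
#'
#' @param peak_time peak latency in seconds (default 7).
#' @param amplitude peak amplitude of the oxygenated-hemoglobin change, uM.
#' @param dip_time,dip_depth latency (s) and depth (uM, positive number)
#'   of the initial dip.
#' @param undershoot_ratio late-undershoot lobe amplitude as a fraction of
#'   the main lobe.
#' @param return_time nominal return-to-baseline time in seconds.
#' @return list of class `hrf_params`.
#' @export
hrf_params <- function(peak_time = 7, amplitude = 0.6,
                       dip_time = 1.4, dip_depth = 0.10,
                       undershoot_ratio = 0.25, return_time = 17) {
  stopifnot(0 < dip_time, dip_time < peak_time, peak_time < return_time)
  structure(list(peak_time = peak_time, amplitude = amplitude,
                 dip_time = dip_time, dip_depth = dip_depth,
                 undershoot_ratio = undershoot_ratio,
                 return_time = return_time),
            class = "hrf_params")
}

#' Task schedule configuration
#'
#' Timing of the two simulated tasks.  The checkerboard task alternates
#' tile colors at `reversal_rate` during a `stimulation_phase`-second
#' stimulation block flanked by rest periods (defaults: 120 reversals over
#' four minutes at 0.5 Hz, 35 s rest before and after).  The start-to-go
#' task repeats `n_cycles` walking cycles: stand for `stand_duration`, wait
#' a uniformly distributed additional `wait_range` seconds, then step off;
#' `post_duration` leaves room for the hemodynamic response and the walk
#' back before the next cycle.
#'
#' @param reversal_rate checkerboard reversal rate in Hz.
#' @param stimulation_phase stimulation block duration in seconds.
#' @param rest_before,rest_after rest durations in seconds.
#' @param n_cycles number of walking cycles.
#' @param stand_duration standing time before the beep, seconds.
#' @param wait_range length-2 range (s) of the self-paced wait after the beep.
#' @param post_duration time (s) allotted after each movement onset.
#' @param emg_lead seconds by which the EMG burst precedes the kinetic onset.
#' @return list of class `schedule_config`.
#' @export
schedule_config <- function(reversal_rate = 0.5, stimulation_phase = 240,
                            rest_before = 35, rest_after = 35,
                            n_cycles = 50, stand_duration = 15,
                            wait_range = c(5, 10), post_duration = 20,
                            emg_lead = 0.120) {
  stopifnot(reversal_rate > 0, stimulation_phase > 0, rest_before > 0,
            rest_after > 0, n_cycles >= 1, stand_duration > 0,
            length(wait_range) == 2L, diff(wait_range) >= 0,
            post_duration > 0, emg_lead >= 0)
  structure(list(reversal_rate = reversal_rate,
                 stimulation_phase = stimulation_phase,
                 rest_before = rest_before, rest_after = rest_after,
                 n_cycles = n_cycles, stand_duration = stand_duration,
                 wait_range = wait_range, post_duration = post_duration,
                 emg_lead = emg_lead),
            class = "schedule_config")
}
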