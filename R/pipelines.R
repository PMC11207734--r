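# Bundle-level pipelines composing the codec, alignment, onset and
# event-related modules.

#' Decode photodiode events from a bundle
#'
#' Digitizes the analog photodiode stream with the Schmitt trigger and
#' decodes the byte events.
#'
#' @param bundle a [stream_bundle] containing a `photodiode_analog` stream.
#' @param codec a [codec_config].
#' @param stream_name name of the photodiode stream (default: the first
#'   `photodiode_analog` stream).
#' @return [marker_events] with `source = "photodiode_decoded"` on the
#'   photodiode stream's clock.
#' @export
decode_bundle_events <- function(bundle, codec = codec_config(),
                                 stream_name = NULL) {
  if (is.null(stream_name)) {
    mods <- vapply(bundle$streams, `[[`, character(1), "modality")
    i <- which(mods == "photodiode_analog")[1]
    if (is.na(i)) stop("bundle has no photodiode_analog stream", call. = FALSE)
    stream_name <- names(bundle$streams)[i]
  }
  decode_events(digitize_schmitt(bundle$streams[[stream_name]], codec), codec)
}

#' Stimulus-locked VEP pipeline on a session bundle
#'
#' Decodes the photodiode events (projection-true stimulus times), maps
#' them onto the EEG clock via the command markers shared between the
#' kinetics and EEG recordings, locks epochs to the decoded times
#' ([compensate_display_delay()]), preprocesses the EEG, averages, and
#' measures the N75/P100 peaks.
#'
#' @param bundle a checkerboard-session [stream_bundle].
#' @param cfg a [vep_config].
#' @param codec a [codec_config].
#' @param eeg_stream,ref_clock,eeg_clock stream/clock names.
#' @return list with `peaks` (from [find_vep_peaks()]), `evoked`,
#'   `epochs`, and the locking `events` on the EEG clock.
#' @export
vep_pipeline <- function(bundle, cfg = vep_config(), codec = codec_config(),
                         eeg_stream = "eeg", ref_clock = "kinetics",
                         eeg_clock = NULL) {
  eeg <- bundle$streams[[eeg_stream]]
  eeg_clock <- eeg_clock %||% eeg$clock_id
  decoded <- decode_bundle_events(bundle, codec)
  mapping <- clock_mapping_between(bundle, ref_clock, eeg_clock)
  lock <- compensate_display_delay(apply_mapping(decoded, mapping))
  pre <- suppressWarnings(preprocess_eeg(eeg, cfg))
  epochs <- epoch_stream(pre, lock, cfg$epoch_window, baseline = cfg$baseline)
  evoked <- detrend_baseline_average(epochs)
  peaks <- find_vep_peaks(evoked, cfg)
  list(peaks = peaks, evoked = evoked, epochs = epochs, events = lock,
       mapping = mapping)
}

#' Display-chain jitter diagnosis on a session bundle
#'
#' Decodes the photodiode events and compares them with the command
#' markers on the same (kinetics) clock.  The known constant projector
#' delay is subtracted so the report isolates the variable part of the
#' stimulus-to-blink delay; a faulty two-script display chain shows up as
#' a delay range larger than half a frame period.
#'
#' @param bundle a [stream_bundle].
#' @param codec a [codec_config].
#' @param ref_clock clock carrying both command markers and the photodiode.
#' @param constant_display_delay constant latency (s) to subtract;
#'   defaults to the projector delay recorded in the bundle metadata, else 0.
#' @param frame_rate display frame rate (Hz) for the jitter threshold;
#'   defaults to the bundle metadata, else 60.
#' @return a [delay_report()].
#' @export
jitter_pipeline <- function(bundle, codec = codec_config(),
                            ref_clock = "kinetics",
                            constant_display_delay = NULL,
                            frame_rate = NULL) {
  decoded <- decode_bundle_events(bundle, codec)
  cmd <- bundle$events[bundle$events$clock_id == ref_clock &
                       bundle$events$source == "command", , drop = FALSE]
  if (!nrow(cmd)) stop("no command markers on clock '", ref_clock, "'",
                       call. = FALSE)
  constant_display_delay <- constant_display_delay %||%
    (bundle$metadata$chain$projector_delay %||% 0)
  frame_rate <- frame_rate %||% (bundle$metadata$chain$frame_rate %||% 60)
  delay_report(cmd, decoded, frame_rate = frame_rate,
               constant_display_delay = constant_display_delay)
}

#' Kinetic movement-onset pipeline on a session bundle
#'
#' Runs [detect_cop_onsets()] on the bundle's COP stream with trial
#' windows starting at the command markers (cycle starts) on the kinetics
#' clock.
#'
#' @param bundle a start-to-go [stream_bundle].
#' @param cfg a [cop_onset_config].
#' @param cop_stream stream name (default `"cop"`).
#' @param ref_clock kinetics clock label.
#' @return as [detect_cop_onsets()].
#' @export
onset_pipeline <- function(bundle, cfg = cop_onset_config(),
                           cop_stream = "cop", ref_clock = "kinetics") {
  cmd <- bundle$events[bundle$events$clock_id == ref_clock &
                       bundle$events$source == "command", , drop = FALSE]
  if (!nrow(cmd)) stop("no command markers on clock '", ref_clock, "'",
                       call. = FALSE)
  detect_cop_onsets(bundle$streams[[cop_stream]], cmd$time, cfg)
}

#' Onset-locked hemodynamic pipeline on a session bundle
#'
#' Detects the kinetic movement onsets from the COP stream, maps them onto
#' the fNIRS clock via shared command markers, converts the
#' dual-wavelength intensities to hemoglobin concentration changes
#' (modified Beer-Lambert law), band-passes, regresses the short channel
#' out of every long channel, epochs around the onsets, baseline-corrects
#' and averages, and measures the response shape.
#'
#' @param bundle a start-to-go [stream_bundle].
#' @param cfg a [hemo_config].
#' @param onset_cfg a [cop_onset_config].
#' @param ref_clock,fnirs_clock clock labels.
#' @return list with `metrics` ([hemo_response_metrics()] of the
#'   long-channel-average HbO2 response), `evoked` (per-channel averages),
#'   `evoked_mean` (long-channel average trace), `times`, `onsets`, and
#'   `hemo` (the corrected continuous streams).
#' @export
hemo_pipeline <- function(bundle, cfg = hemo_config(),
                          onset_cfg = cop_onset_config(),
                          ref_clock = "kinetics", fnirs_clock = "fnirs") {
  geometry <- cfg$geometry
  det <- onset_pipeline(bundle, onset_cfg, ref_clock = ref_clock)
  mapping <- clock_mapping_between(bundle, ref_clock, fnirs_clock)
  onsets <- apply_mapping(det$onsets, mapping)

  wl_names <- paste0("fnirs_", geometry$wavelengths)
  montage <- bundle$metadata$ground_truth$montage %||%
    list(long_channels = bundle$streams[[wl_names[1]]]$channel_labels,
         short_channels = character(), nearest_short = NULL,
         distances_cm = NULL)
  dists <- montage$distances_cm
  if (!is.null(dists)) dists <- unlist(dists)
  hemo <- intensities_to_hemoglobin(bundle$streams[[wl_names[1]]],
                                    bundle$streams[[wl_names[2]]],
                                    geometry, distances_cm = dists)
  fs <- hemo$hbo$nominal_rate
  filt <- function(s) {
    s$samples <- apply(s$samples, 2, bandpass_zero_phase, fs = fs,
                       low = cfg$bandpass[1], high = cfg$bandpass[2])
    s
  }
  hbo <- filt(hemo$hbo); hbr <- filt(hemo$hbr)

  long <- montage$long_channels
  short <- montage$short_channels
  corrected <- hbo
  if (length(short)) {
    colnames(hbo$samples) <- hbo$channel_labels
    colnames(hbr$samples) <- hbr$channel_labels
    hbo_long <- short_channel_correct(hbo$samples[, long, drop = FALSE],
                                      hbo$samples[, short, drop = FALSE],
                                      montage$nearest_short)
    hbr_long <- short_channel_correct(hbr$samples[, long, drop = FALSE],
                                      hbr$samples[, short, drop = FALSE],
                                      montage$nearest_short)
  } else {
    colnames(hbo$samples) <- hbo$channel_labels
    colnames(hbr$samples) <- hbr$channel_labels
    hbo_long <- hbo$samples[, long, drop = FALSE]
    hbr_long <- hbr$samples[, long, drop = FALSE]
  }
  corrected$samples <- hbo_long
  corrected$channel_labels <- long
  corrected$units <- rep("uM", length(long))

  epochs <- epoch_stream(corrected, onsets, cfg$epoch_window,
                         baseline = cfg$baseline)
  evoked <- baseline_average(epochs)
  evoked_mean <- rowMeans(evoked$mean)
  metrics <- hemo_response_metrics(evoked$times, evoked_mean)
  list(metrics = metrics, evoked = evoked, evoked_mean = evoked_mean,
       times = evoked$times, onsets = onsets, detections = det,
       hemo = list(hbo = hbo, hbr = hbr, hbo_corrected_long = hbo_long,
                   hbr_corrected_long = hbr_long))
}

#' Baseline-correct and average epochs without detrending
#'
#' Like [detrend_baseline_average()] but subtracting only the
#' baseline-window mean of each trial (the hemodynamic convention: the
#' mean change over the pre-onset window defines zero).
#'
#' @param epochs an [epoch_set].
#' @param baseline optional baseline window override.
#' @return same structure as [detrend_baseline_average()].
#' @export
baseline_average <- function(epochs, baseline = NULL) {
  bl <- baseline %||% epochs$baseline_window
  tt <- epochs$times
  bsel <- tt >= bl[1] & tt <= bl[2]
  if (!any(bsel)) stop("baseline window outside epoch times", call. = FALSE)
  d <- epochs$data
  for (k in seq_len(dim(d)[1])) {
    for (ch in seq_len(dim(d)[3])) {
      d[k, , ch] <- d[k, , ch] - mean(d[k, bsel, ch], na.rm = TRUE)
    }
  }
  keep <- which(!epochs$qc_excluded)
  if (!length(keep)) stop("all trials excluded", call. = FALSE)
  m <- apply(d[keep, , , drop = FALSE], c(2, 3), mean)
  sem <- apply(d[keep, , , drop = FALSE], c(2, 3), stats::sd) /
    sqrt(length(keep))
  sem[is.na(sem)] <- 0
  list(times = tt, mean = m, ci_low = m - 1.96 * sem,
       ci_high = m + 1.96 * sem, n_trials = length(keep),
       channel_labels = epochs$channel_labels, baseline_window = bl,
       trials = d)
}

#' Onset-locked EMG pipeline on a session bundle
#'
#' @param bundle a start-to-go [stream_bundle].
#' @param cfg an [emg_config].
#' @param onset_cfg a [cop_onset_config].
#' @param emg_stream stream name.
#' @return list with the [emg_pipeline()] result plus the detected
#'   `onsets`.
#' @export
emg_overview <- function(bundle, cfg = emg_config(),
                         onset_cfg = cop_onset_config(),
                         emg_stream = "emg") {
  det <- onset_pipeline(bundle, onset_cfg)
  res <- emg_pipeline(bundle$streams[[emg_stream]], det$onsets, cfg)
  c(res, list(onsets = det$onsets, detections = det))
}
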