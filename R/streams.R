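#' Timestamped multimodal data streams
#'
#' A `timestamped_stream` holds one modality's samples together with
#' per-sample timestamps expressed on a named local clock.  Streams from
#' different acquisition devices (force plate, EMG amplifier, EEG amplifier,
#' fNIRS optodes, photodiode channel) live on independent clocks; the
#' alignment module maps them onto a common timeline.
#'
#' @param name unique stream name within a bundle.
#' @param modality one of `"eeg"`, `"emg"`, `"cop"`, `"fnirs_intensity"`,
#'   `"fnirs_hemo"`, `"photodiode_analog"`, `"photodiode_digital"`.
#' @param samples numeric matrix, `n_samples x n_channels` (a vector is
#'   treated as a single channel).
#' @param timestamps numeric vector of sample times in seconds on the
#'   stream's local clock; must be strictly increasing.
#' @param nominal_rate nominal sampling rate in Hz.
#' @param channel_labels character vector, one label per channel.
#' @param units character vector of per-channel unit strings (recycled if
#'   length one).
#' @param clock_id label of the local clock the timestamps live on.
#' @return An object of class `timestamped_stream`.
#' @examples
#' s <- timestamped_stream("cop", "cop", cbind(AP = 0:9, ML = 0), seq(0, 0.009, by = 0.001),
#'                         1000, c("AP", "ML"), "mm", "kinetics")
#' s
#' @export
timestamped_stream <- function(name, modality, samples, timestamps,
                               nominal_rate, channel_labels,
                               units = "a.u.", clock_id = "default") {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (length(units) == 1L) units <- rep(units, ncol(samples))
  structure(
    list(
      name = as.character(name),
      modality = as.character(modality),
      channel_labels = as.character(channel_labels),
      units = as.character(units),
      nominal_rate = as.numeric(nominal_rate),
      samples = samples,
      timestamps = as.numeric(timestamps),
      clock_id = as.character(clock_id)
    ),
    class = "timestamped_stream"
  )
}

STREAM_MODALITIES <- c("eeg", "emg", "cop", "fnirs_intensity", "fnirs_hemo",
                       "photodiode_analog", "photodiode_digital")
EVENT_SOURCES <- c("command", "photodiode_decoded", "derived_onset")

#' @export
print.timestamped_stream <- function(x, ...) {
  cat(sprintf("<timestamped_stream> %s [%s] on clock '%s'\n",
              x$name, x$modality, x$clock_id))
  cat(sprintf("  %d samples x %d channel(s) (%s) @ %g Hz nominal\n",
              nrow(x$samples), ncol(x$samples),
              paste(x$channel_labels, collapse = ", "), x$nominal_rate))
  if (length(x$timestamps)) {
    cat(sprintf("  time span %.3f .. %.3f s\n",
                x$timestamps[1], x$timestamps[length(x$timestamps)]))
  }
  invisible(x)
}

#' Marker events
#'
#' Events are kept as a data frame with one row per event: a byte code
#' (0-255), a time in seconds on a named clock, and the provenance of the
#' event (`"command"` = issued by the control software,
#' `"photodiode_decoded"` = decoded from the projected blink pattern,
#' `"derived_onset"` = computed movement onset).
#'
#' @param code integer vector of byte codes (0-255).
#' @param time numeric vector of event times in seconds.
#' @param clock_id clock label(s).
#' @param source provenance label(s).
#' @return data frame of class `marker_events`.
#' @export
marker_events <- function(code = integer(), time = numeric(),
                          clock_id = character(), source = "command") {
  n <- max(length(code), length(time))
  df <- data.frame(
    code = as.integer(rep_len(code, n)),
    time = as.numeric(rep_len(time, n)),
    clock_id = as.character(rep_len(clock_id, n)),
    source = as.character(rep_len(source, n)),
    stringsAsFactors = FALSE
  )
  if (n == 0L) {
    df <- data.frame(code = integer(), time = numeric(),
                     clock_id = character(), source = character(),
                     stringsAsFactors = FALSE)
  }
  class(df) <- c("marker_events", "data.frame")
  df
}

#' Session bundle of streams and events
#'
#' Container for one recording session: a list of [timestamped_stream]
#' objects, a [marker_events] table, and free-form metadata (session id,
#' simulator seed and configuration, ground truth for synthetic sessions).
#'
#' @param streams list of [timestamped_stream] objects with unique names.
#' @param events [marker_events] data frame.
#' @param metadata named list.
#' @return object of class `stream_bundle`.
#' @export
stream_bundle <- function(streams = list(), events = marker_events(),
                          metadata = list()) {
  names(streams) <- vapply(streams, function(s) s$name, character(1))
  structure(list(streams = streams, events = events, metadata = metadata),
            class = "stream_bundle")
}

#' @export
print.stream_bundle <- function(x, ...) {
  cat(sprintf("<stream_bundle> %d stream(s), %d event(s)\n",
              length(x$streams), nrow(x$events)))
  for (s in x$streams) {
    cat(sprintf("  - %-18s %-18s %8d x %d @ %6g Hz  clock=%s\n",
                s$name, paste0("[", s$modality, "]"), nrow(s$samples),
                ncol(s$samples), s$nominal_rate, s$clock_id))
  }
  if (length(x$metadata)) {
    cat("  metadata:", paste(names(x$metadata), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Event-locked epochs
#'
#' Trials x time x channels array cut around locking events, with the
#' relative time axis, the baseline window used for correction, the
#' per-trial event codes, and an advisory per-trial exclusion flag.
#' Excluded trials stay stored; exclusion is a flag, never deletion.
#'
#' @param data numeric array `n_trials x n_times x n_channels`.
#' @param times numeric vector of times relative to the locking event (s).
#' @param channel_labels character vector of channel names.
#' @param baseline_window length-2 numeric `(start, end)` in seconds.
#' @param event_codes integer vector, one code per trial.
#' @param qc_excluded logical vector, one flag per trial.
#' @return object of class `epoch_set`.
#' @export
epoch_set <- function(data, times, channel_labels, baseline_window,
                      event_codes = rep(NA_integer_, dim(data)[1]),
                      qc_excluded = rep(FALSE, dim(data)[1])) {
  structure(
    list(data = data, times = as.numeric(times),
         channel_labels = as.character(channel_labels),
         baseline_window = as.numeric(baseline_window),
         event_codes = as.integer(event_codes),
         qc_excluded = as.logical(qc_excluded)),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trial(s) x %d time(s) x %d channel(s)\n",
              d[1], d[2], d[3]))
  cat(sprintf("  window %.3f .. %.3f s, baseline %.3f .. %.3f s, %d excluded\n",
              x$times[1], x$times[length(x$times)],
              x$baseline_window[1], x$baseline_window[2],
              sum(x$qc_excluded)))
  invisible(x)
}

# ---- validation ------------------------------------------------------------

validate_stream <- function(s) {
  v <- character()
  say <- function(fmt, ...) sprintf("stream '%s': %s", s$name %||% "?",
                                    sprintf(fmt, ...))
  if (!is.character(s$modality) || length(s$modality) != 1L ||
      !(s$modality %in% STREAM_MODALITIES)) {
    v <- c(v, say("modality '%s' not one of {%s}",
                  paste(s$modality, collapse = ","),
                  paste(STREAM_MODALITIES, collapse = ", ")))
  }
  n <- tryCatch(nrow(s$samples), error = function(e) NA_integer_)
  nc <- tryCatch(ncol(s$samples), error = function(e) NA_integer_)
  if (is.na(n) || is.na(nc)) {
    v <- c(v, say("samples is not a matrix"))
    return(v)
  }
  if (length(s$timestamps) != n) {
    v <- c(v, say("length(timestamps) == %d but n_samples == %d",
                  length(s$timestamps), n))
  }
  if (length(s$timestamps) > 1L && any(diff(s$timestamps) <= 0)) {
    v <- c(v, say("timestamps not strictly increasing"))
  }
  if (nc != length(s$channel_labels)) {
    v <- c(v, say("%d channels but %d channel_labels", nc,
                  length(s$channel_labels)))
  }
  if (nc != length(s$units)) {
    v <- c(v, say("%d channels but %d unit strings", nc, length(s$units)))
  }
  if (!is.numeric(s$nominal_rate) || length(s$nominal_rate) != 1L ||
      is.na(s$nominal_rate) || s$nominal_rate <= 0) {
    v <- c(v, say("nominal_rate must be a positive number"))
  } else if (length(s$timestamps) > 1L) {
    md <- stats::median(diff(s$timestamps))
    if (is.finite(md) && md > 0 &&
        abs(md - 1 / s$nominal_rate) > 0.1 / s$nominal_rate) {
      v <- c(v, say(paste0("median timestamp increment %.6g s is more than ",
                           "10%% off 1/nominal_rate = %.6g s"),
                    md, 1 / s$nominal_rate))
    }
  }
  v
}

#' Validate a stream bundle against the data-model invariants
#'
#' Checks every stream (monotone timestamps, consistent channel counts and
#' units, plausible nominal rate), every event (byte-range code, finite
#' time, known clock), and bundle-level constraints (unique stream names).
#' The validator reports; it never throws, whatever the field values.
#'
#' @param bundle a [stream_bundle].
#' @return character vector of human-readable violations; empty if the
#'   bundle is well formed.
#' @export
validate_bundle <- function(bundle) {
  v <- character()
  if (!inherits(bundle, "stream_bundle")) {
    return("object is not a stream_bundle")
  }
  nms <- vapply(bundle$streams, function(s) as.character(s$name %||% ""),
                character(1))
  if (anyDuplicated(nms)) {
    v <- c(v, sprintf("duplicate stream names: %s",
                      paste(unique(nms[duplicated(nms)]), collapse = ", ")))
  }
  for (s in bundle$streams) v <- c(v, tryCatch(validate_stream(s),
                                               error = function(e) {
    sprintf("stream '%s': unvalidatable (%s)", s$name %||% "?",
            conditionMessage(e))
  }))
  ev <- bundle$events
  if (NROW(ev)) {
    bad_code <- which(is.na(ev$code) | ev$code < 0 | ev$code > 255)
    for (i in bad_code) {
      v <- c(v, sprintf("event %d: code %s outside 0..255", i,
                        format(ev$code[i])))
    }
    bad_time <- which(!is.finite(ev$time))
    for (i in bad_time) v <- c(v, sprintf("event %d: non-finite time", i))
    known_clocks <- unique(c(
      vapply(bundle$streams, function(s) as.character(s$clock_id %||% ""),
             character(1)),
      as.character(bundle$metadata$clocks %||% character()),
      names(bundle$metadata$clock_models %||% list())
    ))
    unknown <- setdiff(unique(ev$clock_id), known_clocks)
    for (cl in unknown) {
      v <- c(v, sprintf("event clock_id '%s' matches no stream clock or declared clock",
                        cl))
    }
    bad_src <- setdiff(unique(ev$source), EVENT_SOURCES)
    for (sr in bad_src) v <- c(v, sprintf("event source '%s' unknown", sr))
  }
  v
}
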