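# Stimulus/onset-locked analyses: EEG (VEP) and EMG.

#' VEP analysis configuration
#'
#' Band-pass 0.01-40 Hz with a 50 Hz notch, common-average reference,
#' epochs from -500 ms to 400 ms around each stimulus, baseline correction
#' over -500 to -100 ms, per-epoch linear detrending.  The N75 is the most
#' negative point in `n75_window`, the P100 the most positive in
#' `p100_window`; the windows follow standard pattern-reversal practice
#' and are configurable since atypical latencies may clip.
#'
#' @param bandpass length-2 band edges in Hz.
#' @param notch notch center in Hz (`NULL` to disable).
#' @param epoch_window,baseline length-2 windows in seconds.
#' @param n75_window,p100_window peak search windows in seconds.
#' @return list of class `vep_config`.
#' @export
vep_config <- function(bandpass = c(0.01, 40), notch = 50,
                       epoch_window = c(-0.5, 0.4),
                       baseline = c(-0.5, -0.1),
                       n75_window = c(0.05, 0.09),
                       p100_window = c(0.07, 0.15)) {
  stopifnot(epoch_window[1] < epoch_window[2],
            baseline[1] >= epoch_window[1], baseline[2] <= 0)
  structure(list(bandpass = bandpass, notch = notch,
                 epoch_window = epoch_window, baseline = baseline,
                 n75_window = n75_window, p100_window = p100_window),
            class = "vep_config")
}

#' Filter and re-reference an EEG stream
#'
#' Zero-phase band-pass and notch per channel, then common-average
#' re-referencing (per-sample channel mean subtracted).  A single-channel
#' stream skips re-referencing with a warning.  An `artifact_correction`
#' hook runs on the sample matrix after filtering; it defaults to the
#' identity (ocular-artifact ICA, an off-the-shelf step, can be plugged in
#' here).
#'
#' @param stream an `eeg` [timestamped_stream].
#' @param cfg a [vep_config].
#' @param artifact_correction function `matrix -> matrix` applied after
#'   filtering.
#' @return filtered [timestamped_stream].
#' @export
preprocess_eeg <- function(stream, cfg = vep_config(),
                           artifact_correction = identity) {
  fs <- stream$nominal_rate
  if (fs < 2 * cfg$bandpass[2]) {
    stop(sprintf("sampling rate %g Hz below twice the band-pass high edge %g Hz",
                 fs, cfg$bandpass[2]), call. = FALSE)
  }
  x <- stream$samples
  for (ch in seq_len(ncol(x))) {
    y <- bandpass_zero_phase(x[, ch], fs, cfg$bandpass[1], cfg$bandpass[2])
    if (!is.null(cfg$notch) && cfg$notch < fs / 2) {
      y <- notch_zero_phase(y, fs, cfg$notch)
    }
    x[, ch] <- y
  }
  x <- artifact_correction(x)
  if (ncol(x) >= 2L) {
    x <- x - rowMeans(x)
  } else {
    warning("single-channel stream: common-average re-referencing skipped",
            call. = FALSE)
  }
  stream$samples <- x
  stream
}

#' Cut event-locked epochs out of a stream
#'
#' Resampling-free windowing: for each locking event the nearest-timestamp
#' sample is taken as time zero and a fixed number of samples before and
#' after (from the nominal rate) is extracted.  Events whose window falls
#' outside the recording are kept but flagged (`qc_excluded`), never
#' dropped.
#'
#' @param stream a [timestamped_stream].
#' @param lock_events [marker_events] on the stream's clock, or a numeric
#'   vector of locking times.
#' @param window length-2 window `(start, end)` in seconds around each
#'   event.
#' @param baseline baseline window stored in the result.
#' @return an [epoch_set].
#' @export
epoch_stream <- function(stream, lock_events, window,
                         baseline = c(window[1], min(0, window[2]))) {
  times <- if (is.numeric(lock_events)) lock_events else lock_events$time
  codes <- if (is.numeric(lock_events)) rep(NA_integer_, length(times))
           else lock_events$code
  fs <- stream$nominal_rate
  n_pre <- round(-window[1] * fs)
  n_post <- round(window[2] * fs)
  rel <- (-n_pre:n_post) / fs
  nt <- length(rel)
  nc <- ncol(stream$samples)
  n <- nrow(stream$samples)
  data <- array(NA_real_, dim = c(length(times), nt, nc))
  flagged <- logical(length(times))
  for (k in seq_along(times)) {
    i0 <- findInterval(times[k], stream$timestamps)
    if (i0 >= 1L && i0 < n &&
        (stream$timestamps[i0 + 1L] - times[k]) < (times[k] - stream$timestamps[i0])) {
      i0 <- i0 + 1L
    }
    lo <- i0 - n_pre
    hi <- i0 + n_post
    if (i0 < 1L || lo < 1L || hi > n) {
      flagged[k] <- TRUE
      lo_c <- max(lo, 1L); hi_c <- min(hi, n)
      if (i0 >= 1L && lo_c <= hi_c) {
        data[k, (lo_c - lo + 1L):(lo_c - lo + hi_c - lo_c + 1L), ] <-
          stream$samples[lo_c:hi_c, , drop = FALSE]
      }
    } else {
      data[k, , ] <- stream$samples[lo:hi, , drop = FALSE]
    }
  }
  epoch_set(data, rel, stream$channel_labels, baseline,
            event_codes = codes, qc_excluded = flagged)
}

#' Detrend, baseline-correct and average epochs
#'
#' Per epoch and channel: linear detrend over the whole epoch, then
#' subtraction of the mean over the baseline window; the evoked response
#' is the mean across unexcluded trials with a 95% confidence band
#' (`mean +- 1.96 * SEM`, normal approximation -- adequate at the trial
#' counts this package targets).
#'
#' @param epochs an [epoch_set].
#' @param baseline optional override of the epoch set's baseline window.
#' @return list with `times`, `mean`, `ci_low`, `ci_high` (each
#'   `n_times x n_channels`), `n_trials`, `channel_labels`,
#'   `baseline_window`, and the corrected per-trial array `trials`.
#' @export
detrend_baseline_average <- function(epochs, baseline = NULL) {
  bl <- baseline %||% epochs$baseline_window
  tt <- epochs$times
  bsel <- tt >= bl[1] & tt <= bl[2]
  if (!any(bsel)) stop("baseline window outside epoch times", call. = FALSE)
  d <- epochs$data
  nT <- dim(d)[1]; nc <- dim(d)[3]
  tc <- tt - mean(tt)
  stt <- sum(tc^2)
  for (k in seq_len(nT)) {
    for (ch in seq_len(nc)) {
      y <- d[k, , ch]
      ok <- is.finite(y)
      if (!any(ok)) next
      slope <- sum(tc[ok] * (y[ok] - mean(y[ok]))) / sum(tc[ok]^2)
      y <- y - (mean(y[ok]) + slope * tc)
      y <- y - mean(y[bsel], na.rm = TRUE)
      d[k, , ch] <- y
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

#' Measure N75 and P100 on an evoked VEP
#'
#' @param evoked result of [detrend_baseline_average()].
#' @param cfg a [vep_config].
#' @param channel channel label or index (default first channel).
#' @return data frame of peak measures (`label`, `latency` s, `amplitude`,
#'   `channel`, `window_lo`, `window_hi`, `degenerate`); a warning flag is
#'   attached when the N75 latency does not precede the P100 latency.
#' @export
find_vep_peaks <- function(evoked, cfg = vep_config(), channel = 1L) {
  if (is.character(channel)) {
    channel <- match(channel, evoked$channel_labels)
  }
  tt <- evoked$times
  y <- evoked$mean[, channel]
  measure <- function(label, win, sign) {
    sel <- which(tt >= win[1] & tt <= win[2])
    if (!length(sel)) stop("evoked does not cover the ", label, " window",
                           call. = FALSE)
    i <- sel[if (sign > 0) which.max(y[sel]) else which.min(y[sel])]
    degenerate <- stats::sd(y[sel]) == 0
    if (degenerate) i <- sel[1]
    data.frame(label = label, latency = tt[i], amplitude = y[i],
               channel = evoked$channel_labels[channel],
               window_lo = win[1], window_hi = win[2],
               degenerate = degenerate, stringsAsFactors = FALSE)
  }
  out <- rbind(measure("N75", cfg$n75_window, -1),
               measure("P100", cfg$p100_window, +1))
  if (out$latency[1] >= out$latency[2]) {
    warning("N75 latency does not precede P100 latency; check windows",
            call. = FALSE)
    attr(out, "window_conflict") <- TRUE
  }
  out
}

#' EMG analysis configuration
#'
#' @param moving_average_points width of the moving-average filter in
#'   samples (default 100).
#' @param epoch_window epoch window in seconds (default -5 to 15).
#' @return list of class `emg_config`.
#' @export
emg_config <- function(moving_average_points = 100,
                       epoch_window = c(-5, 15)) {
  stopifnot(moving_average_points >= 1)
  structure(list(moving_average_points = moving_average_points,
                 epoch_window = epoch_window),
            class = "emg_config")
}

#' Onset-locked rectified EMG average
#'
#' DC removal over the full recording, rectification (absolute value), a
#' centered moving average over `moving_average_points` samples, epoching
#' around the kinetic movement onsets (never the EMG's own burst times),
#' and averaging with a 95% confidence band.
#'
#' @param stream an `emg` [timestamped_stream].
#' @param onsets [marker_events] of kinetic onsets on the stream's clock,
#'   or a numeric vector of onset times.
#' @param cfg an [emg_config].
#' @return list with `epochs` (an [epoch_set] of the processed signal) and
#'   `evoked` (from [detrend_baseline_average()] without detrending; see
#'   Details).
#' @details The smoothed rectified trace is averaged directly (mean and
#'   95% CI per time point); no per-epoch detrending or baseline
#'   subtraction is applied, since the rectified signal is strictly
#'   non-negative and its baseline level is informative.
#' @export
emg_pipeline <- function(stream, onsets, cfg = emg_config()) {
  x <- stream$samples[, 1]
  x <- abs(x - mean(x))
  k <- cfg$moving_average_points
  sm <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
  sm[is.na(sm)] <- 0
  proc <- stream
  proc$samples <- matrix(sm, ncol = 1)
  epochs <- epoch_stream(proc, onsets, cfg$epoch_window,
                         baseline = c(cfg$epoch_window[1], -0.1))
  keep <- which(!epochs$qc_excluded)
  d <- epochs$data[keep, , 1, drop = FALSE]
  m <- apply(d, 2, mean)
  sem <- apply(d, 2, stats::sd) / sqrt(length(keep))
  list(epochs = epochs,
       evoked = list(times = epochs$times, mean = m,
                     ci_low = m - 1.96 * sem, ci_high = m + 1.96 * sem,
                     n_trials = length(keep)))
}
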