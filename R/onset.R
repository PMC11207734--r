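# Movement-onset detection from center-of-pressure traces.

#' Configuration of the COP movement-onset detector
#'
#' The detector low-pass filters the anteroposterior and mediolateral COP
#' positions (zero-phase second-order Butterworth, 5 Hz), combines their
#' per-sample first differences as the square root of the sum of squares,
#' finds the first crossing of `crossing_threshold`, and designates as the
#' movement onset the local minimum nearest to that crossing whose height
#' does not exceed `local_min_max_height`.
#'
#' Units: the thresholds are in the "combined derivative" unit -- mm of COP
#' displacement per sample at the kinetic sampling rate (first difference
#' of a mm-scaled COP trace at 1000 Hz).  Rescaling the input rescales the
#' statistic, so input units and thresholds must be configured together.
#'
#' @param lowpass_cutoff Hz (default 5).
#' @param filter_order one-pass Butterworth order, applied
#'   forward-backward (default 2).
#' @param crossing_threshold threshold on the combined derivative
#'   (default 0.3, arbitrary/mm-per-sample units).
#' @param local_min_max_height maximum height of a qualifying local
#'   minimum (default 0.05).
#' @param search_radius seconds around the crossing searched for the local
#'   minimum (default 2).
#' @param baseline_qc_limit QC limit on the combined derivative during the
#'   pre-onset baseline (default 0.05).
#' @return list of class `cop_onset_config`.
#' @export
cop_onset_config <- function(lowpass_cutoff = 5, filter_order = 2,
                             crossing_threshold = 0.3,
                             local_min_max_height = 0.05,
                             search_radius = 2.0,
                             baseline_qc_limit = 0.05) {
  stopifnot(local_min_max_height > 0,
            local_min_max_height < crossing_threshold)
  structure(list(lowpass_cutoff = lowpass_cutoff,
                 filter_order = filter_order,
                 crossing_threshold = crossing_threshold,
                 local_min_max_height = local_min_max_height,
                 search_radius = search_radius,
                 baseline_qc_limit = baseline_qc_limit),
            class = "cop_onset_config")
}

#' Combined derivative of the two COP directions
#'
#' Per-sample first differences of the (already filtered) anteroposterior
#' and mediolateral series, combined as the square root of the sum of
#' squares: `c[i] = sqrt(dAP[i]^2 + dML[i]^2)`.
#'
#' @param ap,ml equal-length numeric vectors (filtered COP, mm).
#' @return non-negative numeric vector of length `length(ap) - 1`.
#' @export
combined_derivative <- function(ap, ml) {
  if (length(ap) != length(ml)) {
    stop("ap and ml must have equal length", call. = FALSE)
  }
  sqrt(diff(ap)^2 + diff(ml)^2)
}

# Local minima with plateau rule: a run of equal values counts once, at its
# first sample.  Endpoints are not candidates.
local_minima <- function(c) {
  n <- length(c)
  if (n < 3L) return(integer())
  j <- 2:(n - 1L)
  j[c[j] < c[j - 1L] & c[j] <= c[j + 1L]]
}

#' Detect the movement onset in a combined-derivative series
#'
#' Finds the first sample exceeding `crossing_threshold`; among local
#' minima at or below `local_min_max_height` within `search_radius`
#' seconds of the crossing, returns the one nearest in time to it (an
#' equidistant tie goes to the earlier minimum, since the onset precedes
#' the excursion physically).
#'
#' @param combined combined-derivative series from [combined_derivative()].
#' @param cfg a [cop_onset_config].
#' @param fs sampling rate in Hz.
#' @param t0 time of the first sample of `combined` (s); detected time is
#'   `t0 + (index - 1) / fs`.
#' @return list with `index` (1-based sample index, `NA` if absent),
#'   `time`, `crossing_index`, and `reason` (`"ok"`, `"no_crossing"`, or
#'   `"no_local_min"`).
#' @examples
#' detect_onset(c(0.01, 0.02, 0.01, 0.03, 0.02, 0.20, 0.50),
#'              cop_onset_config(), fs = 1000)
#' @export
detect_onset <- function(combined, cfg = cop_onset_config(), fs = 1000,
                         t0 = 0) {
  cross <- which(combined > cfg$crossing_threshold)[1]
  if (is.na(cross)) {
    return(list(index = NA_integer_, time = NA_real_,
                crossing_index = NA_integer_, reason = "no_crossing"))
  }
  mins <- local_minima(combined)
  mins <- mins[combined[mins] <= cfg$local_min_max_height]
  mins <- mins[abs(mins - cross) <= cfg$search_radius * fs]
  if (!length(mins)) {
    return(list(index = NA_integer_, time = NA_real_,
                crossing_index = cross, reason = "no_local_min"))
  }
  d <- abs(mins - cross)
  best <- mins[d == min(d)]
  idx <- min(best)   # equidistant tie -> earlier minimum
  list(index = idx, time = t0 + (idx - 1L) / fs,
       crossing_index = cross, reason = "ok")
}

#' Advisory quality-control flags for COP trials
#'
#' A trial is flagged when its combined derivative exceeds
#' `baseline_qc_limit` anywhere in the pre-onset baseline window, or when
#' no onset was found.  Flags are advisory: actual exclusion requires an
#' explicit list, mirroring the visual-inspection step of the original
#' workflow, and the manual lists override the flags in both directions.
#'
#' @param combined_trials list of per-trial combined-derivative series.
#' @param detections list of per-trial results from [detect_onset()].
#' @param cfg a [cop_onset_config].
#' @param fs sampling rate in Hz.
#' @param baseline_margin seconds before the detected onset excluded from
#'   the baseline window (default 1).
#' @param manual_exclude,manual_include integer trial indices that force
#'   the final exclusion flag on or off.
#' @return data frame with `flagged`, `reason`, and the final `excluded`.
#' @export
qc_trials <- function(combined_trials, detections, cfg = cop_onset_config(),
                      fs = 1000, baseline_margin = 1,
                      manual_exclude = integer(), manual_include = integer()) {
  n <- length(combined_trials)
  flagged <- logical(n)
  reason <- character(n)
  for (k in seq_len(n)) {
    det <- detections[[k]]
    if (is.na(det$index)) {
      flagged[k] <- TRUE
      reason[k] <- det$reason
      next
    }
    b_end <- det$index - round(baseline_margin * fs)
    if (b_end >= 1L &&
        any(combined_trials[[k]][seq_len(b_end)] > cfg$baseline_qc_limit)) {
      flagged[k] <- TRUE
      reason[k] <- "baseline_excursion"
    } else {
      reason[k] <- "clean"
    }
  }
  excluded <- flagged
  excluded[manual_include] <- FALSE
  excluded[manual_exclude] <- TRUE
  data.frame(trial = seq_len(n), flagged = flagged, reason = reason,
             excluded = excluded, stringsAsFactors = FALSE)
}

#' Detect movement onsets across the trials of a COP stream
#'
#' Full pipeline over a two-channel (`AP`, `ML`) COP stream: zero-phase
#' low-pass filtering of both directions, combined derivative, and
#' per-trial onset detection within windows starting at the given trial
#' start times.
#'
#' @param cop a `cop` [timestamped_stream] with channels `AP` and `ML`.
#' @param trial_starts trial start times on the stream's clock; each trial
#'   window runs to the next start (or the end of the recording).
#' @param cfg a [cop_onset_config].
#' @return list with `onsets` ([marker_events], `source = "derived_onset"`,
#'   code 100, one per detected onset), `detections` (per-trial
#'   [detect_onset()] results), `qc` (from [qc_trials()]), and `combined`
#'   (the full combined-derivative series).
#' @export
detect_cop_onsets <- function(cop, trial_starts, cfg = cop_onset_config()) {
  fs <- cop$nominal_rate
  ap <- lowpass_zero_phase(cop$samples[, "AP"], fs, cfg$lowpass_cutoff,
                           cfg$filter_order)
  ml <- lowpass_zero_phase(cop$samples[, "ML"], fs, cfg$lowpass_cutoff,
                           cfg$filter_order)
  comb <- combined_derivative(ap, ml)
  tt <- cop$timestamps[-1]   # c[i] sits on the later sample of each diff
  starts <- sort(trial_starts)
  ends <- c(starts[-1], tt[length(tt)])
  detections <- vector("list", length(starts))
  combined_trials <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    sel <- which(tt >= starts[k] & tt < ends[k])
    combined_trials[[k]] <- comb[sel]
    det <- detect_onset(comb[sel], cfg, fs = fs, t0 = tt[sel[1]])
    detections[[k]] <- det
  }
  qc <- qc_trials(combined_trials, detections, cfg, fs = fs)
  ok <- !vapply(detections, function(d) is.na(d$index), logical(1))
  onsets <- marker_events(
    code = 100L,
    time = vapply(detections[ok], `[[`, numeric(1), "time"),
    clock_id = cop$clock_id, source = "derived_onset"
  )
  list(onsets = onsets, detections = detections, qc = qc, combined = comb)
}
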