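# Clock alignment and display-delay diagnostics.

#' Match two marker sequences by code
#'
#' When both sequences carry the same codes in the same order every event
#' is paired; otherwise the longest common subsequence of the code
#' sequences is used, with ties broken by nearest event time after a
#' coarse offset estimate (the median time difference).
#'
#' @param events_a,events_b [marker_events], time-sorted.
#' @return two-column integer matrix of (index in a, index in b) pairs.
#' @export
match_marker_sequences <- function(events_a, events_b) {
  a <- events_a$code
  b <- events_b$code
  na <- length(a); nb <- length(b)
  if (na && nb && na == nb && all(a == b)) {
    pairs <- cbind(a = seq_len(na), b = seq_len(nb))
  } else {
    # LCS dynamic program on codes; backtrack prefers time-consistent pairs
    off <- stats::median(outer(events_b$time, events_a$time, "-")[
      outer(b, a, "==")], na.rm = TRUE)
    if (!is.finite(off)) off <- 0
    L <- matrix(0L, na + 1L, nb + 1L)
    for (i in seq_len(na)) {
      for (j in seq_len(nb)) {
        L[i + 1L, j + 1L] <- if (a[i] == b[j]) L[i, j] + 1L
                             else max(L[i, j + 1L], L[i + 1L, j])
      }
    }
    ia <- na; ib <- nb
    pa <- integer(); pb <- integer()
    while (ia > 0L && ib > 0L) {
      if (a[ia] == b[ib] && L[ia + 1L, ib + 1L] == L[ia, ib] + 1L) {
        # tie-break: skip a match far off the coarse offset if an equally
        # long path exists without it
        dt <- abs((events_b$time[ib] - events_a$time[ia]) - off)
        alt <- max(L[ia, ib + 1L], L[ia + 1L, ib])
        if (alt == L[ia + 1L, ib + 1L] && dt > 1) {
          if (L[ia, ib + 1L] >= L[ia + 1L, ib]) ia <- ia - 1L else ib <- ib - 1L
          next
        }
        pa <- c(ia, pa); pb <- c(ib, pb)
        ia <- ia - 1L; ib <- ib - 1L
      } else if (L[ia, ib + 1L] >= L[ia + 1L, ib]) {
        ia <- ia - 1L
      } else {
        ib <- ib - 1L
      }
    }
    pairs <- cbind(a = pa, b = pb)
  }
  if (nrow(pairs) < 2L) {
    stop("fewer than 2 matching marker pairs; cannot fit a clock mapping",
         call. = FALSE)
  }
  pairs
}

#' Fit an affine clock mapping from paired event times
#'
#' Least-squares fit of `t_to = offset_a + rate_b * t_from`, the standard
#' first-order model for near-linear hardware clock drift.  Computed by
#' centered closed-form regression for numerical stability on large time
#' values.
#'
#' @param t_from,t_to numeric vectors of paired times (s); at least 2 pairs.
#' @param from_clock,to_clock clock labels stored in the mapping.
#' @return object of class `clock_mapping` with `offset_a`, `rate_b`, and
#'   residual statistics (`residual_rms`, `residual_min`, `residual_max`,
#'   `n_pairs`).
#' @export
fit_clock_mapping <- function(t_from, t_to, from_clock = "from",
                              to_clock = "to") {
  if (length(t_from) != length(t_to)) {
    stop("t_from and t_to must have equal length", call. = FALSE)
  }
  if (length(t_from) < 2L) stop("need at least 2 pairs", call. = FALSE)
  mx <- mean(t_from); my <- mean(t_to)
  dx <- t_from - mx; dy <- t_to - my
  sxx <- sum(dx^2)
  if (sxx == 0) stop("degenerate pairs: all t_from identical", call. = FALSE)
  rate <- sum(dx * dy) / sxx
  offset <- my - rate * mx
  resid <- t_to - (offset + rate * t_from)
  structure(list(from_clock = from_clock, to_clock = to_clock,
                 offset_a = offset, rate_b = rate,
                 residual_rms = sqrt(mean(resid^2)),
                 residual_min = min(resid), residual_max = max(resid),
                 n_pairs = length(t_from)),
            class = "clock_mapping")
}

#' @export
print.clock_mapping <- function(x, ...) {
  cat(sprintf("<clock_mapping> %s -> %s: t' = %.9g + %.9f * t\n",
              x$from_clock, x$to_clock, x$offset_a, x$rate_b))
  cat(sprintf("  drift %+.1f ppm, residual rms %.3g s over %d pairs\n",
              (x$rate_b - 1) * 1e6, x$residual_rms, x$n_pairs))
  invisible(x)
}

#' Invert a clock mapping
#' @param mapping a `clock_mapping`.
#' @return the inverse `clock_mapping`.
#' @export
invert_mapping <- function(mapping) {
  structure(list(from_clock = mapping$to_clock, to_clock = mapping$from_clock,
                 offset_a = -mapping$offset_a / mapping$rate_b,
                 rate_b = 1 / mapping$rate_b,
                 residual_rms = mapping$residual_rms,
                 residual_min = mapping$residual_min,
                 residual_max = mapping$residual_max,
                 n_pairs = mapping$n_pairs),
            class = "clock_mapping")
}

#' Re-time a stream or event table onto another clock
#'
#' @param x a [timestamped_stream] or [marker_events].
#' @param mapping a `clock_mapping`; applied as
#'   `t' = offset_a + rate_b * t`, and the clock label is updated.
#' @return a retimed copy of `x`.
#' @export
apply_mapping <- function(x, mapping) {
  if (inherits(x, "timestamped_stream")) {
    x$timestamps <- mapping$offset_a + mapping$rate_b * x$timestamps
    x$clock_id <- mapping$to_clock
  } else {
    x$time <- mapping$offset_a + mapping$rate_b * x$time
    x$clock_id <- mapping$to_clock
  }
  x
}

#' Fit the mapping between two clocks of a bundle from shared command markers
#'
#' @param bundle a [stream_bundle] whose event table carries command
#'   markers stamped on both clocks.
#' @param from_clock,to_clock clock labels.
#' @return a `clock_mapping`.
#' @export
clock_mapping_between <- function(bundle, from_clock, to_clock) {
  ev <- bundle$events
  a <- ev[ev$clock_id == from_clock & ev$source == "command", , drop = FALSE]
  b <- ev[ev$clock_id == to_clock & ev$source == "command", , drop = FALSE]
  if (!nrow(a) || !nrow(b)) {
    stop(sprintf("no command markers on clock '%s' and/or '%s'",
                 from_clock, to_clock), call. = FALSE)
  }
  pairs <- match_marker_sequences(a, b)
  fit_clock_mapping(a$time[pairs[, 1]], b$time[pairs[, 2]],
                    from_clock, to_clock)
}

#' Display-delay report between command and decoded blink events
#'
#' Pairs command events with photodiode-decoded events
#' ([match_marker_sequences()]) and reports the per-event delay
#' `decoded blink time - command time - constant_display_delay` on the
#' common clock.  With `constant_display_delay = 0` the delays include the
#' fixed projection latency; passing the calibrated projector delay
#' isolates the variable (jitter) part, as used when diagnosing the
#' two-script fault.  The session is flagged as jittered when the delay
#' range exceeds `jitter_threshold` -- by default half a frame period,
#' since a delay constant up to frame quantization is synchronous for a
#' frame-locked display.
#'
#' @param command_events,decoded_events [marker_events] on a common clock.
#' @param jitter_threshold seconds; default half the frame period.
#' @param frame_rate display frame rate used for the default threshold.
#' @param constant_display_delay known constant display latency (s)
#'   subtracted from every delay.
#' @return object of class `delay_report` with fields `delays`, `min`,
#'   `max`, `range`, `mean`, `sd`, `is_jittered`, `jitter_threshold`.
#' @export
delay_report <- function(command_events, decoded_events,
                         jitter_threshold = NULL, frame_rate = 60,
                         constant_display_delay = 0) {
  if (is.null(jitter_threshold)) jitter_threshold <- 0.5 / frame_rate
  pairs <- match_marker_sequences(command_events, decoded_events)
  delays <- decoded_events$time[pairs[, 2]] -
    command_events$time[pairs[, 1]] - constant_display_delay
  structure(list(delays = delays,
                 min = min(delays), max = max(delays),
                 range = max(delays) - min(delays),
                 mean = mean(delays), sd = stats::sd(delays),
                 is_jittered = (max(delays) - min(delays)) > jitter_threshold,
                 jitter_threshold = jitter_threshold,
                 n = length(delays)),
            class = "delay_report")
}

#' @export
print.delay_report <- function(x, ...) {
  cat(sprintf("<delay_report> %d event(s)\n", x$n))
  cat(sprintf("  delay mean %.1f ms (sd %.2f), range %.1f ms [%.1f, %.1f]\n",
              x$mean * 1e3, x$sd * 1e3, x$range * 1e3, x$min * 1e3,
              x$max * 1e3))
  cat(sprintf("  jitter threshold %.2f ms -> %s\n", x$jitter_threshold * 1e3,
              if (x$is_jittered) "JITTERED" else "synchronous"))
  invisible(x)
}

#' Select projection-true locking events
#'
#' Downstream epoching must lock to photodiode-decoded events, which carry
#' the same delay as the entire projection, never to software command
#' times.  This is a selection policy: the decoded events are returned
#' unchanged and the choice is recorded in an audit attribute.
#'
#' @param decoded_events photodiode-decoded [marker_events].
#' @return the events, with an `audit` attribute describing the policy.
#' @export
compensate_display_delay <- function(decoded_events) {
  if (nrow(decoded_events) &&
      !all(decoded_events$source == "photodiode_decoded")) {
    warning("locking to events not decoded from the photodiode; ",
            "projection delay is NOT compensated", call. = FALSE)
  }
  attr(decoded_events, "audit") <-
    sprintf("locking to %d photodiode-decoded event time(s); command times not used",
            nrow(decoded_events))
  decoded_events
}
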