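# Zero-phase IIR filtering utilities.
#
# Filter design comes from signal::butter; the forward-backward pass is done
# here with odd (reflective, point-symmetric) end padding so that edge
# transients do not leak into the record, matching the standard
# filter-filter-reverse recipe.

apply_filtfilt <- function(b, a, x) {
  n <- length(x)
  nfilt <- max(length(a), length(b))
  if (n <= 3L * (nfilt - 1L)) {
    stop(sprintf("series of length %d too short for zero-phase filtering (need > %d)",
                 n, 3L * (nfilt - 1L)), call. = FALSE)
  }
  # pad by three pole time constants so start-up transients die inside the
  # padding -- essential for high-pass edges far below Nyquist, whose poles
  # sit within 1e-4 of the unit circle
  r <- max(Mod(polyroot(rev(a))))
  tau <- if (r < 1) -1 / log(r) else n
  padlen <- min(n - 1L, max(3L * (nfilt - 1L), ceiling(3 * tau)))
  # odd extension: 2*x[1] - x[k] mirrors the signal point-symmetrically
  pre <- 2 * x[1] - x[seq(padlen + 1L, 2L)]
  post <- 2 * x[n] - x[seq(n - 1L, n - padlen)]
  ext <- c(pre, x, post)
  # steady-state initialization: treat the record as preceded (followed)
  # by an infinite constant at its first (last) value, so DC passes a
  # low-pass exactly and is removed exactly by a high-pass, without the
  # kilosample start-up transients of zero initial conditions
  hdc <- sum(b) / sum(a)
  run <- function(z) {
    signal::filter(b, a, z, init.x = rep(z[1], nfilt - 1L),
                   init.y = rep(z[1] * hdc, nfilt - 1L))
  }
  y <- run(ext)
  y <- rev(run(rev(y)))
  y[seq(padlen + 1L, padlen + n)]
}

butter_coefs <- function(order, cutoff_hz, fs, type) {
  nyq <- fs / 2
  w <- cutoff_hz / nyq
  if (any(w <= 0) || any(w >= 1)) {
    stop(sprintf("cutoff %s Hz outside (0, Nyquist = %g Hz)",
                 paste(cutoff_hz, collapse = ", "), nyq), call. = FALSE)
  }
  bf <- signal::butter(order, w, type = type)
  list(b = bf$b, a = bf$a)
}

#' Zero-phase Butterworth low-pass filter
#'
#' Second-order (by default) low-pass Butterworth applied forward and
#' backward, so the effective magnitude response is the squared one-pass
#' response and the phase is identically zero.  Used to smooth
#' center-of-pressure traces before onset detection.
#'
#' @param x numeric vector, uniformly sampled.
#' @param fs sampling rate in Hz.
#' @param cutoff_hz low-pass cut-off frequency in Hz (default 5).
#' @param order one-pass filter order (default 2).
#' @return filtered numeric vector, same length as `x`.
#' @examples
#' lowpass_zero_phase(rep(1, 100), fs = 100)  # DC passes unchanged
#' @export
lowpass_zero_phase <- function(x, fs, cutoff_hz = 5, order = 2) {
  co <- butter_coefs(order, cutoff_hz, fs, "low")
  apply_filtfilt(co$b, co$a, x)
}

#' Zero-phase band-pass (high-pass + low-pass cascade)
#'
#' The band edges are implemented as a cascade of a second-order high-pass
#' and a second-order low-pass, each run forward-backward.  The cascade is
#' numerically safer than a single band-pass section when the lower edge is
#' orders of magnitude below Nyquist (0.01 Hz on a 500 Hz EEG record).
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param low,high band edges in Hz; either may be `NULL` to skip that edge.
#' @param order per-section one-pass order.
#' @return filtered vector.
#' @export
bandpass_zero_phase <- function(x, fs, low, high, order = 2) {
  y <- x
  if (!is.null(low) && low > 0) {
    co <- butter_coefs(order, low, fs, "high")
    y <- apply_filtfilt(co$b, co$a, y)
  }
  if (!is.null(high) && is.finite(high)) {
    co <- butter_coefs(order, high, fs, "low")
    y <- apply_filtfilt(co$b, co$a, y)
  }
  y
}

#' Zero-phase band-stop (notch) filter
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param center notch center frequency in Hz.
#' @param width full stop-band width in Hz (default 4).
#' @param order one-pass order of the band-stop section.
#' @return filtered vector.
#' @export
notch_zero_phase <- function(x, fs, center, width = 4, order = 2) {
  co <- butter_coefs(order, c(center - width / 2, center + width / 2),
                     fs, "stop")
  apply_filtfilt(co$b, co$a, x)
}
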