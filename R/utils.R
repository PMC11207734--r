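# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so simulator calls are reproducible
#' without disturbing the caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

#' Band-limited 1/f-shaped noise via spectral shaping
#'
#' White Gaussian noise is shaped in the frequency domain with an amplitude
#' spectrum proportional to 1/f above `f_floor` (flat below it, so the DC
#' region stays finite), then rescaled to the requested standard deviation.
#' The 1/f amplitude roll-off concentrates the variance at slow drifts the
#' event-related pipeline removes by detrending, as in resting EEG.
#'
#' @param n number of samples
#' @param fs sampling rate in Hz
#' @param sd target standard deviation of the trace
#' @param f_floor Hz below which the spectrum is flat
#' @noRd
pink_noise <- function(n, fs, sd = 1, f_floor = 0.1) {
  shaped_noise(n, fs, sd, function(freq) 1 / pmax(freq, f_floor))
}

# Spectrally shaped Gaussian noise.  The FFT length is padded to the next
# highly composite integer (radix 2/3/5) -- R's fft degrades to quadratic
# time on awkward prime lengths -- and the series truncated back to n.
shaped_noise <- function(n, fs, sd, gain_fn) {
  if (n < 2) return(rep(0, n))
  m <- stats::nextn(n, c(2L, 3L, 5L))
  white <- stats::rnorm(m)
  spec <- stats::fft(white)
  freq <- seq(0, fs, length.out = m + 1)[seq_len(m)]
  freq[freq > fs / 2] <- fs - freq[freq > fs / 2]  # fold negative frequencies
  gain <- gain_fn(freq)
  gain[1] <- 0  # zero-mean
  x <- Re(stats::fft(spec * gain, inverse = TRUE))[seq_len(n)] / m
  s <- stats::sd(x)
  if (s == 0) return(rep(0, n))
  x * (sd / s)
}

#' Band-limited Gaussian noise (flat spectrum inside [f_min, f_max])
#' @noRd
band_noise <- function(n, fs, sd = 1, f_min = 0, f_max = Inf) {
  shaped_noise(n, fs, sd,
               function(freq) as.numeric(freq >= f_min & freq <= f_max))
}

lowband_noise <- function(n, fs, sd = 1, f_max = 1) {
  band_noise(n, fs, sd = sd, f_min = 0, f_max = f_max)
}

# Smoothstep ramp: 0 for u <= 0, 1 for u >= 1, 3u^2 - 2u^3 between.
smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}
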