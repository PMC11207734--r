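# fNIRS analysis: modified Beer-Lambert law, short-channel regression,
# hemodynamic response metrics.

#' fNIRS hemodynamic analysis configuration
#'
#' @param bandpass band edges in Hz (default 0.02-0.2, attenuating slow
#'   drifts and cardiac/respiratory frequencies around the hemodynamic
#'   band).
#' @param epoch_window epoch window in seconds (default -5 to 15 around
#'   movement onset).
#' @param baseline baseline window in seconds (default -5 to -0.1 before
#'   onset).
#' @param geometry an [fnirs_geometry] (wavelengths, extinction table,
#'   differential pathlength factor, source-detector distances).
#' @return list of class `hemo_config`.
#' @export
hemo_config <- function(bandpass = c(0.02, 0.2),
                        epoch_window = c(-5, 15),
                        baseline = c(-5, -0.1),
                        geometry = fnirs_geometry()) {
  structure(list(bandpass = bandpass, epoch_window = epoch_window,
                 baseline = baseline, geometry = geometry),
            class = "hemo_config")
}

#' Convert dual-wavelength intensities to hemoglobin concentration changes
#'
#' Optical density `OD(t) = -log10(I(t) / mean(I))` per channel and
#' wavelength, then the 2x2 extinction system is solved per channel with
#' pathlength `distance * DPF` (modified Beer-Lambert law), giving
#' concentration changes in uM.  Non-positive intensity samples are
#' linearly interpolated and reported in the `interp_log` attribute.
#'
#' @param wl1,wl2 `fnirs_intensity` [timestamped_stream]s for the two
#'   wavelengths, same channels and timestamps.
#' @param geometry an [fnirs_geometry].
#' @param distances_cm named numeric vector of source-detector distances
#'   per channel (cm); defaults to the long distance for every channel.
#' @return list of two `fnirs_hemo` [timestamped_stream]s, `hbo` and
#'   `hbr`, in uM.
#' @export
intensities_to_hemoglobin <- function(wl1, wl2, geometry = fnirs_geometry(),
                                      distances_cm = NULL) {
  if (!isTRUE(all.equal(wl1$timestamps, wl2$timestamps))) {
    stop("wavelength streams must share timestamps", call. = FALSE)
  }
  chs <- wl1$channel_labels
  if (is.null(distances_cm)) {
    distances_cm <- stats::setNames(rep(geometry$long_distance, length(chs)),
                                    chs)
  }
  interp_log <- character()
  fix_positive <- function(x, ch, wl) {
    bad <- which(!(x > 0) | !is.finite(x))
    if (length(bad)) {
      interp_log <<- c(interp_log,
                       sprintf("channel %s @ %s nm: %d non-positive sample(s) interpolated",
                               ch, wl, length(bad)))
      good <- setdiff(seq_along(x), bad)
      x[bad] <- stats::approx(good, x[good], xout = bad, rule = 2)$y
    }
    x
  }
  E <- geometry$extinction
  hbo <- hbr <- matrix(0, nrow(wl1$samples), length(chs))
  for (j in seq_along(chs)) {
    i1 <- fix_positive(wl1$samples[, j], chs[j], geometry$wavelengths[1])
    i2 <- fix_positive(wl2$samples[, j], chs[j], geometry$wavelengths[2])
    od <- rbind(-log10(i1 / mean(i1)), -log10(i2 / mean(i2)))
    L <- (distances_cm[[chs[j]]] %||% geometry$long_distance) * geometry$dpf
    conc <- solve(E, od) / (1e-6 * L)   # uM
    hbo[, j] <- conc[1, ]
    hbr[, j] <- conc[2, ]
  }
  mk <- function(mat, nm) {
    s <- timestamped_stream(
      name = nm, modality = "fnirs_hemo", samples = mat,
      timestamps = wl1$timestamps, nominal_rate = wl1$nominal_rate,
      channel_labels = chs, units = "uM", clock_id = wl1$clock_id
    )
    attr(s, "interp_log") <- interp_log
    s
  }
  list(hbo = mk(hbo, "hbo"), hbr = mk(hbr, "hbr"))
}

#' Regress short-channel systemic signal out of long channels
#'
#' Per long channel (and chromophore, if applied to each in turn):
#' ordinary least-squares regression of the long-channel series on its
#' nearest short channel; the corrected series is the residual.  Short
#' channels (~1 cm separation) sample mainly extracerebral systemic
#' physiology, so the residual retains the cortical signal.
#'
#' @param long_mat matrix of long-channel series (columns = channels).
#' @param short_mat matrix (or vector) of short-channel series.
#' @param nearest_short named character vector mapping long-channel names
#'   to short-channel names; defaults to the single short channel.
#' @return matrix of corrected long-channel series; regression slopes in
#'   the `slopes` attribute.
#' @export
short_channel_correct <- function(long_mat, short_mat,
                                  nearest_short = NULL) {
  long_mat <- as.matrix(long_mat)
  short_mat <- as.matrix(short_mat)
  if (ncol(short_mat) < 1L) {
    stop("at least one short channel is required", call. = FALSE)
  }
  out <- long_mat
  slopes <- numeric(ncol(long_mat))
  for (j in seq_len(ncol(long_mat))) {
    sname <- if (!is.null(nearest_short) && !is.null(colnames(long_mat))) {
      nearest_short[[colnames(long_mat)[j]]] %||% colnames(short_mat)[1]
    } else {
      colnames(short_mat)[1] %||% 1L
    }
    s <- short_mat[, sname]
    fit <- stats::lm.fit(cbind(1, s), long_mat[, j])
    slopes[j] <- fit$coefficients[2]
    out[, j] <- fit$residuals
  }
  attr(out, "slopes") <- slopes
  out
}

#' Shape metrics of an evoked hemodynamic response
#'
#' Initial dip: minimum in (0, 3) s; peak: maximum in (3, 12) s; return
#' time: first time after the peak at which the absolute response falls
#' below 10% of the peak amplitude.  Latencies are relative to movement
#' onset.
#'
#' @param times time axis in seconds relative to onset.
#' @param evoked evoked oxygenated-hemoglobin change, uM.
#' @param dip_window,peak_window search windows in seconds.
#' @param return_fraction return-to-baseline criterion as a fraction of
#'   the peak amplitude.
#' @return data frame of measures (`HbO2_dip`, `HbO2_peak`,
#'   `HbO2_return`), with `latency` and `amplitude`; degenerate (flat)
#'   input is flagged.
#' @export
hemo_response_metrics <- function(times, evoked, dip_window = c(0, 3),
                                  peak_window = c(3, 12),
                                  return_fraction = 0.1) {
  stopifnot(length(times) == length(evoked))
  degenerate <- stats::sd(evoked, na.rm = TRUE) == 0
  sel_d <- which(times > dip_window[1] & times < dip_window[2])
  sel_p <- which(times > peak_window[1] & times < peak_window[2])
  i_d <- sel_d[which.min(evoked[sel_d])]
  i_p <- sel_p[which.max(evoked[sel_p])]
  peak_amp <- evoked[i_p]
  after <- which(times > times[i_p] & abs(evoked) < return_fraction * abs(peak_amp))
  ret_t <- if (length(after)) times[after[1]] else NA_real_
  data.frame(
    label = c("HbO2_dip", "HbO2_peak", "HbO2_return"),
    latency = c(times[i_d], times[i_p], ret_t),
    amplitude = c(evoked[i_d], peak_amp, NA_real_),
    degenerate = degenerate,
    stringsAsFactors = FALSE
  )
}
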