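#' EMG processing configuration
#'
#' The processing recipe is: high-pass filter, demean, full-wave rectify,
#' low-pass filter at a cutoff tied to the gait-cycle period, then (across
#' trials) normalise each channel to its maximum over all cycles. The
#' low-pass cutoff is `lowpass_cutoff_scale / tf` Hz so that faster cycles
#' keep proportionally more envelope bandwidth.
#'
#' @param highpass_cutoff high-pass cutoff, Hz (default 40).
#' @param lowpass_cutoff_scale low-pass cutoff in cycles (default 3.5,
#'   applied as `3.5 / tf` Hz for a cycle period of `tf` seconds).
#' @param filter_order Butterworth order (default 4); filters are applied
#'   forward-backward (zero phase) so no group delay is introduced that
#'   would confound the calibrated electromechanical delay.
#' @return list of class `emg_config`.
#' @export
emg_config <- function(highpass_cutoff = 40, lowpass_cutoff_scale = 3.5,
                       filter_order = 4L) {
  if (highpass_cutoff <= 0 || lowpass_cutoff_scale <= 0)
    stop("cutoffs must be positive")
  structure(list(highpass_cutoff = highpass_cutoff,
                 lowpass_cutoff_scale = lowpass_cutoff_scale,
                 filter_order = as.integer(filter_order)),
            class = "emg_config")
}

# Forward-backward Butterworth with odd-reflection edge padding (the
# padding suppresses the start/end transients that plain filtfilt leaves).
.zero_phase_butter <- function(x, cutoff, fs, order, type) {
  bf <- signal::butter(order, cutoff / (fs / 2), type = type)
  x <- as.matrix(x)
  n <- nrow(x)
  pad <- min(n - 1L, as.integer(ceiling(3 * fs / cutoff)))
  apply(x, 2L, function(col) {
    ext <- c(2 * col[1] - rev(col[2:(pad + 1)]),
             col,
             2 * col[n] - rev(col[(n - pad):(n - 1)]))
    signal::filtfilt(bf, ext)[pad + seq_len(n)]
  })
}

#' Process raw EMG into muscle excitations
#'
#' High-pass filter (zero-phase Butterworth), demean, full-wave rectify,
#' low-pass filter at `lowpass_cutoff_scale / tf` Hz. Small negative values
#' produced by low-pass ringing are clipped to zero so the output can feed
#' the activation dynamics, which expects excitations in `[0, 1]` after
#' normalisation.
#'
#' @param raw numeric matrix, samples x channels, volts.
#' @param fs sampling rate, Hz.
#' @param tf gait-cycle period, seconds (sets the low-pass cutoff).
#' @param cfg an [emg_config()].
#' @return matrix of the same shape: non-negative linear envelopes, not yet
#'   normalised (see [normalize_over_trials()]).
#' @export
process_raw_emg <- function(raw, fs, tf, cfg = emg_config()) {
  raw <- as.matrix(raw)
  if (tf <= 0) stop("tf must be positive")
  if (fs <= 2 * cfg$highpass_cutoff)
    stop("sampling rate ", fs, " Hz too low for a ", cfg$highpass_cutoff,
         " Hz high-pass cutoff")
  lp <- cfg$lowpass_cutoff_scale / tf
  if (lp >= fs / 2)
    stop("low-pass cutoff ", signif(lp, 4), " Hz is at or above Nyquist")
  x <- .zero_phase_butter(raw, cfg$highpass_cutoff, fs, cfg$filter_order,
                          "high")
  x <- sweep(as.matrix(x), 2L, colMeans(as.matrix(x)))
  x <- abs(x)
  x <- .zero_phase_butter(x, lp, fs, cfg$filter_order, "low")
  x <- as.matrix(x)
  x[x < 0] <- 0
  dimnames(x) <- dimnames(raw)
  x
}

#' Normalise excitations to per-channel maxima over all trials
#'
#' Each channel is divided by its maximum over all supplied trials, so the
#' global per-channel maximum becomes exactly 1 while relative shape within
#' and across trials is preserved. Channels that are identically zero across
#' all trials are left at zero with a warning.
#'
#' @param traces list of frames x channels matrices (one per trial) with a
#'   common channel ordering.
#' @return list of matrices of the same shapes.
#' @export
normalize_over_trials <- function(traces) {
  if (length(traces) == 0) stop("at least one trial is required")
  traces <- lapply(traces, as.matrix)
  k <- ncol(traces[[1]])
  if (!all(vapply(traces, ncol, integer(1)) == k))
    stop("all trials must have the same number of channels")
  maxima <- Reduce(pmax, lapply(traces, function(m)
    apply(m, 2L, max)))
  zero <- maxima <= 0
  if (any(zero)) {
    nm <- colnames(traces[[1]])
    warning("channel(s) with all-zero signal left unnormalised: ",
            paste(if (is.null(nm)) which(zero) else nm[zero], collapse = ", "))
    maxima[zero] <- 1
  }
  lapply(traces, function(m) sweep(m, 2L, maxima, "/"))
}
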