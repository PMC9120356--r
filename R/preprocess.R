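#' Band-pass filter specification
#'
#' Sensorimotor rhythms relevant to motor imagery live in the mu (8-12 Hz) and
#' beta (18-26 Hz) bands, so the default pass band is 8-30 Hz with a 5th-order
#' Butterworth design.
#'
#' @param low_hz,high_hz band edges in Hz, `0 < low_hz < high_hz`.
#' @param order filter order (the effective order doubles under zero-phase
#'   forward-backward application).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(low_hz = 8, high_hz = 30, order = 5) {
  if (!(low_hz > 0 && high_hz > low_hz)) stop("need 0 < low_hz < high_hz")
  if (order < 1) stop("`order` must be >= 1")
  structure(list(low_hz = low_hz, high_hz = high_hz, order = order),
            class = "filter_spec")
}

#' Zero-phase Butterworth band-pass filtering
#'
#' Applies the Butterworth band-pass forward and backward (`signal::filtfilt`)
#' so that cue-locked latencies are preserved. The signal is extended by odd
#' reflection at both ends before filtering to suppress edge transients, then
#' trimmed back to its original length.
#'
#' @param x numeric vector, one channel of EEG.
#' @param fs sampling rate in Hz.
#' @param spec a [filter_spec()].
#' @return Filtered signal, same length as `x`.
#' @examples
#' fs <- 250
#' t <- seq(0, 4, by = 1 / fs)
#' y <- bandpass(sin(2 * pi * 15 * t), fs, filter_spec())
#' @export
bandpass <- function(x, fs, spec = filter_spec()) {
  if (!inherits(spec, "filter_spec")) stop("`spec` must be a filter_spec")
  if (spec$high_hz >= fs / 2)
    stop("band edge ", spec$high_hz, " Hz is at or above Nyquist (", fs / 2,
         " Hz)")
  if (anyNA(x) || any(!is.finite(x))) stop("non-finite samples in input")
  n <- length(x)
  if (n <= 3 * spec$order) stop("signal too short for filter order")
  bf <- signal::butter(spec$order, c(spec$low_hz, spec$high_hz) / (fs / 2),
                       type = "pass")
  x <- x - mean(x)   # the pass band excludes DC; removing it up front keeps
                     # the numerical residual of filtfilt at machine level
  npad <- min(n - 1, max(3 * spec$order, round(fs)))
  left <- 2 * x[1] - x[(npad + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - npad)]
  y <- signal::filtfilt(bf, c(left, x, right))
  y[(npad + 1):(npad + n)]
}

bandpass_trials <- function(ts, spec = filter_spec()) {
  d <- dim(ts$data)
  out <- ts$data
  for (i in seq_len(d[1]))
    for (j in seq_len(d[2]))
      out[i, j, ] <- bandpass(ts$data[i, j, ], ts$fs, spec)
  trial_set(out, if (is.null(ts$labels)) NULL else as.character(ts$labels),
            ts$fs, ts$channels)
}

#' Extract a cue-locked epoch from a continuous recording
#'
#' Sample indexing is 0-based and the window is half-open, so a window of
#' `(start_s, end_s)` yields exactly `round((end_s - start_s) * fs)` samples
#' per channel: e.g. a 0.5-3 s window at 128 Hz gives 320 samples and a 0-4 s
#' window at 250 Hz gives 1000 samples.
#'
#' @param continuous channel x sample numeric matrix.
#' @param fs sampling rate in Hz.
#' @param cue_s cue onset in seconds from the start of the recording.
#' @param window length-2 numeric, `(start_s, end_s)` relative to the cue.
#' @return channel x sample matrix of the epoch.
#' @export
extract_epoch <- function(continuous, fs, cue_s, window) {
  if (!is.matrix(continuous)) stop("`continuous` must be a channel x sample matrix")
  if (length(window) != 2L || window[1] >= window[2])
    stop("empty or inverted epoch window")
  i0 <- round((cue_s + window[1]) * fs)        # 0-based, inclusive
  nsmp <- round((window[2] - window[1]) * fs)  # half-open [i0, i0 + nsmp)
  if (i0 < 0 || i0 + nsmp > ncol(continuous))
    stop("epoch window [", i0, ", ", i0 + nsmp, ") exceeds the recording (",
         ncol(continuous), " samples)")
  continuous[, (i0 + 1):(i0 + nsmp), drop = FALSE]
}
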