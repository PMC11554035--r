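#' On-demand ECG preprocessing
#'
#' The cleaning applied to raw recordings before evaluation or detection:
#' mains interference is removed with a 4th-order Butterworth band-stop
#' (notch) centred on 50 Hz, and DC drift with a 4th-order 0.1 Hz Butterworth
#' highpass. Both are applied forward-backward (zero phase), so R-peak
#' positions are not shifted and the output length equals the input length.
#'
#' @param samples Numeric ECG series.
#' @param fs Sampling rate (samples/sec), `> 100`.
#' @param notch_hz Mains frequency to notch out (default 50).
#' @param notch_halfwidth Half-width of the stop band in Hz (default 2).
#' @param highpass_hz Highpass corner frequency in Hz (default 0.1).
#' @return Filtered series, same length as the input. When `fs` does not
#'   satisfy the Nyquist condition for the notch (`fs <= 2 * notch_hz`) the
#'   notch is skipped with a warning and only the highpass is applied.
#' @export
preprocess_ecg <- function(samples, fs, notch_hz = 50, notch_halfwidth = 2,
                           highpass_hz = 0.1) {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 100) {
    stop("`fs` must be a single number > 100")
  }
  out <- samples
  if (fs <= 2 * notch_hz) {
    warning(sprintf(
      "fs = %g cannot represent %g Hz: notch skipped, highpass only", fs,
      notch_hz))
  } else {
    band <- c(notch_hz - notch_halfwidth, notch_hz + notch_halfwidth) / (fs / 2)
    bs <- signal::butter(2, band, type = "stop")  # 2nd-order design, 4 poles
    out <- signal::filtfilt(bs, out)
  }
  hp <- signal::butter(4, highpass_hz / (fs / 2), type = "high")
  out <- signal::filtfilt(hp, out)
  stopifnot(length(out) == length(samples))
  out
}

# Zero-phase Butterworth bandpass used by the detectors.
bandpass <- function(x, fs, low, high, order = 2) {
  high <- min(high, 0.99 * fs / 2)
  bp <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  signal::filtfilt(bp, x)
}

# Zero-phase Butterworth lowpass.
lowpass <- function(x, fs, cutoff, order = 2) {
  lp <- signal::butter(order, min(cutoff, 0.99 * fs / 2) / (fs / 2),
                       type = "low")
  signal::filtfilt(lp, x)
}
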