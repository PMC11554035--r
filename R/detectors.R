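#' @name detectors
#' @title Reference QRS detectors
#'
#' @description
#' A registry of real-time-capable QRS detectors with a uniform contract: a
#' registered detector is a pure function of `(samples, fs)` returning
#' sorted, de-duplicated 0-based sample indices marking R-peak estimates.
#' Constant detection latencies are permitted — they are removed downstream
#' by the median delay correction — but jitter is the detector's own.
#'
#' Fully implemented: `matched_filter`, `pan_tompkins`, `engzee`, `wqrs`,
#' `elgendi`. Registered with documented contracts but not implemented here
#' (each is implementable from its original publication): `kalidas_tamil`
#' (stationary-wavelet-transform filtering ahead of Pan-Tompkins-style
#' thresholding), `christov` (adaptive steep-slope/integrating thresholds on
#' a combined lead), `hamilton` (Pan-Tompkins derivative with an added
#' decision-rule set; a `variant` parameter distinguishes the full and the
#' stripped-down microcontroller rule set).
#'
#' All implemented detectors use only relative (adaptive) thresholds, so
#' detections are invariant under positive rescaling of the input, and all
#' apply a 0.2 s refractory period (a 300 bpm physiological rate ceiling).
NULL

.detector_registry <- new.env(parent = emptyenv())

#' Register a detector
#'
#' Adds (or replaces) a detector in the registry. The function must accept
#' `(samples, fs, ...)` and return integer 0-based sample indices, sorted
#' ascending.
#'
#' @param name Detector name.
#' @param fun Detector function, or `NULL` for a declared-but-unimplemented
#'   stub.
#' @param description One-line description.
#' @param params Named list of default parameters (documentation only;
#'   passed through `...` of [detect()]).
#' @return Invisibly, the registry entry.
#' @export
register_detector <- function(name, fun, description = "", params = list()) {
  entry <- list(name = name, fun = fun, implemented = !is.null(fun),
                description = description, params = params)
  assign(name, entry, envir = .detector_registry)
  invisible(entry)
}

#' List registered detectors
#'
#' @param implemented_only If `TRUE`, only detectors with an implementation.
#' @return Data frame with columns `name`, `implemented`, `description`.
#' @export
list_detectors <- function(implemented_only = FALSE) {
  entries <- lapply(sort(ls(.detector_registry)), get,
                    envir = .detector_registry)
  df <- data.frame(
    name = vapply(entries, `[[`, "", "name"),
    implemented = vapply(entries, `[[`, TRUE, "implemented"),
    description = vapply(entries, `[[`, "", "description"),
    stringsAsFactors = FALSE
  )
  if (implemented_only) df[df$implemented, , drop = FALSE] else df
}

get_detector <- function(name) {
  if (!exists(name, envir = .detector_registry)) {
    stop(sprintf("unknown detector '%s'; see list_detectors()", name))
  }
  get(name, envir = .detector_registry)
}

#' Run a detector on a record
#'
#' Uniform wrapper around the registry: validates the input, handles the
#' degenerate flat-line case (no energy, no beats), runs the named detector
#' and returns its output as a [detection_set()].
#'
#' @param detector Detector name (see [list_detectors()]).
#' @param samples Numeric ECG series, or an [annotated_record()].
#' @param fs Sampling rate (samples/sec), within `[100, 1000]`; taken from
#'   the record if one is given.
#' @param ... Detector-specific parameters.
#' @param warmup Minimum record length in seconds (default 2); shorter
#'   records error.
#' @return A [detection_set()] with `detector_name = detector`.
#' @examples
#' rec <- generate_record(duration = 30, seed = 7)
#' d <- detect("matched_filter", rec)
#' evaluate_record(rec, d)
#' @export
detect <- function(detector, samples, fs = NULL, ..., warmup = 2) {
  if (inherits(samples, "annotated_record")) {
    fs <- samples$fs
    samples <- samples$samples
  }
  samples <- as.numeric(samples)
  if (is.null(fs)) stop("`fs` is required when `samples` is a bare vector")
  if (fs < 100 || fs > 1000) {
    stop("`fs` must lie within [100, 1000] samples/sec")
  }
  if (length(samples) < warmup * fs) {
    stop(sprintf("record shorter than the %g s detector warm-up", warmup))
  }
  entry <- get_detector(detector)
  if (!entry$implemented) {
    stop(sprintf(
      "detector '%s' is registered but not implemented: %s",
      detector, entry$description))
  }
  if (max(samples) - min(samples) == 0) {
    return(detection_set(integer(0), detector_name = detector))
  }
  idx <- entry$fun(samples, fs, ...)
  idx <- sort(unique(as.integer(idx)))
  idx <- idx[idx >= 0 & idx < length(samples)]
  detection_set(idx, detector_name = detector)
}

# ---- shared detector machinery ------------------------------------------

# Local maxima of x honouring a minimum peak separation: taller peaks win.
local_maxima <- function(x, min_dist = 1L) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (length(cand) == 0L || min_dist <= 1L) return(cand)
  ord <- cand[order(x[cand], decreasing = TRUE)]
  keep <- logical(n)
  blocked <- logical(n)
  for (i in ord) {
    if (!blocked[i]) {
      keep[i] <- TRUE
      lo <- max(1L, i - min_dist); hi <- min(n, i + min_dist)
      blocked[lo:hi] <- TRUE
    }
  }
  which(keep)
}

# Generic adaptive-threshold beat picker over a non-negative feature signal.
# Running signal-peak estimate spk; a candidate peak is accepted when it
# exceeds frac * spk and lies beyond the refractory period. All quantities
# are relative to the signal's own scale.
pick_beats <- function(feature, fs, refractory = 0.2, frac = 0.35,
                       update = 0.125) {
  cand <- local_maxima(feature, min_dist = max(1L, round(0.06 * fs)))
  if (length(cand) == 0L) return(integer(0))
  h <- feature[cand]
  # initialise the running peak estimate from heights that must be beats:
  # at any physiological rate there is at least one beat per 2 s, so the
  # median of the top duration/2 candidate heights tracks the QRS level
  k <- max(1L, min(length(h), as.integer(length(feature) / fs / 2)))
  spk <- stats::median(sort(h, decreasing = TRUE)[seq_len(k)])
  if (spk <= 0) return(integer(0))
  out <- integer(0)
  last <- -Inf
  for (j in seq_along(cand)) {
    if (h[j] > frac * spk && (cand[j] - last) >= refractory * fs) {
      out <- c(out, cand[j])
      last <- cand[j]
      spk <- update * h[j] + (1 - update) * spk
    }
  }
  out
}

# Snap a trigger index to the nearest dominant deflection of the reference
# signal within an asymmetric window (samples, 1-based in/out).
refine_peak <- function(ref, idx, fs, before = 0.10, after = 0.10,
                        use_abs = TRUE) {
  n <- length(ref)
  vapply(as.integer(idx), function(i) {
    lo <- max(1L, i - as.integer(round(before * fs)))
    hi <- min(n, i + as.integer(round(after * fs)))
    seg <- ref[lo:hi]
    if (use_abs) seg <- abs(seg)
    lo + which.max(seg) - 1L
  }, integer(1))
}

# Causal moving sum with zero-padded start.
moving_sum <- function(x, width) {
  cs <- cumsum(c(rep(0, width), x))
  cs[(width + 1):length(cs)] - cs[1:(length(cs) - width)]
}

# ---- matched filter ------------------------------------------------------

#' Default matched-filter QRS template
#'
#' The QRS portion (+/- 60 ms around the R-peak) of the synthetic
#' Einthoven-like beat template, generated analytically rather than learned
#' from any recording, so matched filtering is reproducible without training
#' data.
#'
#' @param fs Sampling rate (samples/sec).
#' @param morphology Template morphology, as in [beat_model()].
#' @return Numeric template vector.
#' @export
default_qrs_template <- function(fs, morphology = "einthoven_like") {
  tm <- beat_template(beat_model(morphology), fs)
  half <- round(0.06 * fs)
  lo <- tm$r_offset + 1L - half
  hi <- tm$r_offset + 1L + half
  tm$wave[max(1L, lo):min(length(tm$wave), hi)]
}

#' Matched filter QRS detector
#'
#' Band-passes the ECG, cross-correlates it with a time-reversed QRS
#' template, squares the correlator output, and picks local maxima above an
#' adaptive threshold (a fraction of a running peak-amplitude estimate) with
#' a 0.2 s refractory period. Detections are snapped to the dominant
#' deflection of the band-passed signal. The threshold is relative, so the
#' detector is invariant to amplitude scaling of the input.
#'
#' @param samples Numeric ECG series.
#' @param fs Sampling rate (samples/sec).
#' @param template QRS template; defaults to [default_qrs_template()].
#' @param band Passband in Hz (default `c(5, 35)`).
#' @param frac Threshold fraction of the running peak estimate.
#' @return Integer 0-based detection indices (used via [detect()]).
#' @export
matched_filter_detect <- function(samples, fs,
                                  template = default_qrs_template(fs),
                                  band = c(5, 35), frac = 0.35) {
  if (all(template == 0)) stop("matched filter template must not be all zero")
  bp <- bandpass(samples, fs, band[1], band[2])
  mf <- signal::filter(rev(template), 1, bp)
  sq <- as.numeric(mf)^2
  trig <- pick_beats(sq, fs, frac = frac)
  # correlator peak lags the R-peak by (template length - 1 - r position)
  lag <- length(template) - 1L - (which.max(abs(template)) - 1L)
  trig <- pmax(1L, trig - lag)
  r <- refine_peak(bp, trig, fs, before = 0.06, after = 0.06)
  r - 1L
}

# ---- Pan-Tompkins --------------------------------------------------------

#' Pan-Tompkins QRS detector
#'
#' The classic real-time detection chain: 5-15 Hz bandpass, five-point
#' derivative, squaring, 150 ms moving-window integration, then adaptive
#' dual thresholds on the integrated signal with running signal/noise peak
#' estimates, a 0.2 s refractory period, and a search-back pass that rescans
#' with half the threshold whenever the gap since the last beat exceeds 1.66
#' times the running RR average. Marks are snapped to the dominant
#' deflection of the band-passed signal.
#'
#' @inheritParams matched_filter_detect
#' @param mwi_width Moving-window integrator width in seconds (default
#'   0.15).
#' @return Integer 0-based detection indices (used via [detect()]).
#' @export
pan_tompkins_detect <- function(samples, fs, mwi_width = 0.15) {
  bp <- bandpass(samples, fs, 5, 15)
  der <- as.numeric(signal::filter(c(1, 2, 0, -2, -1) / 8, 1, bp))
  sq <- der^2
  w <- max(1L, round(mwi_width * fs))
  mwi <- moving_sum(sq, w) / w

  cand <- local_maxima(mwi, min_dist = max(1L, round(0.06 * fs)))
  if (length(cand) == 0L) return(integer(0))
  h <- mwi[cand]

  init <- mwi[seq_len(min(length(mwi), round(2 * fs)))]
  spk <- max(init) * 0.6
  npk <- mean(init) * 0.5
  thr <- function() npk + 0.25 * (spk - npk)

  beats <- integer(0)
  rr_hist <- numeric(0)
  last <- NA_integer_
  refr <- round(0.2 * fs)
  pending <- integer(0)  # sub-threshold candidates since the last beat

  for (j in seq_along(cand)) {
    i <- cand[j]; hi <- h[j]
    # search-back: long gap since the last beat -> rescan pending peaks
    if (!is.na(last) && length(rr_hist) >= 2L) {
      rr_avg <- mean(utils::tail(rr_hist, 8))
      if ((i - last) > 1.66 * rr_avg && length(pending)) {
        sb <- pending[mwi[pending] > 0.5 * thr() &
                        mwi[pending] > 3 * npk & (pending - last) > refr]
        if (length(sb)) {
          k <- sb[which.max(mwi[sb])]
          rr_hist <- c(rr_hist, k - last)
          beats <- c(beats, k)
          spk <- 0.25 * mwi[k] + 0.75 * spk
          last <- k
          pending <- pending[pending > k]
        }
      }
    }
    # a QRS must clear the adaptive threshold and stand well above the
    # running noise-peak level: in the squared/integrated domain real
    # complexes sit far above noise peaks, which keeps a signal-free
    # record from triggering at the refractory rate
    if (hi > thr() && hi > 3 * npk &&
        (is.na(last) || (i - last) >= refr)) {
      if (!is.na(last)) rr_hist <- c(rr_hist, i - last)
      beats <- c(beats, i)
      spk <- 0.125 * hi + 0.875 * spk
      last <- i
      pending <- integer(0)
    } else {
      npk <- 0.125 * hi + 0.875 * npk
      pending <- c(pending, i)
    }
  }
  if (length(beats) == 0L) return(integer(0))
  # the integrator peak trails the R-peak by roughly half its width plus the
  # derivative delay; search backwards for the underlying deflection
  r <- refine_peak(bp, beats, fs, before = mwi_width + 0.05, after = 0.05)
  r - 1L
}

# ---- EngZee --------------------------------------------------------------

#' EngZee QRS detector (real-time variant)
#'
#' Differentiates the ECG (`y[n] = x[n] - x[n-4]`), smooths with the
#' four-fold binomial lowpass `(1, 4, 6, 4, 1)`, and thresholds the
#' rectified slope signal adaptively (fraction of a running peak estimate,
#' 0.2 s refractory). Each threshold crossing is resolved to the local
#' extremum of the band-passed ECG in a short surrounding window, per the
#' real-time adaptive-threshold formulation of the original
#' derivative-based detector.
#'
#' @inheritParams matched_filter_detect
#' @return Integer 0-based detection indices (used via [detect()]).
#' @export
engzee_detect <- function(samples, fs, frac = 0.4) {
  # remove baseline so the differentiator sees only the ECG
  x <- bandpass(samples, fs, 1, min(40, 0.45 * fs))
  d <- as.numeric(signal::filter(c(1, 0, 0, 0, -1), 1, x))
  sm <- as.numeric(signal::filter(c(1, 4, 6, 4, 1) / 16, 1, d))
  feat <- sm^2
  trig <- pick_beats(feat, fs, frac = frac)
  if (length(trig) == 0L) return(integer(0))
  r <- refine_peak(x, trig, fs, before = 0.08, after = 0.08)
  r - 1L
}

# ---- WQRS ----------------------------------------------------------------

#' WQRS curve-length QRS detector
#'
#' Lowpass-filters the ECG at 16 Hz, computes the curve-length transform (a
#' rolling sum, over a 130 ms window, of `sqrt(c^2 + dy^2)` where `dy` is
#' the first difference and `c` a scale constant proportional to the
#' signal's own median slope, keeping the transform amplitude-invariant),
#' and applies the adaptive peak picker to the baseline-removed length
#' signal. Length-transform peaks are snapped to the dominant deflection of
#' a 5-30 Hz band-passed copy.
#'
#' @inheritParams matched_filter_detect
#' @param window Curve-length window in seconds (default 0.13).
#' @return Integer 0-based detection indices (used via [detect()]).
#' @export
wqrs_detect <- function(samples, fs, window = 0.13, frac = 0.35) {
  lp <- lowpass(samples, fs, 16)
  dy <- diff(lp)
  cscale <- stats::median(abs(dy))
  if (cscale == 0) cscale <- max(abs(dy))
  if (cscale == 0) return(integer(0))
  seg <- sqrt((4 * cscale)^2 + dy^2)
  w <- max(2L, round(window * fs))
  len <- moving_sum(seg, w)
  feat <- pmax(len - stats::median(len), 0)
  trig <- pick_beats(feat, fs, frac = frac)
  if (length(trig) == 0L) return(integer(0))
  bp <- bandpass(samples, fs, 5, 30)
  r <- refine_peak(bp, trig, fs, before = window + 0.04, after = 0.05)
  r - 1L
}

# ---- Elgendi -------------------------------------------------------------

#' Elgendi two-moving-average QRS detector
#'
#' Band-passes at the 8-20 Hz band, squares, and compares a short
#' moving average (QRS-scale, 120 ms) against a long one (beat-scale,
#' 610 ms) plus an offset proportional to the mean squared signal. Runs of
#' samples where the short average exceeds this dynamic threshold form
#' blocks of interest; blocks at least one QRS wide yield a beat at the
#' dominant deflection of the band-passed signal, subject to the 0.2 s
#' refractory period.
#'
#' @inheritParams matched_filter_detect
#' @param w_qrs,w_beat Short/long moving-average windows in seconds.
#' @param beta Offset coefficient on the mean squared signal (default 0.08).
#' @return Integer 0-based detection indices (used via [detect()]).
#' @export
elgendi_detect <- function(samples, fs, w_qrs = 0.12, w_beat = 0.61,
                           beta = 0.08) {
  bp <- bandpass(samples, fs, 8, 20)
  sq <- pmax(bp, 0)^2
  n1 <- max(1L, as.integer(round(w_qrs * fs)))
  n2 <- max(n1 + 1L, as.integer(round(w_beat * fs)))
  ma_qrs <- moving_sum(sq, n1) / n1
  ma_beat <- moving_sum(sq, n2) / n2
  thr <- ma_beat + beta * mean(sq)
  on <- ma_qrs > thr
  # contiguous blocks of interest
  rl <- rle(on)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  blocks <- which(rl$values & rl$lengths >= n1)
  if (length(blocks) == 0L) return(integer(0))
  # causal moving averages trail the waveform; look slightly before the block
  r <- vapply(blocks, function(b) {
    lo <- max(1L, as.integer(starts[b]) - n1)
    hi <- min(length(bp), as.integer(ends[b]))
    lo + which.max(abs(bp[lo:hi])) - 1L
  }, integer(1))
  r <- sort(r)
  # refractory dedupe, earlier beat wins
  keep <- c(TRUE, diff(r) >= 0.2 * fs)
  r[keep] - 1L
}

# ---- registry ------------------------------------------------------------

register_builtin_detectors <- function() {
  register_detector("matched_filter", matched_filter_detect,
    "Template cross-correlation with adaptive threshold",
    params = list(band = c(5, 35), frac = 0.35))
  register_detector("pan_tompkins", pan_tompkins_detect,
    "Bandpass/derivative/square/integrate with adaptive dual thresholds",
    params = list(mwi_width = 0.15))
  register_detector("engzee", engzee_detect,
    "Differentiated ECG with adaptive threshold and extremum search",
    params = list(frac = 0.4))
  register_detector("wqrs", wqrs_detect,
    "Curve-length transform detector",
    params = list(window = 0.13, frac = 0.35))
  register_detector("elgendi", elgendi_detect,
    "Two-moving-average blocks of interest on the 8-20 Hz band",
    params = list(w_qrs = 0.12, w_beat = 0.61, beta = 0.08))
  register_detector("kalidas_tamil", NULL,
    "Stationary wavelet transform filtering + adaptive thresholding (stub)")
  register_detector("christov", NULL,
    "Adaptive steep-slope and integrating thresholds on a combined lead (stub)")
  register_detector("hamilton", NULL,
    paste("Pan-Tompkins derivative plus decision rules; `variant` selects the",
          "full or stripped-down rule set (stub)"))
}
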