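#' Beat morphology model
#'
#' Parametric single-beat template used by the synthetic record generator.
#' Two morphologies are provided, emulating the best/worst-case recording
#' setups of ambulatory ECG studies: `"einthoven_like"` (limb-lead style:
#' broader QRS, pronounced P and T waves) and `"chest_strap_like"` (V1-V2
#' difference style: narrower, taller R, deeper S, flatter P). The analytic
#' shapes are sums of Gaussian deflections; the R deflection is always the
#' global absolute maximum of the beat so the template peak defines the
#' ground-truth annotation exactly.
#'
#' @param morphology `"einthoven_like"` or `"chest_strap_like"`.
#' @param qrs_width Total QRS duration in seconds (default 0.08).
#' @param p_amp,r_amp,s_amp,t_amp Deflection amplitudes relative to the
#'   R-peak amplitude of 1 (defaults depend on morphology).
#' @param rr_mean Mean RR interval in seconds (default 1.0, i.e. 60 bpm).
#' @param rr_sd RR interval standard deviation in seconds, the heart-rate
#'   variability spread (default 0.05).
#' @return Object of class `beat_model`.
#' @export
beat_model <- function(morphology = c("einthoven_like", "chest_strap_like"),
                       qrs_width = 0.08,
                       p_amp = NULL, r_amp = NULL, s_amp = NULL, t_amp = NULL,
                       rr_mean = 1.0, rr_sd = 0.05) {
  morphology <- match.arg(morphology)
  defaults <- switch(morphology,
    einthoven_like  = list(p_amp = 0.15, r_amp = 1.0, s_amp = -0.25,
                           t_amp = 0.30),
    chest_strap_like = list(p_amp = 0.06, r_amp = 1.3, s_amp = -0.55,
                            t_amp = 0.20)
  )
  p_amp <- if (is.null(p_amp)) defaults$p_amp else p_amp
  r_amp <- if (is.null(r_amp)) defaults$r_amp else r_amp
  s_amp <- if (is.null(s_amp)) defaults$s_amp else s_amp
  t_amp <- if (is.null(t_amp)) defaults$t_amp else t_amp
  if (qrs_width <= 0) stop("`qrs_width` must be positive")
  if (rr_mean <= 2 * qrs_width) stop("`rr_mean` must exceed 2 * qrs_width")
  if (rr_sd < 0) stop("`rr_sd` must be non-negative")
  if (abs(r_amp) <= max(abs(p_amp), abs(s_amp), abs(t_amp))) {
    stop("the R deflection must dominate the beat (|r_amp| largest)")
  }
  structure(
    list(morphology = morphology, qrs_width = qrs_width,
         p_amp = p_amp, r_amp = r_amp, s_amp = s_amp, t_amp = t_amp,
         rr_mean = rr_mean, rr_sd = rr_sd),
    class = "beat_model"
  )
}

#' Single-beat template waveform
#'
#' Samples the analytic beat shape of a [beat_model()] on the sampling grid.
#' Offset 0 of the returned template is the R-peak sample and is guaranteed
#' to carry the maximum absolute amplitude.
#'
#' @param beat A [beat_model()].
#' @param fs Sampling rate (samples/sec); must resolve the QRS with at least
#'   4 samples.
#' @return List with `wave` (numeric vector) and `r_offset` (0-based offset
#'   of the R-peak within `wave`).
#' @export
beat_template <- function(beat, fs) {
  stopifnot(inherits(beat, "beat_model"))
  if (beat$qrs_width * fs < 4) {
    stop(sprintf("fs = %g too low to represent a %.0f ms QRS (< 4 samples)",
                 fs, 1000 * beat$qrs_width))
  }
  narrow <- beat$morphology == "chest_strap_like"
  r_sd <- beat$qrs_width / (if (narrow) 9 else 7)
  s_sd <- beat$qrs_width / (if (narrow) 10 else 8)
  pre <- as.integer(round(0.30 * fs)); post <- as.integer(round(0.45 * fs))
  t <- (-pre:post) / fs
  g <- function(amp, mu, sd) amp * exp(-0.5 * ((t - mu) / sd)^2)
  wave <- g(beat$p_amp, -0.17, 0.025) +                    # P
    g(-0.12 * abs(beat$r_amp), -0.6 * beat$qrs_width / 2, s_sd) +  # Q
    g(beat$r_amp, 0, r_sd) +                               # R
    g(beat$s_amp, 0.6 * beat$qrs_width / 2, s_sd) +        # S
    g(beat$t_amp, 0.25, 0.05)                              # T
  # place the true extremum exactly on the grid point at t = 0
  stopifnot(which.max(abs(wave)) == pre + 1L)
  list(wave = wave, r_offset = pre)
}

#' Noise regime specification
#'
#' Defines the additive noise mixture of one rung of the activity ladder.
#' The five activity regimes emulate recordings of a subject sitting,
#' doing a maths test on a tablet, walking, operating a hand-bike and
#' jogging: successive rungs add strictly more total noise power. Component
#' amplitudes are expressed relative to the R-peak amplitude and are
#' calibration constants of the generator, not measurements of any
#' particular hardware.
#'
#' Components: `broadband_emg` (white Gaussian muscle noise, amplitude =
#' RMS), `baseline_wander` (sub-Hz sinusoid mixture, amplitude = peak),
#' `powerline_50hz` (mains sinusoid, amplitude = peak), `step_artefact`
#' (random sudden baseline shifts with exponential recovery; amplitude =
#' typical step height, with a fixed event rate of 0.08/s).
#'
#' @param regime One of `"none"`, `"sitting"`, `"maths"`, `"walking"`,
#'   `"handbike"`, `"jogging"`, or `"custom"` (then `components` must be
#'   given).
#' @param components Optional named numeric vector of component amplitudes
#'   (names among `broadband_emg`, `baseline_wander`, `powerline_50hz`,
#'   `step_artefact`) overriding the regime preset.
#' @return Object of class `noise_spec`.
#' @examples
#' noise_spec("jogging")
#' noise_spec("custom", c(broadband_emg = 0.1))
#' @export
noise_spec <- function(regime = c("none", "sitting", "maths", "walking",
                                  "handbike", "jogging", "custom"),
                       components = NULL) {
  regime <- match.arg(regime)
  presets <- list(
    none     = c(broadband_emg = 0,    baseline_wander = 0,
                 powerline_50hz = 0,    step_artefact = 0),
    sitting  = c(broadband_emg = 0.02, baseline_wander = 0.05,
                 powerline_50hz = 0.01, step_artefact = 0),
    maths    = c(broadband_emg = 0.06, baseline_wander = 0.12,
                 powerline_50hz = 0.02, step_artefact = 0.15),
    walking  = c(broadband_emg = 0.15, baseline_wander = 0.35,
                 powerline_50hz = 0.02, step_artefact = 0.5),
    handbike = c(broadband_emg = 0.22, baseline_wander = 0.50,
                 powerline_50hz = 0.03, step_artefact = 0.8),
    jogging  = c(broadband_emg = 0.33, baseline_wander = 0.80,
                 powerline_50hz = 0.03, step_artefact = 1.4)
  )
  comp <- if (regime == "custom") {
    if (is.null(components)) stop("`components` required for regime 'custom'")
    presets$none
  } else presets[[regime]]
  if (!is.null(components)) {
    bad <- setdiff(names(components), names(comp))
    if (length(bad)) stop("unknown noise components: ",
                          paste(bad, collapse = ", "))
    comp[names(components)] <- components
  }
  if (any(comp < 0)) stop("noise amplitudes must be non-negative")
  structure(list(regime = regime, components = comp), class = "noise_spec")
}

#' Ordered activity ladder
#'
#' The five activity regimes in order of increasing noise power.
#' @return Character vector.
#' @export
noise_ladder <- function() {
  c("sitting", "maths", "walking", "handbike", "jogging")
}

#' Generate a synthetic annotated ECG record
#'
#' Builds a record by placing single-beat templates ([beat_template()]) at RR
#' intervals drawn from a truncated normal distribution (truncated at +/- 3
#' SD and floored at 0.25 s so beats never overlap), then adding the additive
#' noise mixture of a [noise_spec()]. The ground-truth annotation of every
#' beat is the exact sample of its R-peak. Generation is fully seeded: the
#' same seed reproduces the identical record bit for bit.
#'
#' @param beat A [beat_model()] (default: Einthoven-like at 60 bpm).
#' @param noise A [noise_spec()] or regime name (default `"none"`).
#' @param duration Record length in seconds (default 120, `>= 10`).
#' @param fs Sampling rate in samples/sec (default 250).
#' @param seed Integer seed; required, reproducibility is mandatory.
#' @param label Record label (default describes morphology/regime/seed).
#' @return An [annotated_record()] with `meta$morphology`, `meta$regime`,
#'   `meta$seed`, and `meta$snr_db` (R-peak power over noise power; `Inf`
#'   for the noise-free regime).
#' @examples
#' rec <- generate_record(noise = "sitting", duration = 30, seed = 1)
#' rec
#' @export
generate_record <- function(beat = beat_model(), noise = "none",
                            duration = 120, fs = 250, seed,
                            label = NULL) {
  stopifnot(inherits(beat, "beat_model"))
  if (is.character(noise)) noise <- noise_spec(noise)
  stopifnot(inherits(noise, "noise_spec"))
  if (duration < 10) stop("`duration` must be at least 10 seconds")
  if (missing(seed) || is.null(seed)) stop("`seed` is required")
  tmpl <- beat_template(beat, fs)  # errors if fs cannot resolve the QRS

  local_seed(seed)
  n <- round(duration * fs)

  # beat placement on a truncated-normal RR grid
  r_times <- numeric(0)
  t_cur <- 0.5
  end_margin <- duration - 0.5
  while (t_cur <= end_margin) {
    r_times <- c(r_times, t_cur)
    rr <- if (beat$rr_sd > 0) {
      x <- stats::rnorm(1, beat$rr_mean, beat$rr_sd)
      x <- min(max(x, beat$rr_mean - 3 * beat$rr_sd),
               beat$rr_mean + 3 * beat$rr_sd)
      max(x, 0.25)
    } else beat$rr_mean
    t_cur <- t_cur + rr
  }
  r_idx <- round(r_times * fs)          # 0-based annotation samples

  samples <- numeric(n)
  wave <- tmpl$wave
  for (r in r_idx) {
    lo <- r - tmpl$r_offset             # 0-based start of template
    idx <- seq.int(lo, lo + length(wave) - 1L)
    ok <- idx >= 0L & idx < n
    samples[idx[ok] + 1L] <- samples[idx[ok] + 1L] + wave[ok]
  }

  r_peak <- abs(beat$r_amp)
  amps <- noise$components * r_peak
  t <- (0:(n - 1)) / fs
  noise_sig <- numeric(n)
  if (amps[["broadband_emg"]] > 0) {
    noise_sig <- noise_sig + stats::rnorm(n, 0, amps[["broadband_emg"]])
  }
  if (amps[["baseline_wander"]] > 0) {
    f <- stats::runif(3, 0.05, 0.45)
    ph <- stats::runif(3, 0, 2 * pi)
    w <- c(1, 0.5, 0.3)
    bw <- Reduce(`+`, lapply(1:3, function(i) w[i] * sin(2 * pi * f[i] * t + ph[i])))
    noise_sig <- noise_sig + amps[["baseline_wander"]] * bw / sum(w)
  }
  if (amps[["powerline_50hz"]] > 0) {
    noise_sig <- noise_sig +
      amps[["powerline_50hz"]] * sin(2 * pi * 50 * t + stats::runif(1, 0, 2 * pi))
  }
  if (amps[["step_artefact"]] > 0) {
    n_steps <- stats::rpois(1, 0.08 * duration)
    if (n_steps > 0) {
      at <- sort(stats::runif(n_steps, 0, duration))
      for (s_t in at) {
        h <- amps[["step_artefact"]] * stats::runif(1, 0.5, 1.5) *
          sample(c(-1, 1), 1)
        tau <- stats::runif(1, 0.5, 1.5)
        rel <- t - s_t
        noise_sig <- noise_sig + ifelse(rel >= 0, h * exp(-rel / tau), 0)
      }
    }
  }

  snr_db <- if (all(amps == 0)) Inf else {
    10 * log10(r_peak^2 / mean(noise_sig^2))
  }

  if (is.null(label)) {
    label <- sprintf("%s_%s_seed%d", beat$morphology, noise$regime, seed)
  }
  annotated_record(samples + noise_sig, fs, r_idx, label = label,
                   meta = list(morphology = beat$morphology,
                               regime = noise$regime, seed = seed,
                               snr_db = snr_db))
}

#' Corruption specification for detection streams
#'
#' Describes a controlled error structure imposed on a perfect detection
#' stream, used to validate the metric chain against known ground truth:
#' beats deleted at a fixed probability, spurious detections inserted as a
#' Poisson process, Gaussian timing jitter, and a constant delay.
#'
#' @param delete_prob Probability a true beat is dropped, in `[0, 1)`.
#' @param insert_rate Spurious detections per second, `>= 0`.
#' @param jitter_sd Standard deviation of Gaussian timing error, seconds.
#' @param constant_delay Constant shift applied to all surviving beats,
#'   seconds.
#' @return Object of class `corruption_spec`.
#' @export
corruption_spec <- function(delete_prob = 0, insert_rate = 0,
                            jitter_sd = 0, constant_delay = 0) {
  if (delete_prob < 0 || delete_prob >= 1) stop("`delete_prob` must be in [0, 1)")
  if (insert_rate < 0) stop("`insert_rate` must be non-negative")
  if (jitter_sd < 0) stop("`jitter_sd` must be non-negative")
  structure(list(delete_prob = delete_prob, insert_rate = insert_rate,
                 jitter_sd = jitter_sd, constant_delay = constant_delay),
            class = "corruption_spec")
}

#' Corrupt a perfect detection stream
#'
#' Applies a [corruption_spec()] to ground-truth annotations: each beat is
#' independently deleted with `delete_prob`; survivors are shifted by
#' `constant_delay` plus Gaussian jitter (rounded to integer samples);
#' spurious detections are inserted as a Poisson process at `insert_rate`,
#' kept at least 0.1 s away from every true beat. Output is sorted and
#' de-duplicated. Fully seeded.
#'
#' @param annotations Ground-truth sample indices (or [annotated_record()]);
#'   non-empty.
#' @param spec A [corruption_spec()].
#' @param fs Sampling rate (samples/sec).
#' @param seed Integer seed.
#' @param duration Record duration in seconds used for the insertion
#'   process; defaults to the span of the annotations plus one mean gap.
#' @return A [detection_set()] named `"corrupted_truth"`.
#' @export
corrupt_detections <- function(annotations, spec = corruption_spec(), fs,
                               seed, duration = NULL) {
  a <- as_indices(annotations)
  if (inherits(annotations, "annotated_record")) {
    fs <- annotations$fs
    if (is.null(duration)) duration <- length(annotations$samples) / fs
  }
  if (length(a) == 0L) stop("`annotations` must be non-empty")
  stopifnot(inherits(spec, "corruption_spec"))
  if (missing(seed) || is.null(seed)) stop("`seed` is required")
  if (is.null(duration)) {
    duration <- (max(a) + if (length(a) > 1) mean(diff(a)) else fs) / fs
  }
  local_seed(seed)

  keep <- stats::runif(length(a)) >= spec$delete_prob
  d <- a[keep]
  if (length(d) > 0L) {
    shift <- spec$constant_delay * fs +
      stats::rnorm(length(d), 0, spec$jitter_sd * fs)
    d <- round(d + shift)
  }
  n_ins <- stats::rpois(1, spec$insert_rate * duration)
  if (n_ins > 0L) {
    cand <- round(stats::runif(2 * n_ins + 20L, 0, duration * fs - 1))
    far <- vapply(cand, function(x) min(abs(x - a)) >= 0.1 * fs, logical(1))
    d <- c(d, utils::head(cand[far], n_ins))
  }
  d <- sort(unique(pmax(d, 0)))
  detection_set(d, detector_name = "corrupted_truth")
}

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
local_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single integer")
  }
  env <- parent.frame()
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(as.integer(seed))
  # restore when the *calling* function exits
  expr <- if (is.null(old)) {
    quote(rm(".Random.seed", envir = globalenv()))
  } else {
    bquote(assign(".Random.seed", .(old), envir = globalenv()))
  }
  do.call(on.exit, list(expr, add = TRUE), envir = env)
  invisible(NULL)
}
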