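#' Default temporal tolerance window
#'
#' The widely used fixed tolerance for classic beat-detection scoring is ten
#' sampling intervals, `w = 10 / fs` seconds. At 250 samples/sec this is the
#' familiar 40 ms window.
#'
#' @param fs Sampling rate in samples per second, `> 0`.
#' @return Window half-width in seconds.
#' @examples
#' default_window(250)  # 0.04 s
#' @export
default_window <- function(fs) {
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number")
  }
  10 / fs
}

#' Classic fixed-window confusion counts
#'
#' Scores detections against annotations with a fixed temporal tolerance: an
#' annotation is a true positive if some detection lies within `w` seconds of
#' it, each detection being consumed by at most one annotation (nearest first,
#' ties toward the earlier index). Detections left unconsumed are false
#' positives; annotations left unmatched are false negatives.
#'
#' @param annotations Sample indices of true beats (or an
#'   [annotated_record()]); non-empty, sorted ascending.
#' @param detections Sample indices reported by a detector (or a
#'   [detection_set()]); sorted ascending. May be empty.
#' @param fs Sampling rate (samples/sec).
#' @param w Tolerance window in seconds; defaults to [default_window()].
#' @return Named list with integer fields `tp`, `fp`, `fn`.
#' @examples
#' classic_confusion(c(100, 200, 300), c(100, 204, 310), fs = 250)
#' @export
classic_confusion <- function(annotations, detections, fs,
                              w = default_window(fs)) {
  a <- as_indices(annotations)
  d <- as_indices(detections)
  if (length(a) == 0L) stop("empty annotation list: record unusable")
  if (!is.numeric(w) || length(w) != 1L || w <= 0) {
    stop("`w` must be a single positive number of seconds")
  }
  if (length(d) == 0L) {
    return(list(tp = 0L, fp = 0L, fn = length(a)))
  }
  w_samples <- w * fs
  taken <- rep(FALSE, length(d))
  tp <- 0L
  for (al in a) {
    diffs <- abs(al - d)
    diffs[taken] <- Inf
    k <- which.min(diffs)  # which.min takes the earliest on ties
    if (diffs[k] <= w_samples) {
      taken[k] <- TRUE
      tp <- tp + 1L
    }
  }
  list(tp = tp, fp = length(d) - tp, fn = length(a) - tp)
}

#' Sensitivity and positive predictivity
#'
#' `sensitivity()` is TP / (TP + FN), the fraction of true beats found;
#' `positive_predictivity()` is TP / (TP + FP), the fraction of detections
#' that are true beats. A zero denominator is undefined: the functions warn
#' and return `NA` rather than silently reporting 0.
#'
#' @param tp,fp,fn Non-negative integer counts.
#' @return Fraction in `[0, 1]`, or `NA` with a warning when undefined.
#' @examples
#' sensitivity(tp = 9, fn = 1)            # 0.9
#' positive_predictivity(tp = 2, fp = 1)  # 2/3
#' @export
sensitivity <- function(tp, fn) {
  check_counts(tp = tp, fn = fn)
  if (tp + fn == 0) {
    warning("sensitivity undefined: TP + FN = 0")
    return(NA_real_)
  }
  tp / (tp + fn)
}

#' @rdname sensitivity
#' @export
positive_predictivity <- function(tp, fp) {
  check_counts(tp = tp, fp = fp)
  if (tp + fp == 0) {
    warning("positive predictivity undefined: TP + FP = 0")
    return(NA_real_)
  }
  tp / (tp + fp)
}

#' F1-score from confusion counts
#'
#' `F1 = 2 TP / (2 TP + FP + FN)`, the harmonic combination of detection
#' completeness and purity. Undefined (warning + `NA`) when all three counts
#' are zero.
#'
#' @param tp,fp,fn Non-negative integer counts, not all zero.
#' @return Fraction in `[0, 1]`; 1 exactly when `fp = fn = 0` with `tp > 0`.
#' @examples
#' f1_score(tp = 2, fp = 1, fn = 1)  # 2/3
#' @export
f1_score <- function(tp, fp, fn) {
  check_counts(tp = tp, fp = fp, fn = fn)
  if (tp + fp + fn == 0) {
    warning("F1 undefined: TP = FP = FN = 0")
    return(NA_real_)
  }
  2 * tp / (2 * tp + fp + fn)
}

check_counts <- function(...) {
  counts <- list(...)
  for (nm in names(counts)) {
    x <- counts[[nm]]
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 ||
        x != floor(x)) {
      stop(sprintf("`%s` must be a single non-negative integer count", nm))
    }
  }
  invisible(TRUE)
}

#' Median delay correction
#'
#' Every detector delays the signal to some extent, so raw detection time
#' stamps lag the annotated R-peaks by a roughly constant per-record offset.
#' Before jitter is measured this constant is removed: the median delay
#' between detections and their nearest annotations is subtracted from every
#' detection. The correction is computed independently per record, never
#' pooled across records.
#'
#' Two estimators of the median delay are available:
#' \describe{
#'   \item{`"signed"` (default)}{for each detection, the signed difference to
#'     its nearest annotation; the median of these. Handles detectors that
#'     fire early as well as late, and reduces to `"absolute"` when all
#'     detections lag their beats.}
#'   \item{`"absolute"`}{for each annotation, the minimum absolute difference
#'     to any detection; the median of these (always a non-negative shift,
#'     appropriate when detections are known to trail the annotations).}
#' }
#'
#' @param annotations Sample indices of true beats; non-empty.
#' @param detections Sample indices from a detector; non-empty.
#' @param mode Delay estimator, `"signed"` or `"absolute"`.
#' @return A [detection_set()] whose `corrected` field holds the shifted
#'   indices (possibly non-integer: the median of an even count is a
#'   half-sample). Relative spacing of detections is unchanged.
#' @examples
#' median_delay_correct(c(100, 200, 300), c(105, 205, 305))$corrected
#' @export
median_delay_correct <- function(annotations, detections,
                                 mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  a <- as_indices(annotations)
  d_raw <- if (inherits(detections, "detection_set")) detections$raw
           else as.numeric(detections)
  name <- if (inherits(detections, "detection_set")) detections$detector_name
          else "unknown"
  if (length(a) == 0L) stop("empty annotation list: record unusable")
  if (length(d_raw) == 0L) stop("empty detection list: record unusable")

  delay <- if (mode == "signed") {
    stats::median(vapply(d_raw, function(dk) {
      dk - a[which.min(abs(dk - a))]
    }, numeric(1)))
  } else {
    stats::median(vapply(a, function(al) min(abs(al - d_raw)), numeric(1)))
  }
  detection_set(d_raw, detector_name = name, corrected = d_raw - delay)
}

#' Match annotations to delay-corrected detections
#'
#' Builds the annotation-to-detection correspondence used by the JF score.
#' Each annotation claims its nearest (delay-corrected) detection. When two
#' or more annotations claim the same detection, only the closest annotation
#' keeps it and the others become false negatives — a losing annotation is
#' not re-matched to another free detection. Ties (exactly equidistant) break
#' toward the earlier index, making results deterministic and
#' order-independent. Surviving pairs are unique on both sides; their
#' absolute time differences are the per-beat jitters.
#'
#' @param annotations Sample indices of true beats; non-empty, sorted.
#' @param detections Delay-corrected detection indices (a [detection_set()]
#'   from [median_delay_correct()], or a sorted numeric vector); non-empty.
#' @param fs Sampling rate (samples/sec), used to express jitters in seconds.
#' @return Object of class `match_result`: `pairs` (data frame with 1-based
#'   positions `annotation`, `detection` into the input vectors), `jitters`
#'   (seconds, one per pair), and counts `tp`, `fp`, `fn`.
#' @examples
#' m <- match_detections(c(100, 200, 300), c(102, 310), fs = 250)
#' m$tp; m$fn; m$jitters
#' @export
match_detections <- function(annotations, detections, fs) {
  a <- as_indices(annotations)
  d <- as_indices(detections)
  if (length(a) == 0L || length(d) == 0L) {
    stop("annotations and detections must both be non-empty")
  }
  if (is.unsorted(a) || is.unsorted(d)) {
    stop("annotations and detections must be sorted ascending")
  }

  # nearest detection per annotation; which.min breaks ties toward earlier k
  p <- vapply(a, function(al) which.min(abs(al - d)), integer(1))
  dist <- abs(a - d[p])

  # duplicate resolution: each detection keeps its closest claimant only
  keep <- rep(TRUE, length(a))
  for (k in unique(p)) {
    claimants <- which(p == k)
    if (length(claimants) > 1L) {
      winner <- claimants[which.min(dist[claimants])]
      keep[setdiff(claimants, winner)] <- FALSE
    }
  }

  pairs <- data.frame(annotation = which(keep), detection = p[keep])
  jitters <- dist[keep] / fs
  tp <- nrow(pairs)
  structure(
    list(pairs = pairs, jitters = jitters, tp = tp,
         fp = length(d) - tp, fn = length(a) - tp),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> TP=%d FP=%d FN=%d, mean jitter %s\n",
              x$tp, x$fp, x$fn,
              if (x$tp > 0) sprintf("%.3f ms", 1000 * mean(x$jitters))
              else "undefined"))
  invisible(x)
}

#' Jitter score
#'
#' Maps the average absolute jitter of true detections to a dimensionless
#' score in `(0, 1]` via `f = 1 / (1 + mean_jitter / half_score)`. The
#' half-score constant (default 12 ms) is the jitter at which the score drops
#' to 0.5; zero jitter scores exactly 1, and the score decreases strictly
#' with increasing jitter.
#'
#' @param mean_jitter Average absolute jitter in seconds, `>= 0`.
#' @param half_score Jitter in seconds at which the score is 0.5
#'   (default 0.012 s).
#' @return Score in `(0, 1]`.
#' @examples
#' jitter_score(0.012)  # 0.5
#' jitter_score(0)      # 1
#' @export
jitter_score <- function(mean_jitter, half_score = 0.012) {
  if (!is.numeric(mean_jitter) || any(!is.finite(mean_jitter)) ||
      any(mean_jitter < 0)) {
    stop("`mean_jitter` must be non-negative (seconds)")
  }
  if (!is.numeric(half_score) || length(half_score) != 1L || half_score <= 0) {
    stop("`half_score` must be a single positive number of seconds")
  }
  1 / (1 + mean_jitter / half_score)
}

#' JF score: jitter-penalised F1
#'
#' The full JF pipeline for one record: (1) subtract the per-record median
#' detection delay ([median_delay_correct()]); (2) match annotations to
#' corrected detections with unique pairing ([match_detections()]); (3)
#' average the per-pair jitters and map through [jitter_score()]; (4) compute
#' the F1-score from the TP/FP/FN counts; (5) combine as
#' `JF = F1 * f(mean_jitter) * 100%`. No fixed tolerance window is involved:
#' instead of an all-or-nothing cut-off, the F1-score is penalised
#' continuously with increasing jitter. JF reaches 100 exactly when every
#' beat is found, nothing spurious is reported, and the corrected detections
#' coincide with the annotations.
#'
#' @param annotations Sample indices of true beats (or [annotated_record()]);
#'   non-empty.
#' @param detections Raw detection sample indices (or [detection_set()]);
#'   non-empty.
#' @param fs Sampling rate (samples/sec).
#' @param half_score Jitter half-score constant in seconds (see
#'   [jitter_score()]).
#' @param delay_mode Median-delay estimator (see [median_delay_correct()]).
#' @return Object of class `jf_report`: `mean_jitter` (seconds; `NA` if no
#'   pair was matched), `jitter_score`, `f1`, `jf` (percent in `[0, 100]`),
#'   and the underlying `match` ([match_detections()] result).
#' @examples
#' a <- seq(0, 119) * 250          # one beat per second at 250 Hz
#' jf(a, a + 7, fs = 250)$jf       # constant delay is removed: 100
#' @export
jf <- function(annotations, detections, fs, half_score = 0.012,
               delay_mode = c("signed", "absolute")) {
  a <- as_indices(annotations)
  corrected <- median_delay_correct(a, detections, mode = match.arg(delay_mode))
  m <- match_detections(a, corrected, fs)
  if (m$tp == 0L) {
    # unreachable with non-empty inputs under nearest matching; kept so a
    # pathological matcher change cannot turn an undefined jitter into 0
    rep <- list(mean_jitter = NA_real_, jitter_score = NA_real_,
                f1 = 0, jf = 0, match = m)
    return(structure(rep, class = "jf_report"))
  }
  mean_jitter <- mean(m$jitters)
  js <- jitter_score(mean_jitter, half_score = half_score)
  f1 <- f1_score(m$tp, m$fp, m$fn)
  structure(
    list(mean_jitter = mean_jitter, jitter_score = js, f1 = f1,
         jf = f1 * js * 100, match = m),
    class = "jf_report"
  )
}

#' @export
print.jf_report <- function(x, ...) {
  cat(sprintf("<jf_report> JF = %.2f%%\n", x$jf))
  cat(sprintf("  F1 = %.4f (TP=%d FP=%d FN=%d)\n",
              x$f1, x$match$tp, x$match$fp, x$match$fn))
  cat(sprintf("  mean jitter = %s, jitter score = %s\n",
              if (is.na(x$mean_jitter)) "undefined"
              else sprintf("%.3f ms", 1000 * x$mean_jitter),
              if (is.na(x$jitter_score)) "undefined"
              else sprintf("%.4f", x$jitter_score)))
  invisible(x)
}

#' Evaluate a detection stream against one annotated record
#'
#' Convenience wrapper computing both metric families for one
#' record/detection pair: classic fixed-window counts with sensitivity and
#' positive predictivity, and the JF report. Returns a one-row data frame in
#' the export layout used throughout the package.
#'
#' @param record An [annotated_record()].
#' @param detections Raw detection indices (or [detection_set()]).
#' @param w Classic tolerance window in seconds (default `10 / fs`).
#' @inheritParams jf
#' @return One-row data frame with columns `record`, `detector`, `tp`, `fp`,
#'   `fn`, `mean_jitter_ms`, `jitter_score`, `f1`, `jf_percent`, `se`, `ppv`.
#'   Counts are the JF pipeline's (window-free) counts; `se`/`ppv` come from
#'   the classic windowed confusion.
#' @export
evaluate_record <- function(record, detections, w = NULL,
                            half_score = 0.012,
                            delay_mode = c("signed", "absolute")) {
  stopifnot(inherits(record, "annotated_record"))
  if (is.null(w)) w <- default_window(record$fs)
  detector <- if (inherits(detections, "detection_set"))
    detections$detector_name else "unknown"
  cls <- classic_confusion(record$annotations, detections, record$fs, w)
  rep <- jf(record$annotations, detections, record$fs,
            half_score = half_score, delay_mode = delay_mode)
  data.frame(
    record = record$label,
    detector = detector,
    tp = rep$match$tp, fp = rep$match$fp, fn = rep$match$fn,
    mean_jitter_ms = 1000 * rep$mean_jitter,
    jitter_score = rep$jitter_score,
    f1 = rep$f1,
    jf_percent = rep$jf,
    se = sensitivity(cls$tp, cls$fn),
    ppv = if (cls$tp + cls$fp == 0) NA_real_
          else positive_predictivity(cls$tp, cls$fp),
    stringsAsFactors = FALSE
  )
}
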