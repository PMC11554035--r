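#' Define a benchmark suite
#'
#' A suite is the cross of a record list with a detector list, scored on a
#' chosen set of metrics and submitted to the statistical protocol: each
#' (detector, regime, metric) score list is tested against a performance
#' threshold (default 90%) with a one-sided one-sample t-test at
#' `alpha = 0.05`, and a test is only valid when it rests on at least
#' `min_n` per-record scores.
#'
#' @param records List of [annotated_record()] objects. A record's regime is
#'   taken from `meta$regime` (`"unspecified"` when absent).
#' @param detectors Character vector of detector names (see
#'   [list_detectors()]).
#' @param metrics Subset of `c("se", "ppv", "jf")`.
#' @param threshold Performance threshold as a fraction (default 0.9; JF
#'   scores are compared against `100 * threshold`).
#' @param alpha Significance level (default 0.05).
#' @param min_n Minimum number of scores for a valid test (default 20).
#' @param window Classic tolerance window in seconds (default `10 / fs` per
#'   record).
#' @return Object of class `benchmark_suite`.
#' @export
benchmark_suite <- function(records, detectors,
                            metrics = c("se", "ppv", "jf"),
                            threshold = 0.9, alpha = 0.05, min_n = 20,
                            window = NULL) {
  if (!is.list(records) || length(records) == 0L ||
      !all(vapply(records, inherits, TRUE, "annotated_record"))) {
    stop("`records` must be a non-empty list of annotated_record objects")
  }
  if (length(detectors) == 0L) stop("at least one detector is required")
  for (d in detectors) get_detector(d)  # fail early on unknown names
  metrics <- match.arg(metrics, several.ok = TRUE)
  if (threshold <= 0 || threshold >= 1) stop("`threshold` must be in (0, 1)")
  if (min_n < 2) stop("`min_n` must be at least 2")
  structure(
    list(records = records, detectors = detectors, metrics = metrics,
         threshold = threshold, alpha = alpha, min_n = min_n,
         window = window),
    class = "benchmark_suite"
  )
}

#' Run a benchmark suite
#'
#' Evaluates every (detector, record) pair independently — delay correction
#' and scores are computed per record, never pooled — then applies the
#' threshold test per (detector, regime, metric). Records a detector cannot
#' process are excluded from that detector's score list and counted; the
#' suite continues.
#'
#' The threshold test is a one-sided one-sample t-test (alternative: mean
#' greater than the threshold). A cell is `valid` only when it holds at
#' least `min_n` scores, and `significant` only when it is valid, the mean
#' exceeds the threshold and `p < alpha`. A degenerate score list with zero
#' variance leaves the t-statistic undefined; such a cell is decided by the
#' threshold comparison alone (noted in `note`).
#'
#' @param suite A [benchmark_suite()].
#' @return Object of class `suite_result`: `scores` (long data frame of
#'   per-record scores), `summary` (one row per detector/regime/metric with
#'   `n`, `n_failed`, `mean`, `sd`, `t`, `p`, `valid`, `significant`,
#'   `note`), and the suite settings.
#' @export
run_suite <- function(suite) {
  stopifnot(inherits(suite, "benchmark_suite"))
  rows <- list()
  fails <- list()
  for (det in suite$detectors) {
    for (rec in suite$records) {
      regime <- if (!is.null(rec$meta$regime)) rec$meta$regime else "unspecified"
      res <- tryCatch({
        d <- detect(det, rec)
        w <- if (is.null(suite$window)) default_window(rec$fs) else suite$window
        evaluate_record(rec, d, w = w)
      }, error = function(e) e)
      key <- paste(det, regime, sep = "\r")
      if (inherits(res, "error")) {
        fails[[key]] <- (if (is.null(fails[[key]])) 0L else fails[[key]]) + 1L
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          detector = det, regime = regime, record = rec$label,
          se = res$se, ppv = res$ppv, jf = res$jf_percent,
          stringsAsFactors = FALSE)
      }
    }
  }
  scores <- if (length(rows)) do.call(rbind, rows) else
    data.frame(detector = character(), regime = character(),
               record = character(), se = numeric(), ppv = numeric(),
               jf = numeric())

  regimes <- unique(vapply(suite$records, function(r) {
    if (!is.null(r$meta$regime)) r$meta$regime else "unspecified"
  }, ""))
  summ <- list()
  for (det in suite$detectors) {
    for (reg in regimes) {
      sub <- scores[scores$detector == det & scores$regime == reg, ,
                    drop = FALSE]
      n_failed <- fails[[paste(det, reg, sep = "\r")]]
      if (is.null(n_failed)) n_failed <- 0L
      for (met in suite$metrics) {
        x <- sub[[met]]
        x <- x[!is.na(x)]
        mu0 <- if (met == "jf") 100 * suite$threshold else suite$threshold
        tt <- threshold_test(x, mu0, suite$alpha, suite$min_n)
        summ[[length(summ) + 1L]] <- data.frame(
          detector = det, regime = reg, metric = met,
          n = tt$n, n_failed = n_failed, mean = tt$mean, sd = tt$sd,
          t = tt$t, p = tt$p, valid = tt$valid,
          significant = tt$significant, note = tt$note,
          stringsAsFactors = FALSE)
      }
    }
  }
  summary <- do.call(rbind, summ)
  ord <- order(summary$detector,
               match(summary$regime, c(noise_ladder(), "none", "unspecified")),
               summary$metric)
  structure(
    list(scores = scores, summary = summary[ord, , drop = FALSE],
         threshold = suite$threshold, alpha = suite$alpha,
         min_n = suite$min_n),
    class = "suite_result"
  )
}

# One-sided one-sample t-test of scores against mu0, with the validity and
# zero-variance rules of the protocol.
threshold_test <- function(x, mu0, alpha, min_n) {
  n <- length(x)
  out <- list(n = n, mean = if (n) mean(x) else NA_real_,
              sd = if (n > 1) stats::sd(x) else NA_real_,
              t = NA_real_, p = NA_real_,
              valid = n >= min_n, significant = FALSE, note = "")
  if (n == 0L) {
    out$note <- "no scores"
    return(out)
  }
  if (!out$valid) out$note <- sprintf("n < %d", min_n)
  if (n > 1 && stats::sd(x) > 0) {
    tt <- stats::t.test(x, mu = mu0, alternative = "greater")
    out$t <- unname(tt$statistic)
    out$p <- tt$p.value
    out$significant <- out$valid && out$p < alpha && out$mean > mu0
  } else {
    out$note <- trimws(paste(out$note, "zero variance: threshold comparison only"))
    out$significant <- out$valid && out$mean > mu0
  }
  out
}

#' @export
print.suite_result <- function(x, ...) {
  cat(sprintf("<suite_result> %d detector(s) x %d regime(s), threshold %g%%\n",
              length(unique(x$summary$detector)),
              length(unique(x$summary$regime)), 100 * x$threshold))
  print(suite_table(x), digits = 4)
  invisible(x)
}

#' Tabulate a suite result
#'
#' Deterministically ordered (detector, regime, metric) table of the
#' summary, with an asterisk marker for cells significantly above the
#' threshold and an explicit `n < min_n` marker for invalid cells.
#'
#' @param result A `suite_result` from [run_suite()].
#' @return Data frame.
#' @export
suite_table <- function(result) {
  stopifnot(inherits(result, "suite_result"))
  df <- result$summary
  df$flag <- ifelse(!df$valid, sprintf("n < %d", result$min_n),
                    ifelse(df$significant, "*", ""))
  df
}

#' Export a suite result
#'
#' Writes the per-record score list and the summary table as delimited text
#' (the significance decision is reproducible from the exported score list
#' alone).
#'
#' @param result A `suite_result`.
#' @param dir Output directory (created if needed).
#' @param format `"tsv"` or `"csv"`.
#' @return Invisibly, the paths written.
#' @export
write_suite_results <- function(result, dir, format = c("tsv", "csv")) {
  stopifnot(inherits(result, "suite_result"))
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    scores = file.path(dir, paste0("scores.", format)),
    summary = file.path(dir, paste0("summary.", format))
  )
  write_metric_report(result$scores, paths["scores"], format)
  write_metric_report(suite_table(result), paths["summary"], format)
  invisible(paths)
}

#' Generate a ladder of synthetic records
#'
#' Convenience generator for benchmark suites: `n_per_regime` seeded records
#' for each requested noise regime, all from one master seed. Per-record
#' seeds are derived deterministically from the master seed, so the whole
#' suite is reproducible from a single integer.
#'
#' @param n_per_regime Records per regime.
#' @param regimes Character vector of regime names (default the five-step
#'   activity ladder).
#' @param beat A [beat_model()].
#' @param duration,fs Record length (s) and sampling rate.
#' @param seed Master seed.
#' @return List of [annotated_record()] objects.
#' @export
simulate_records <- function(n_per_regime, regimes = noise_ladder(),
                             beat = beat_model(), duration = 120, fs = 250,
                             seed = 1) {
  records <- list()
  for (ri in seq_along(regimes)) {
    for (i in seq_len(n_per_regime)) {
      rec_seed <- (as.integer(seed) + 104729L * ri + 7919L * i) %% 2147483647L
      records[[length(records) + 1L]] <- generate_record(
        beat = beat, noise = regimes[ri], duration = duration, fs = fs,
        seed = rec_seed)
    }
  }
  records
}

#' Metric validation battery (parameter recovery)
#'
#' Validates the metric chain against streams with known error structure:
#' for each seeded record, the ground truth is corrupted with
#' [corrupt_detections()] and the corrupted stream is scored with [jf()].
#' Recovered false-negative rate, false-positive rate and mean jitter are
#' then comparable to the generating `delete_prob`, `insert_rate` and the
#' folded-normal mean `jitter_sd * sqrt(2/pi)`.
#'
#' Because the matcher uses no tolerance window, a deleted beat whose
#' annotation happens to lie near an inserted spurious event is paired with
#' it, producing a "true detection" with a very large jitter. The generator
#' keeps insertions at least `guard` seconds away from every true beat, so
#' any matched pair with jitter at or beyond the guard is, by construction,
#' such a deletion/insertion collision rather than timing noise. The battery
#' therefore reclassifies those pairs for parameter recovery — each counts
#' as one missed beat and one spurious detection — and recovers the jitter
#' parameter from the sub-guard pairs only. The raw pooled quantities are
#' also returned.
#'
#' @param spec A [corruption_spec()].
#' @param n_records Number of records.
#' @param duration,fs Record length (s) and sampling rate.
#' @param rr_mean,rr_sd RR interval distribution (s).
#' @param seed Master seed.
#' @param guard Insertion guard distance in seconds (must match
#'   [corrupt_detections()], which uses 0.1 s).
#' @return List with recovered `fn_rate`, `fp_rate` (per second),
#'   `mean_jitter` (seconds); raw pooled `fn_rate_raw`, `fp_rate_raw`,
#'   `mean_jitter_raw`; `n_collisions`; totals `n_beats`, `n_detections`,
#'   `total_duration`; and the per-record `reports`.
#' @export
validate_metric <- function(spec, n_records = 25, duration = 120, fs = 250,
                            rr_mean = 1.0, rr_sd = 0.05, seed = 1,
                            guard = 0.1) {
  stopifnot(inherits(spec, "corruption_spec"))
  beat <- beat_model(rr_mean = rr_mean, rr_sd = rr_sd)
  fn_tot <- 0L; fp_tot <- 0L; n_beats <- 0L; n_det <- 0L
  jit <- numeric(0)
  reports <- vector("list", n_records)
  for (i in seq_len(n_records)) {
    rec_seed <- (as.integer(seed) + 7919L * i) %% 2147483647L
    rec <- generate_record(beat = beat, noise = "none", duration = duration,
                           fs = fs, seed = rec_seed)
    d <- corrupt_detections(rec, spec, seed = rec_seed + 1L)
    rep <- jf(rec$annotations, d, fs)
    fn_tot <- fn_tot + rep$match$fn
    fp_tot <- fp_tot + rep$match$fp
    n_beats <- n_beats + length(rec$annotations)
    n_det <- n_det + length(d$raw)
    jit <- c(jit, rep$match$jitters)
    reports[[i]] <- rep
  }
  total_duration <- n_records * duration
  collision <- jit >= guard
  n_coll <- sum(collision)
  list(fn_rate = (fn_tot + n_coll) / n_beats,
       fp_rate = (fp_tot + n_coll) / total_duration,
       mean_jitter = mean(jit[!collision]),
       fn_rate_raw = fn_tot / n_beats,
       fp_rate_raw = fp_tot / total_duration,
       mean_jitter_raw = mean(jit),
       n_collisions = n_coll,
       n_beats = n_beats, n_detections = n_det,
       total_duration = total_duration,
       reports = reports)
}
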