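test_that("classic windowed confusion applies the tolerance rule exactly", {
  # identity
  r <- classic_confusion(c(100, 200, 300), c(100, 200, 300), fs = 250)
  expect_equal(r, list(tp = 3L, fp = 0L, fn = 0L))
  # 48 ms > 40 ms window: miss
  expect_equal(classic_confusion(250, 262, fs = 250, w = 0.04),
               list(tp = 0L, fp = 1L, fn = 1L))
  # 36 ms <= 40 ms window: hit
  expect_equal(classic_confusion(250, 259, fs = 250, w = 0.04),
               list(tp = 1L, fp = 0L, fn = 0L))
  # empty detections: all beats missed, not an error
  expect_equal(classic_confusion(c(10, 20), numeric(0), fs = 250),
               list(tp = 0L, fp = 0L, fn = 2L))
  # each detection consumed at most once
  r <- classic_confusion(c(100, 101), c(100), fs = 250, w = 0.04)
  expect_equal(r$tp, 1L)
  expect_error(classic_confusion(numeric(0), c(1), fs = 250), "unusable")
})

test_that("the default tolerance window is ten sampling intervals", {
  expect_equal(default_window(250), 0.040)
  expect_equal(default_window(360), 10 / 360)
  expect_equal(default_window(1000), 0.010)
  expect_error(default_window(0))
  expect_error(default_window(-5))
})

test_that("sensitivity, positive predictivity and F1 follow their ratios", {
  expect_equal(sensitivity(tp = 3, fn = 0), 1.0)
  expect_equal(sensitivity(tp = 9, fn = 1), 0.9)
  expect_equal(sensitivity(tp = 2, fn = 1), 2 / 3)
  expect_equal(positive_predictivity(tp = 2, fp = 1), 2 / 3)
  expect_equal(f1_score(tp = 10, fp = 0, fn = 0), 1.0)
  expect_equal(f1_score(tp = 2, fp = 1, fn = 1), 4 / 6)
  expect_equal(f1_score(tp = 0, fp = 3, fn = 5), 0.0)
})

test_that("undefined ratios warn and return NA instead of a silent zero", {
  expect_warning(se <- sensitivity(0, 0), "undefined")
  expect_true(is.na(se))
  expect_warning(pp <- positive_predictivity(0, 0), "undefined")
  expect_true(is.na(pp))
  expect_warning(f1 <- f1_score(0, 0, 0), "undefined")
  expect_true(is.na(f1))
  expect_error(sensitivity(-1, 2))
  expect_error(f1_score(1.5, 0, 0))
})

test_that("median delay correction removes the per-record constant offset", {
  expect_equal(median_delay_correct(c(100, 200, 300),
                                    c(105, 205, 305))$corrected,
               c(100, 200, 300))
  expect_equal(median_delay_correct(c(100, 200, 300),
                                    c(100, 200, 300))$corrected,
               c(100, 200, 300))
  # signed nearest-annotation differences {4, 6, 5}: median 5
  expect_equal(median_delay_correct(c(100, 200, 300),
                                    c(104, 206, 305))$corrected,
               c(99, 201, 300))
  # relative spacing unchanged
  cs <- median_delay_correct(c(100, 200), c(104, 212))$corrected
  expect_equal(diff(cs), 108)
  expect_error(median_delay_correct(c(100), numeric(0)), "unusable")
  expect_error(median_delay_correct(numeric(0), c(100)), "unusable")
})

test_that("the absolute-difference delay estimator matches its definition", {
  # per annotation min |a - d|: {4, 6, 5}; median 5 subtracted throughout
  out <- median_delay_correct(c(100, 200, 300), c(104, 206, 305),
                              mode = "absolute")
  expect_equal(out$corrected, c(99, 201, 300))
  # early-firing detector: absolute mode still shifts earlier (its known
  # limitation), signed mode recovers the true negative delay
  expect_equal(median_delay_correct(c(100, 200), c(95, 195))$corrected,
               c(100, 200))
})

test_that("matching is unique on both sides with closest-claimant wins", {
  m <- match_detections(c(100, 200, 300), c(100, 200, 300), fs = 250)
  expect_equal(c(m$tp, m$fp, m$fn), c(3L, 0L, 0L))
  expect_equal(m$jitters, c(0, 0, 0))

  # annotations 100 and 200 both claim detection 102; 100 is closer and
  # keeps it, 200 is dropped (not re-matched), 300 pairs with 310
  m <- match_detections(c(100, 200, 300), c(102, 310), fs = 250)
  expect_equal(c(m$tp, m$fp, m$fn), c(2L, 0L, 1L))
  expect_equal(sort(m$jitters), sort(c(2, 10) / 250))

  # unclaimed detection becomes a false positive
  m <- match_detections(c(100, 300), c(101, 150, 299), fs = 250)
  expect_equal(c(m$tp, m$fp, m$fn), c(2L, 1L, 0L))
  expect_equal(m$jitters, c(1, 1) / 250)

  # pair uniqueness on both sides
  expect_false(anyDuplicated(m$pairs$annotation) > 0)
  expect_false(anyDuplicated(m$pairs$detection) > 0)
})

test_that("the jitter score halves at the 12 ms constant", {
  expect_equal(jitter_score(0.012), 0.5)
  expect_equal(jitter_score(0), 1.0)
  expect_equal(jitter_score(0.024), 1 / 3)
  expect_error(jitter_score(-0.001), "non-negative")
  # strictly decreasing
  x <- seq(0, 0.1, by = 0.005)
  expect_true(all(diff(jitter_score(x)) < 0))
  # configurable half-score constant
  expect_equal(jitter_score(0.020, half_score = 0.020), 0.5)
})

test_that("JF composes delay correction, matching, jitter score and F1", {
  a <- seq(0, 99) * 250
  expect_equal(jf(a, a, fs = 250)$jf, 100)

  # hand-composition from fixed counts and jitters
  mean_j <- mean(c(2, 10) / 250)            # 24 ms
  expect_equal(jitter_score(mean_j), 1 / 3)
  expect_equal(f1_score(2, 0, 1) * jitter_score(mean_j) * 100,
               100 * (4 / 5) * (1 / 3))

  # constant +3 sample delay is removed entirely
  expect_equal(jf(a, a + 3, fs = 250)$jf, 100)

  rep <- jf(c(100, 200, 300), c(102, 310), fs = 250)
  expect_s3_class(rep, "jf_report")
  expect_equal(rep$jf, rep$f1 * rep$jitter_score * 100)
  expect_error(jf(numeric(0), c(1), fs = 250))
  expect_error(jf(c(1), numeric(0), fs = 250))
})

test_that("JF is exactly invariant under constant detection delay", {
  # exactness requires the delay to stay well below half the beat spacing,
  # the regime in which delay correction is meaningful; larger shifts can
  # re-assign a detection to a different nearest beat
  set.seed(11)
  for (i in 1:20) {
    inst <- random_instance(jitter_sd_samples = 2.5, insertions = FALSE)
    if (length(inst$d) == 0) next
    base <- jf(inst$a, inst$d, fs = 250)
    for (c_shift in c(-30L, -3L, 1L, 7L, 50L)) {
      shifted <- jf(inst$a, inst$d + c_shift, fs = 250)
      expect_identical(shifted$jf, base$jf)
      expect_identical(shifted$mean_jitter, base$mean_jitter)
    }
  }
})

test_that("counts are conserved: tp+fp = detections, tp+fn = annotations", {
  set.seed(22)
  for (i in 1:50) {
    inst <- random_instance(jitter_sd_samples = sample(c(1, 3, 6), 1))
    if (length(inst$d) == 0) next
    m <- match_detections(inst$a, inst$d, fs = 250)
    expect_identical(m$tp + m$fp, length(inst$d))
    expect_identical(m$tp + m$fn, length(inst$a))
    expect_identical(m$tp, length(m$jitters))
    expect_true(all(m$jitters >= 0))
  }
})

test_that("zero jitter and no missed/spurious beats give SE = +P = F1 = 1 and JF = 100", {
  a <- cumsum(c(100, 240, 260, 250, 245))
  cls <- classic_confusion(a, a, fs = 250)
  expect_equal(sensitivity(cls$tp, cls$fn), 1)
  expect_equal(positive_predictivity(cls$tp, cls$fp), 1)
  rep <- jf(a, a, fs = 250)
  expect_equal(rep$f1, 1)
  expect_equal(rep$jf, 100)
  expect_equal(rep$mean_jitter, 0)
})

test_that("expected JF decreases as timing jitter spreads", {
  set.seed(33)
  a <- seq(1, 600) * 250          # 600 beats, enough to average out noise
  spreads <- c(0, 1, 3, 6)        # samples
  mean_jf <- vapply(spreads, function(s) {
    mean(vapply(1:8, function(i) {
      d <- sort(unique(round(a + rnorm(length(a), 0, s))))
      jf(a, d, fs = 250)$jf
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_jf) <= 0))
  expect_lt(mean_jf[4], mean_jf[1])
})

test_that("evaluate_record returns the standard export row", {
  rec <- generate_record(duration = 30, seed = 3)
  row <- evaluate_record(rec, detection_set(rec$annotations, "perfect"))
  expect_named(row, c("record", "detector", "tp", "fp", "fn",
                      "mean_jitter_ms", "jitter_score", "f1", "jf_percent",
                      "se", "ppv"))
  expect_equal(row$jf_percent, 100)
  expect_equal(row$se, 1)
  expect_equal(row$detector, "perfect")
})
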