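clean_rec <- generate_record(noise = "none", duration = 120, fs = 250,
                             seed = 42)
implemented <- list_detectors(implemented_only = TRUE)$name

test_that("the registry lists implementations and rejects unknown names", {
  df <- list_detectors()
  expect_true(all(c("matched_filter", "pan_tompkins", "engzee", "wqrs",
                    "elgendi", "kalidas_tamil", "christov", "hamilton")
                  %in% df$name))
  expect_true(all(c("matched_filter", "pan_tompkins", "engzee", "wqrs")
                  %in% implemented))
  expect_error(detect("no_such_detector", clean_rec), "unknown detector")
  # declared stubs refuse to run but document themselves
  expect_error(detect("kalidas_tamil", clean_rec), "not implemented")
})

test_that("custom detectors can be registered and dispatched", {
  register_detector("test_dummy", function(samples, fs) {
    which(samples > 0.9 * max(samples)) - 1L
  }, "threshold on the raw signal")
  on.exit(rm("test_dummy", envir = jfbench:::.detector_registry))
  d <- detect("test_dummy", clean_rec)
  expect_s3_class(d, "detection_set")
  expect_false(is.unsorted(d$raw, strictly = TRUE))
})

test_that("input contract: warm-up length, fs bounds, flat line", {
  expect_error(detect("matched_filter", rep(0.5, 100), fs = 250), "warm-up")
  expect_error(detect("matched_filter", rnorm(1000), fs = 50), "\\[100, 1000\\]")
  expect_error(detect("matched_filter", rnorm(1000), fs = 2000), "\\[100, 1000\\]")
  # no energy, no beats: valid empty result
  for (det in implemented) {
    expect_length(detect(det, rep(0, 3000), fs = 250)$raw, 0)
    expect_length(detect(det, rep(2.5, 3000), fs = 250)$raw, 0)
  }
})

test_that("every implemented detector finds essentially all clean beats", {
  for (det in implemented) {
    d <- detect(det, clean_rec)
    cls <- classic_confusion(clean_rec$annotations, d, clean_rec$fs)
    expect_gt(sensitivity(cls$tp, cls$fn), 0.99, label = det)
    expect_gt(positive_predictivity(cls$tp, cls$fp), 0.99, label = det)
  }
})

test_that("matched filter recovers exactly one detection per clean beat", {
  d <- detect("matched_filter", clean_rec)
  expect_length(d$raw, length(clean_rec$annotations))
  expect_error(matched_filter_detect(clean_rec$samples, 250,
                                     template = rep(0, 20)), "all zero")
})

test_that("detectors are deterministic and shift with the signal", {
  fs <- 250
  rec <- generate_record(noise = "sitting", duration = 60, fs = fs, seed = 5)
  margin <- 2 * fs
  n <- length(rec$samples)
  for (det in implemented) {
    d1 <- detect(det, rec)$raw
    expect_identical(d1, detect(det, rec)$raw, label = det)
    # translation covariance away from the record edges
    s <- 100L
    d_shift <- detect(det, c(rep(0, s), rec$samples), fs = fs)$raw - s
    core <- d1[d1 > margin & d1 < n - margin]
    core_shift <- d_shift[d_shift > margin & d_shift < n - margin]
    expect_equal(core_shift, core, label = det)
  }
})

test_that("adaptive thresholds make detections amplitude-invariant", {
  rec <- generate_record(noise = "walking", duration = 60, fs = 250, seed = 9)
  for (det in implemented) {
    d1 <- detect(det, rec)$raw
    expect_identical(detect(det, rec$samples * 10, fs = 250)$raw, d1,
                     label = paste(det, "x10"))
    expect_identical(detect(det, rec$samples * 0.001, fs = 250)$raw, d1,
                     label = paste(det, "x0.001"))
  }
})

test_that("Pan-Tompkins adapts to a heart-rate step within eight beats", {
  fs <- 250
  slow <- generate_record(beat_model(rr_mean = 1.0, rr_sd = 0),
                          duration = 60, fs = fs, seed = 1)
  fast <- generate_record(beat_model(rr_mean = 0.5, rr_sd = 0),
                          duration = 60, fs = fs, seed = 2)
  rec <- annotated_record(
    c(slow$samples, fast$samples), fs,
    c(slow$annotations, fast$annotations + length(slow$samples)),
    label = "hr_step")
  d <- detect("pan_tompkins", rec)
  # exclude the eight beats following the step from the adaptation demand
  step_at <- length(slow$samples)
  post <- which(rec$annotations >= step_at)
  grace <- rec$annotations %in% rec$annotations[post[seq_len(min(8, length(post)))]]
  w <- default_window(fs) * fs
  found <- vapply(rec$annotations, function(al) min(abs(al - d$raw)) <= w,
                  logical(1))
  expect_true(all(found[!grace]))
})

test_that("white-noise input yields a low false-trigger rate", {
  set.seed(99)
  noise <- rnorm(120 * 250)
  d <- detect("pan_tompkins", noise, fs = 250)
  expect_lt(length(d$raw) / 120, 0.5)
})
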