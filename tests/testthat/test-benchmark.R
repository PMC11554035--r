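small_suite <- function(n = 4, regimes = c("sitting", "jogging"),
                        detectors = "matched_filter", ...) {
  recs <- simulate_records(n, regimes = regimes, duration = 20, seed = 31)
  benchmark_suite(recs, detectors, ...)
}

test_that("suite construction validates its inputs", {
  recs <- simulate_records(2, regimes = "sitting", duration = 20, seed = 1)
  expect_error(benchmark_suite(list(), "matched_filter"), "non-empty")
  expect_error(benchmark_suite(recs, character(0)), "at least one")
  expect_error(benchmark_suite(recs, "nope"), "unknown detector")
  expect_error(benchmark_suite(recs, "matched_filter", threshold = 1.2),
               "threshold")
  expect_error(benchmark_suite(recs, "matched_filter", min_n = 1), "min_n")
})

test_that("a suite evaluates every detector-record pair independently", {
  res <- run_suite(small_suite(n = 3, detectors = c("matched_filter",
                                                    "pan_tompkins")))
  expect_s3_class(res, "suite_result")
  expect_equal(nrow(res$scores), 2 * 3 * 2)   # detectors x regimes x records
  expect_equal(sort(unique(res$summary$metric)), c("jf", "ppv", "se"))
  tab <- suite_table(res)
  expect_true(all(tab$flag[!tab$valid] == "n < 20"))
})

test_that("permuting the record list changes nothing", {
  suite <- small_suite(n = 3)
  res1 <- run_suite(suite)
  suite$records <- rev(suite$records)
  res2 <- run_suite(suite)
  key <- c("detector", "regime", "metric")
  s1 <- res1$summary[do.call(order, res1$summary[key]), ]
  s2 <- res2$summary[do.call(order, res2$summary[key]), ]
  rownames(s1) <- rownames(s2) <- NULL
  expect_equal(s1, s2)
})

test_that("adding a detector leaves other detectors' cells unchanged", {
  s1 <- run_suite(small_suite(n = 3, detectors = "matched_filter"))
  s2 <- run_suite(small_suite(n = 3, detectors = c("matched_filter", "wqrs")))
  a <- s1$summary[s1$summary$detector == "matched_filter", ]
  b <- s2$summary[s2$summary$detector == "matched_filter", ]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("failing detectors are excluded and counted, not fatal", {
  register_detector("always_fails", function(samples, fs) stop("boom"),
                    "test stub that always errors")
  on.exit(rm("always_fails", envir = jfbench:::.detector_registry))
  res <- run_suite(small_suite(n = 3, regimes = "sitting",
                               detectors = c("matched_filter",
                                             "always_fails")))
  cell <- res$summary[res$summary$detector == "always_fails" &
                        res$summary$metric == "jf", ]
  expect_equal(cell$n, 0L)
  expect_equal(cell$n_failed, 3L)
  expect_false(cell$valid)
  expect_false(cell$significant)
  ok <- res$summary[res$summary$detector == "matched_filter" &
                      res$summary$metric == "jf", ]
  expect_equal(ok$n, 3L)
})

test_that("the threshold test follows the protocol rules", {
  tt <- jfbench:::threshold_test(rep(100, 25), 90, 0.05, 20)
  expect_true(tt$valid)
  expect_true(tt$significant)        # zero variance, above threshold
  expect_match(tt$note, "zero variance")

  tt <- jfbench:::threshold_test(rep(100, 10), 90, 0.05, 20)
  expect_false(tt$valid)
  expect_false(tt$significant)       # n below the minimum, no asterisk
  expect_match(tt$note, "n < 20")

  set.seed(44)
  hi <- 95 + rnorm(25, sd = 1)
  tt <- jfbench:::threshold_test(hi, 90, 0.05, 20)
  expect_true(tt$significant)
  expect_equal(tt$p, stats::t.test(hi, mu = 90,
                                   alternative = "greater")$p.value)
  lo <- 85 + rnorm(25, sd = 1)
  expect_false(jfbench:::threshold_test(lo, 90, 0.05, 20)$significant)
  # mean above threshold but inconclusive: not significant
  wide <- 91 + rnorm(25, sd = 20)
  tt <- jfbench:::threshold_test(wide, 90, 0.05, 20)
  expect_false(tt$significant && tt$p >= 0.05)
})

test_that("the significance decision is reproducible from exported scores", {
  res <- run_suite(small_suite(n = 3))
  dir <- withr::local_tempdir()
  paths <- write_suite_results(res, dir)
  scores <- utils::read.delim(paths["scores"])
  for (i in seq_len(nrow(res$summary))) {
    row <- res$summary[i, ]
    x <- scores[scores$detector == row$detector &
                  scores$regime == row$regime, row$metric]
    x <- x[!is.na(x)]
    mu0 <- if (row$metric == "jf") 90 else 0.9
    redo <- jfbench:::threshold_test(x, mu0, 0.05, 20)
    expect_equal(redo$significant, row$significant)
    expect_equal(redo$mean, row$mean)
  }
})

test_that("suite results render as table and plot", {
  res <- run_suite(small_suite(n = 2, regimes = "sitting"))
  tab <- suite_table(res)
  expect_equal(nrow(tab), 3)       # one detector, one regime, three metrics
  p <- plot_suite(res)
  expect_s3_class(p, "ggplot")
  expect_error(plot_suite(res, metric = "nonexistent"), "no cells")
})
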