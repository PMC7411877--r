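test_that("timelines validate and merge their intervals", {
  tl <- labeled_timeline(
    onsets = 7200,
    interictal = data.frame(start_s = c(0, 1000, 900), end_s = c(900, 3000, 1100)),
    exclusions = data.frame(start_s = 100, end_s = 200, tag = "nap"))
  # contiguous/overlapping half-open pieces coalesce into [0, 3000)
  expect_equal(nrow(tl$interictal_intervals), 1L)
  expect_equal(tl$interictal_intervals$end_s, 3000)
  # interictal time within 30 min of an onset is rejected
  expect_error(labeled_timeline(onsets = 3600,
                                interictal = cbind(0, 2000)),
               "30|1800")
  expect_error(labeled_timeline(onsets = -5), "non-negative")
})

test_that("label files round-trip", {
  tl <- labeled_timeline(
    onsets = c(9000, 12000),
    interictal = cbind(c(0, 14000), c(7000, 20000)),
    exclusions = data.frame(start_s = c(500, 1500), end_s = c(800, 1700),
                            tag = c("nocturnal", "PVC")))
  path <- withr::local_tempfile(fileext = ".csv")
  write_labels(tl, path)
  back <- read_labels(path)
  expect_equal(back$seizure_onsets, tl$seizure_onsets)
  expect_equal(back$interictal_intervals, tl$interictal_intervals)
  expect_equal(back$exclusion_intervals$tag, c("nocturnal", "PVC"))
})

test_that("exclusion masks drop beats and clip episodes", {
  tl0 <- labeled_timeline(exclusions = NULL)
  beats <- rri_records(seq_len(100), rep(1000, 100))
  expect_identical(apply_exclusions(beats, tl0), beats)

  tl <- labeled_timeline(exclusions = data.frame(start_s = 40, end_s = 60,
                                                 tag = "noisy-EEG"))
  kept <- apply_exclusions(beats, tl)
  expect_equal(nrow(kept), 80L)          # 20-beat window removed
  expect_false(any(kept$t_beat_s >= 40 & kept$t_beat_s < 60))

  eps <- data.frame(t_start_s = c(45, 10, 30), t_end_s = c(55, 20, 70),
                    statistic = "Q")
  out <- apply_exclusions(eps, tl)
  # fully inside: dropped; disjoint: kept; spanning: split at the edges
  expect_equal(nrow(out), 3L)
  expect_equal(sort(out$t_start_s), c(10, 30, 60))
  expect_equal(sort(out$t_end_s), c(20, 40, 70))
})

test_that("horizon sensitivity scores the bundled per-seizure alarm table", {
  tbl <- read.csv(extdata("alarm_intervals.csv"))
  q <- sensitivity_from_alarm_table(tbl, "Q", horizon = 900)
  expect_equal(q$n_seizures, 14L)
  expect_equal(q$n_predicted, 12L)
  expect_equal(round(100 * q$sensitivity, 1), 85.7)
  expect_false(q$hits[["A3"]])
  expect_false(q$hits[["C2"]])
  # an episode straddling the horizon edge still counts (overlap rule)
  expect_true(q$hits[["E1"]])

  t2 <- sensitivity_from_alarm_table(tbl, "T2", horizon = 900)
  expect_equal(t2$n_predicted, 2L)
  expect_equal(round(100 * t2$sensitivity, 1), 14.3)
  expect_equal(names(which(t2$hits)), c("C2", "F1"))
})

test_that("horizon sensitivity on absolute times is monotone in the horizon", {
  eps <- data.frame(t_start_s = c(100, 5000), t_end_s = c(200, 5100))
  onsets <- c(1500, 5050, 9000)
  res <- sensitivity_at_horizon(eps, onsets, horizon = 900)
  expect_equal(res$hits, c(FALSE, TRUE, FALSE))
  res2 <- sensitivity_at_horizon(eps, onsets, horizon = 1400)
  expect_equal(res2$hits, c(TRUE, TRUE, FALSE))
  prev <- 0
  for (h in c(60, 300, 900, 1400, 4000, 10000)) {
    s <- sensitivity_at_horizon(eps, onsets, horizon = h)$sensitivity
    expect_gte(s, prev)
    prev <- s
  }
  expect_equal(sensitivity_at_horizon(eps[0, ], onsets, 900)$sensitivity, 0)
  expect_error(sensitivity_at_horizon(eps, numeric(0)), "undefined")
})

test_that("false positives are counted per interictal hour", {
  iv <- cbind(0, 0.883 * 3600)
  eps <- data.frame(t_start_s = c(10, 100, 3000), t_end_s = c(20, 120, 3050))
  expect_equal(false_positive_rate(eps, iv), 3 / 0.883)
  expect_equal(false_positive_rate(eps[0, ], iv), 0)
  # half-open convention: an onset exactly at an interval start counts,
  # at the end it does not
  iv2 <- cbind(100, 200)
  expect_equal(false_positive_rate(data.frame(t_start_s = 100,
                                              t_end_s = 110), iv2) > 0, TRUE)
  expect_equal(false_positive_rate(data.frame(t_start_s = 200,
                                              t_end_s = 210), iv2), 0)
  # invariant to splitting an interval into contiguous pieces
  split_iv <- cbind(c(0, 1000, 2500), c(1000, 2500, 0.883 * 3600))
  expect_equal(false_positive_rate(eps, split_iv),
               false_positive_rate(eps, iv))
  expect_error(false_positive_rate(eps, cbind(numeric(0), numeric(0))),
               "zero interictal")
})

test_that("the one-sided sign test is the exact binomial tail", {
  expect_equal(sign_test_one_sided(12, 14), 106 / 16384)
  expect_equal(signif(sign_test_one_sided(12, 14), 2), 0.0065)
  expect_equal(sign_test_one_sided(14, 14), 0.5^14)
  # brute-force tail sum oracle
  brute <- sum(choose(14, 7:14)) / 2^14
  expect_equal(sign_test_one_sided(7, 14), brute)
  expect_equal(sign_test_one_sided(7, 14, direction = "less"),
               sum(choose(14, 0:7)) / 2^14)
  # tail consistency: P(X >= k) + P(X <= k - 1) = 1
  for (k in 1:14)
    expect_equal(sign_test_one_sided(k, 14) +
                   sign_test_one_sided(k - 1, 14, direction = "less"), 1)
  expect_error(sign_test_one_sided(15, 14), "between")
})

test_that("group false-positive rates are compared by Welch's t-test", {
  expect_equal(compare_fp_rates(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(compare_fp_rates(rep(2, 4), rep(2, 5)), 1)
  a <- withr::with_seed(61, rnorm(7, 0, 1))
  b <- withr::with_seed(62, rnorm(7, 5, 1))  # 5-SD separation
  expect_lt(compare_fp_rates(a, b), 0.01)
  # cross-check against the generic implementation
  expect_equal(compare_fp_rates(a, b), t.test(a, b)$p.value)
  expect_error(compare_fp_rates(1, c(1, 2)), "at least 2")

  # bundled per-subject rates: patients vs controls not significant
  fp <- read.csv(extdata("interictal_fp_rates.csv"))
  for (stat in c("Q", "T2")) {
    p <- compare_fp_rates(
      fp$rate_per_h[fp$statistic == stat & fp$group == "patient"],
      fp$rate_per_h[fp$statistic == stat & fp$group == "control"])
    expect_gt(p, 0.05)
  }
})

test_that("Bland-Altman bias and limits of agreement", {
  x <- withr::with_seed(63, rnorm(100, 900, 50))
  ba <- bland_altman(x, x)
  expect_equal(ba$bias, 0)
  expect_equal(unname(ba$loa), c(0, 0))

  ba <- bland_altman(x, x - 2)
  expect_equal(ba$bias, 2)
  expect_equal(unname(ba$loa), c(2, 2))

  d <- withr::with_seed(64, rnorm(10000, 1, 3))
  ba <- bland_altman(x <- rep(1000, 10000), x - d)
  expect_equal(ba$bias, 1, tolerance = 0.1)
  expect_equal(unname(ba$loa), c(-4.88, 6.88), tolerance = 0.05)

  # adding a constant to the reference shifts the bias by exactly that
  r <- withr::with_seed(65, rnorm(50, 900, 40))
  dev <- r + withr::with_seed(66, rnorm(50, 0, 5))
  expect_equal(bland_altman(r + 7, dev)$bias, bland_altman(r, dev)$bias + 7)
  expect_error(bland_altman(1:3, 1:4), "equal length")
})

test_that("failure-rate summaries reproduce the bundled device counts", {
  counts <- read.csv(extdata("rri_failure_counts.csv"))
  s <- failure_rate_summary(counts$total_rri, counts$outliers)
  expect_equal(s$rate_pct[counts$subject == "A"], 4.7)
  expect_equal(s$rate_pct[counts$subject == "D"], 6.7)
  expect_equal(s$mean_pct, 3.46)
  expect_equal(s$sd_pct, 1.91)  # population SD of the rounded rates
  single <- failure_rate_summary(1000, 35)
  expect_equal(single$rate_pct, 3.5)
  expect_equal(single$sd_pct, 0)
  expect_error(failure_rate_summary(0, 0), "positive")
})
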