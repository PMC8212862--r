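test_that("RR series arithmetic and validation", {
  s <- rr_intervals(c(0, 800, 1600))
  expect_equal(s$intervals, c(800, 800))
  expect_equal(s$median_rr, 800)
  s2 <- rr_intervals(c(0, 600, 1500))
  expect_equal(s2$intervals, c(600, 900))
  expect_equal(s2$median_rr, 750)
  expect_error(rr_intervals(1000), "at least two")
  expect_error(rr_intervals(c(0, 500, 500)), "zero interval")
})

test_that("the gamma threshold scales the window median", {
  expect_equal(gamma_threshold(c(700, 720, 740, 760), 0.07), 51.1)
  expect_equal(gamma_threshold(c(600, 900), 0), 0)
  expect_equal(gamma_threshold(rep(800, 8), 0.1), 80)
})

test_that("irregularity fraction matches the hand-worked windows", {
  expect_equal(irregularity_fraction(rep(800, 4), 10), 0)
  expect_equal(irregularity_fraction(c(600, 900, 600, 900), 30), 4 / 6)
  w <- c(700, 710, 1000, 690, 705, 1010, 695, 700)
  g <- gamma_threshold(w, 0.07)
  expect_equal(g, 0.07 * 702.5)
  expect_equal(irregularity_fraction(w, g), 12 / 42)
  expect_error(irregularity_fraction(c(700, 800), 10), "at least 3")
})

test_that("a pair difference exactly at gamma counts as regular", {
  # differences are 0, 50, 50; at gamma = 50 no pair is discordant
  expect_equal(irregularity_fraction(c(700, 750, 700), 50), 0)
  expect_equal(irregularity_fraction(c(700, 750, 700), 49.999), 1)
})

test_that("fraction agrees with brute-force pair enumeration", {
  set.seed(21)
  for (i in 1:200) {
    N <- sample(3:12, 1)
    w <- runif(N, 300, 1500)
    g <- runif(1, 0, 400)
    expect_identical(irregularity_fraction(w, g), lambda_brute(w, g))
    expect_identical(irregularity_fraction(w, g, variant = "printed"),
                     lambda_brute(w, g, discordant = FALSE))
  }
})

test_that("discordant and printed variants are complementary", {
  set.seed(22)
  for (i in 1:100) {
    N <- sample(3:10, 1)
    w <- runif(N, 300, 1500)
    g <- runif(1, 1, 300)
    total <- irregularity_fraction(w, g) +
      irregularity_fraction(w, g, variant = "printed")
    expect_equal(total, (N * (N - 1) / 2) / ((N - 1) * (N - 2)))
  }
})

test_that("the vectorized window sweep equals the per-window computation", {
  set.seed(23)
  iv <- runif(40, 400, 1200)
  for (N in c(3, 4, 8)) {
    ls <- afqc:::lambda_series(iv, N, 0.07)
    expect_length(ls$lambda, 40 - N + 1)
    for (i in seq_along(ls$lambda)) {
      w <- iv[i:(i + N - 1)]
      g <- gamma_threshold(w, 0.07)
      expect_equal(ls$gamma[i], g)
      expect_equal(ls$lambda[i], irregularity_fraction(w, g))
    }
  }
})

test_that("window flag is boundary-inclusive", {
  expect_equal(window_flag(0.667, 0.65), 1L)
  expect_equal(window_flag(0.65, 0.65), 1L)
  expect_equal(window_flag(0, 0.3), 0L)
})

test_that("the detector is invariant to a common time-scale factor", {
  times <- gen_rr_series(rhythm_spec("af", 700, 150), 30, seed = 31)
  p <- detector_preset("with_qc")
  d1 <- detect_af(times, p)
  d2 <- detect_af(times * 3.7, p)
  expect_identical(d1$label, d2$label)
  expect_equal(d1$windows$lambda, d2$windows$lambda)
})

test_that("an inserted false detection makes a regular series more irregular", {
  times <- seq(0, 28800, by = 800)
  p <- detector_params(4, 0.07, 0.65)
  base <- detect_af(times, p)
  expect_true(all(base$windows$lambda == 0))
  with_fd <- detect_af(sort(c(times, 2000)), p)
  expect_gt(max(with_fd$windows$lambda), 0)
})

test_that("pruning merges an isolated false detection between normal beats", {
  times <- c(0, 800, 1600, 2000, 2400, 3200)
  labels <- c(rep("true_beat", 3), "false_detection", rep("true_beat", 2))
  pr <- qc_prune(times, labels)
  expect_equal(pr$times, c(0, 800, 1600, 2400, 3200))
  expect_equal(pr$merged_times, 2000)
  expect_length(pr$excluded_times, 0)
  expect_equal(diff(pr$times), rep(800, 4))
  expect_false(pr$quality_flag)
  # all windows qualify
  d <- detect_af(pr$times, detector_params(4, 0.07, 0.65),
                 excluded_times = pr$excluded_times)
  expect_true(all(d$windows$qualifies))
})

test_that("pruning excludes a false detection inside an abnormal gap", {
  times <- c(0, 800, 1600, 2100, 3000)
  labels <- c(rep("true_beat", 3), "false_detection", "true_beat")
  pr <- qc_prune(times, labels)
  expect_equal(pr$times, c(0, 800, 1600, 3000))
  expect_equal(pr$excluded_times, 2100)
  expect_length(pr$merged_times, 0)
  # every window spanning t = 2100 is disqualified
  d <- detect_af(pr$times, detector_params(3, 0.07, 0.65),
                 excluded_times = pr$excluded_times)
  t0 <- pr$times[seq_len(nrow(d$windows))]
  t1 <- pr$times[seq_len(nrow(d$windows)) + 3]
  expect_identical(d$windows$qualifies, !(2100 > t0 & 2100 < t1))
})

test_that("pruning edge cases: no falses, all falses, runs of two", {
  times <- c(0, 800, 1600)
  pr <- qc_prune(times, rep("true_beat", 3))
  expect_equal(pr$times, times)
  expect_length(pr$excluded_times, 0)

  pr2 <- qc_prune(times, rep("false_detection", 3))
  expect_true(pr2$quality_flag)
  expect_length(pr2$times, 0)

  # two consecutive false detections never merge even in a normal gap
  times3 <- c(0, 800, 1000, 1200, 1600, 2400)
  labels3 <- c("true_beat", "true_beat", "false_detection",
               "false_detection", "true_beat", "true_beat")
  pr3 <- qc_prune(times3, labels3)
  expect_equal(sort(pr3$excluded_times), c(1000, 1200))
  expect_length(pr3$merged_times, 0)
})

test_that("the recording decision threshold is boundary-inclusive", {
  # engineered so exactly 2 of 6 windows (N = 3) are irregular
  iv <- c(300, 1700, rep(800, 6))
  times <- cumsum(c(0, iv))
  p <- detector_params(3, 0.1, 0.9, eta_d = 1 / 3)
  d <- detect_af(times, p)
  expect_equal(nrow(d$windows), 6)
  expect_equal(sum(d$windows$O), 2)
  expect_equal(d$fraction, 1 / 3)
  expect_identical(d$label, "AF")
  # just above the boundary the same series is non-AF
  p2 <- detector_params(3, 0.1, 0.9, eta_d = 0.34)
  expect_identical(detect_af(times, p2)$label, "non-AF")
})

test_that("degenerate inputs yield non-AF with the quality flag", {
  p <- detector_params(8, 0.07, 0.55)
  short <- detect_af(c(0, 800, 1600), p)
  expect_identical(short$label, "non-AF")
  expect_true(short$quality_flag)

  # all windows disqualified by a central excluded event
  times <- seq(0, 4000, by = 800)
  d <- detect_af(times, detector_params(4, 0.07, 0.65),
                 excluded_times = 2000)
  expect_identical(d$label, "non-AF")
  expect_true(d$quality_flag)
  expect_equal(d$I, 0L)
})

test_that("perfect quality control restores the clean decision after noise", {
  clean_times <- seq(0, 28800, by = 800)
  p <- detector_preset("with_qc")
  clean_dec <- detect_af(clean_times, p)
  # inject false detections midway into normal gaps: the merge rule applies
  noisy <- sort(c(clean_times, c(4400, 12400, 20400)))
  labels <- ifelse(noisy %in% clean_times, "true_beat", "false_detection")
  pr <- qc_prune(noisy, labels)
  expect_equal(pr$times, clean_times)
  dec <- detect_af(pr$times, p, excluded_times = pr$excluded_times)
  expect_identical(dec$label, clean_dec$label)
  expect_equal(dec$fraction, clean_dec$fraction)
})
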