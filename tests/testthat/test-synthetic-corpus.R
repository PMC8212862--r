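test_that("sinus RR series are regular, AF series irregular", {
  b <- gen_rr_series(rhythm_spec("sinus", 800, 30), 30, seed = 1)
  iv <- diff(b)
  expect_true(length(b) >= 36 && length(b) <= 39)
  expect_true(all(iv > 0))
  expect_lt(stats::sd(iv) / mean(iv), 0.06)
  expect_true(all(b >= 0 & b < 30000))

  b_af <- gen_rr_series(rhythm_spec("af", 700, 150), 30, seed = 1)
  iv_af <- diff(b_af)
  expect_gt(stats::sd(iv_af) / mean(iv_af), 0.15)
  expect_true(all(iv_af >= 300 & iv_af <= 1800))
})

test_that("degenerate sd gives exactly constant intervals", {
  b <- gen_rr_series(rhythm_spec("sinus", 800, 0), 30, seed = 3)
  expect_equal(diff(b), rep(800, length(b) - 1))
})

test_that("ectopy inserts premature beats with compensatory pauses", {
  spec <- rhythm_spec("ectopic-sinus", 800, 10, ectopy_rate = 0.3)
  iv <- diff(gen_rr_series(spec, 30, seed = 5))
  short <- which(iv < 0.7 * 800)
  expect_gt(length(short), 0)
  # each premature interval is followed by a longer-than-normal pause
  after <- iv[pmin(short + 1, length(iv))]
  expect_true(all(after > 800))
})

test_that("RR generation is deterministic and rejects bad input", {
  s <- rhythm_spec("af", 700, 150)
  expect_identical(gen_rr_series(s, 30, seed = 9), gen_rr_series(s, 30, seed = 9))
  expect_false(identical(gen_rr_series(s, 30, seed = 9),
                         gen_rr_series(s, 30, seed = 10)))
  expect_error(gen_rr_series(s, 0, seed = 1), "duration")
  expect_error(rhythm_spec("sinus", mean_rr = -5), "mean_rr")
  expect_error(rhythm_spec("af", af_episode_onset = 5, af_episode_offset = 10),
               "10 s")
})

test_that("rendered beats appear as prominent peaks at the beat times", {
  r <- clean_sinus()
  x <- r$recording$samples
  expect_length(x, 30000)
  thr <- 3 * stats::sd(x)
  n <- length(x)
  peaks <- which(c(FALSE, x[2:(n - 1)] > x[1:(n - 2)] &
                     x[2:(n - 1)] >= x[3:n], FALSE) & x > thr)
  peak_ms <- (peaks - 1)
  # each prominent peak lies within 10 ms of a true beat, one peak per beat
  offs <- vapply(peak_ms, function(p) min(abs(r$truth$beat_times - p)), 1)
  expect_true(all(offs <= 10))
  matched <- vapply(r$truth$beat_times,
                    function(b) any(abs(peak_ms - b) <= 10), logical(1))
  expect_true(all(matched))
})

test_that("rendering handles empty input and applies the AF labeling rule", {
  spec <- rhythm_spec("sinus", 800, 30)
  r0 <- render_ecg(numeric(0), spec, seed = 1)
  expect_length(r0$truth$beat_times, 0)
  expect_length(r0$recording$samples, 30000)
  expect_identical(r0$truth$rhythm_label, "non-AF")

  b <- gen_rr_series(rhythm_spec("af", 700, 150), 30, seed = 2)
  r_af <- render_ecg(b, rhythm_spec("af", 700, 150), seed = 2)
  expect_identical(r_af$truth$rhythm_label, "AF")
  expect_equal(r_af$truth$af_intervals, list(c(0, 30)))

  ep <- rhythm_spec("af", 700, 150, af_episode_onset = 5,
                    af_episode_offset = 16)
  b_ep <- gen_rr_series(ep, 30, seed = 2)
  expect_identical(render_ecg(b_ep, ep, seed = 2)$truth$rhythm_label, "AF")

  expect_error(render_ecg(c(500, 100), spec, seed = 1), "increasing")
})

test_that("transient injection is local, conservative, and seeded", {
  r <- clean_sinus()
  ns <- noise_spec(spike_rate = 3, step_rate = 0, burst_rate = 0)
  nz <- inject_transients(r$recording, r$truth, ns, seed = 7)
  expect_gt(length(nz$truth$noise_times), 0)
  # true beats never move
  expect_identical(nz$truth$beat_times, r$truth$beat_times)
  # spikes alter the signal only within +/- 50 ms of their centers
  changed <- which(nz$recording$samples != r$recording$samples)
  changed_ms <- (changed - 1)
  near <- vapply(changed_ms, function(t)
    any(abs(nz$truth$noise_times - t) <= 50), logical(1))
  expect_true(all(near))

  # zero rates are a strict no-op
  nz0 <- inject_transients(r$recording, r$truth, noise_spec(0, 0, 0), seed = 1)
  expect_identical(nz0$recording$samples, r$recording$samples)
  expect_identical(nz0$truth$noise_times, numeric(0))

  # determinism
  nz2 <- inject_transients(r$recording, r$truth, ns, seed = 7)
  expect_identical(nz$recording$samples, nz2$recording$samples)
})

test_that("a strong burst defeats the reference QRS detector", {
  r <- clean_sinus()
  ns <- noise_spec(spike_rate = 0, step_rate = 0, burst_rate = 1,
                   burst_amp_range = c(2, 2), burst_duration_range = c(1, 1))
  # pick a seed whose Poisson draw places at least one burst
  nz <- NULL
  for (s in 1:10) {
    cand <- inject_transients(r$recording, r$truth, ns, seed = s)
    if (length(cand$truth$noise_times) > 0) { nz <- cand; break }
  }
  expect_false(is.null(nz))
  det <- detect_qrs(nz$recording)
  far <- det[vapply(det, function(t)
    min(abs(r$truth$beat_times - t)), 1) > 75]
  expect_gt(sum(vapply(far, function(f)
    any(abs(f - nz$truth$noise_times) < 700), logical(1))), 0)
})

test_that("corpus construction honors prevalence, labeling, and determinism", {
  ns <- noise_spec(spike_rate = 1, step_rate = 0, burst_rate = 0)
  corpus <- build_corpus(10, 3, af_prevalence = 0.2, noise = ns, seed = 42)
  expect_length(corpus$recordings, 30)
  expect_length(corpus$af_subjects, 2)
  man <- corpus_manifest(corpus)
  expect_equal(nrow(man), 30)

  # a subject is AF iff at least one of its recordings is labeled AF
  for (sid in names(corpus$subjects)) {
    labs <- man$rhythm_label[man$subject_id == sid]
    expect_identical(sid %in% corpus$af_subjects, any(labs == "AF"))
  }
  # the >= 10 s rule holds on every recording
  for (r in corpus$recordings) {
    tot <- sum(vapply(r$truth$af_intervals, function(iv) iv[2] - iv[1], 1))
    expect_identical(r$truth$rhythm_label == "AF", tot >= 10)
  }

  corpus2 <- build_corpus(10, 3, af_prevalence = 0.2, noise = ns, seed = 42)
  expect_identical(corpus$recordings[[5]]$recording$samples,
                   corpus2$recordings[[5]]$recording$samples)
  expect_error(build_corpus(0, 3), "n_subjects")
})

test_that("exact AF-subject count follows round(n * prevalence)", {
  ns <- noise_spec(0, 0, 0)
  corpus <- build_corpus(20, 1, af_prevalence = 0.25, noise = ns, seed = 1)
  expect_length(corpus$af_subjects, 5)
})

test_that("event labeling matches nearest detection within tolerance", {
  truth <- structure(list(beat_times = c(1000, 2000, 3000),
                          rhythm_label = "non-AF", noise_times = numeric(0),
                          af_intervals = list()), class = "beat_truth")
  expect_identical(label_events(c(1000, 2000, 3000), truth),
                   rep("true_beat", 3))
  # an extra detection 300 ms from every beat is a false detection
  expect_identical(label_events(c(1000, 1700, 2000, 3000), truth),
                   c("true_beat", "false_detection", "true_beat", "true_beat"))
  # of two detections near one beat, only the nearer is the true beat
  expect_identical(label_events(c(1010, 1060), truth, tolerance = 75),
                   c("true_beat", "false_detection"))
  expect_error(label_events(c(1, 2), truth, tolerance = -1), "tolerance")
})
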