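# Shared fixtures. Heavy objects (trained CNN runs) are memoised so the
# acceptance tests can reuse them instead of retraining.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- builder()
  .fixture_env[[key]]
}

# One clean sinus recording (75 bpm) with ground truth.
clean_sinus <- function(seed = 1L) {
  memo(paste0("sinus_", seed), function() {
    spec <- rhythm_spec("sinus", mean_rr = 800, rr_sd = 30)
    beats <- gen_rr_series(spec, duration = 30, seed = seed)
    render_ecg(beats, spec, seed = seed + 100L)
  })
}

# A small event dataset with hand-built segment classes: true beats are a
# narrow centered bump on a flat baseline, false detections are broadband
# noise. Used for fast CNN mechanics tests (not for accuracy claims).
tiny_event_dataset <- function(n_per_class = 60, seed = 7L) {
  set.seed(seed)
  t <- seq_len(400)
  mk_beat <- function() {
    x <- exp(-((t - 150)^2) / (2 * 12^2)) + rnorm(400, 0, 0.05)
    (x - min(x)) / (max(x) - min(x))
  }
  mk_noise <- function() {
    x <- rnorm(400)
    (x - min(x)) / (max(x) - min(x))
  }
  segs <- rbind(t(replicate(n_per_class, mk_beat())),
                t(replicate(n_per_class, mk_noise())))
  lab <- rep(c(0L, 1L), each = n_per_class)
  n <- 2L * n_per_class
  split <- rep("train", n)
  split[seq(1, n, by = 4)] <- "validation"
  split[seq(2, n, by = 8)] <- "test"
  structure(list(segments = segs, label = lab,
                 time_ms = seq_len(n) * 800,
                 recording_id = rep("R1", n),
                 subject_id = rep(sprintf("S%02d", seq_len(4)), length.out = n),
                 padded = rep(FALSE, n),
                 split = factor(split, levels = c("train", "validation", "test")),
                 M = n, M0 = sum(lab == 0), M1 = sum(lab == 1)),
            class = "event_dataset")
}

# A full CNN training run on a synthetic screening-noise corpus: corpus,
# event dataset, trained model, F1-selected threshold, and test-split
# metrics. Memoised per seed.
qc_training_run <- function(seed) {
  memo(paste0("qcrun_", seed), function() {
    corpus <- build_corpus(
      65, 2, af_prevalence = 0.1,
      noise = noise_spec(spike_rate = 10, step_rate = 3, burst_rate = 3),
      seed = 100L + seed)
    ds <- build_event_dataset(corpus, seed = 200L + seed)
    model <- train_qc(ds, tconfig = train_config(epochs = 25, patience = 3,
                                                 seed = 300L + seed))
    va <- ds$split == "validation"
    th <- select_threshold(predict(model, ds$segments[va, , drop = FALSE]),
                           ds$label[va])
    te <- ds$split == "test"
    p <- predict(model, ds$segments[te, , drop = FALSE])
    m <- metrics(confusion(as.integer(p > th$theta), ds$label[te],
                           positive = 1L))
    list(dataset = ds, model = model, theta = th$theta, test_metrics = m)
  })
}

# Planted RR-only detector inputs: AF recordings have strongly irregular
# intervals, non-AF recordings nearly regular ones. No rendering involved.
planted_inputs <- function(n_af = 5, n_non = 10, seed = 11L) {
  recs <- list()
  af_subj <- character(0)
  subjects <- list()
  k <- 0L
  for (i in seq_len(n_af)) {
    sid <- sprintf("A%02d", i)
    times <- gen_rr_series(rhythm_spec("af", 700, 150), 30,
                           seed = seed + i)
    k <- k + 1L
    recs[[k]] <- list(subject_id = sid, recording_id = paste0(sid, "-R1"),
                      truth = "AF", times = times,
                      excluded_times = numeric(0), quality_flag = FALSE)
    subjects[[sid]] <- paste0(sid, "-R1")
    af_subj <- c(af_subj, sid)
  }
  for (i in seq_len(n_non)) {
    sid <- sprintf("N%02d", i)
    times <- gen_rr_series(rhythm_spec("sinus", 800, 25), 30,
                           seed = seed + 100L + i)
    k <- k + 1L
    recs[[k]] <- list(subject_id = sid, recording_id = paste0(sid, "-R1"),
                      truth = "non-AF", times = times,
                      excluded_times = numeric(0), quality_flag = FALSE)
    subjects[[sid]] <- paste0(sid, "-R1")
  }
  structure(list(recordings = recs, subjects = subjects,
                 af_subjects = af_subj),
            class = "detector_inputs")
}
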