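#' Write / read a recording as two-column CSV
#'
#' The on-disk format is plain CSV with columns `time_ms` and
#' `amplitude_mV`. On reading, the sampling rate is inferred from the time
#' column and the signal is resampled to 1,000 Hz when recorded at another
#' rate.
#'
#' @param rec an `ecg_recording`.
#' @param path file path.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns an `ecg_recording` at 1,000 Hz.
#' @export
write_recording <- function(rec, path) {
  assert_that(inherits(rec, "ecg_recording"), "rec must be an ecg_recording")
  df <- data.frame(time_ms = (seq_along(rec$samples) - 1) / rec$fs * 1000,
                   amplitude_mV = rec$samples)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @param subject_id,recording_id identifiers attached to the recording.
#' @export
read_recording <- function(path, subject_id = "S0001",
                           recording_id = "R0001") {
  assert_that(file.exists(path), paste("no such file:", path))
  df <- tryCatch(utils::read.csv(path),
                 error = function(e) stop_input(
                   sprintf("cannot parse %s: %s", path, conditionMessage(e))))
  for (col in c("time_ms", "amplitude_mV")) {
    if (!col %in% names(df)) {
      stop_input(sprintf("%s: missing column '%s'", path, col))
    }
  }
  dt <- diff(df$time_ms)
  if (any(dt <= 0)) {
    stop_input(sprintf("%s: time column not strictly increasing at row %d",
                       path, which(dt <= 0)[1] + 2L))  # +1 header, +1 offset
  }
  fs <- 1000 / stats::median(dt)
  rec <- structure(list(subject_id = subject_id, recording_id = recording_id,
                        fs = fs, samples = df$amplitude_mV,
                        duration = length(df$amplitude_mV) / fs,
                        r_amp = 1),
                   class = "ecg_recording")
  resample_to_1000(rec)
}

#' Write / read beat-level ground truth as JSON
#'
#' @param truth a `beat_truth`.
#' @param path file path.
#' @export
write_beat_truth <- function(truth, path) {
  jsonlite::write_json(
    list(beat_times = truth$beat_times,
         rhythm_label = truth$rhythm_label,
         noise_times = truth$noise_times,
         af_intervals = truth$af_intervals),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_beat_truth
#' @export
read_beat_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(beat_times = as.numeric(x$beat_times),
                 rhythm_label = x$rhythm_label,
                 noise_times = as.numeric(x$noise_times),
                 af_intervals = if (length(x$af_intervals))
                   lapply(seq_len(nrow(x$af_intervals)),
                          function(i) as.numeric(x$af_intervals[i, ]))
                 else list()),
            class = "beat_truth")
}

#' Pipeline configuration
#'
#' One object holding every knob of the end-to-end pipeline: corpus shape,
#' noise rates, CNN training settings, detector search settings, and seeds.
#' Round-trips losslessly through YAML via [write_config()] /
#' [read_config()].
#'
#' @param n_subjects,recordings_per_subject,af_prevalence corpus shape.
#' @param duration,fs recording duration (s) and sampling rate (Hz).
#' @param spike_rate,step_rate,burst_rate artifact rates per recording.
#' @param fractions train/validation/test event fractions for the CNN.
#' @param epochs,batch_size,learning_rate,patience CNN training settings.
#' @param min_af_recordings minimum AF recordings per AF subject.
#' @param n_repeats evaluation repeats.
#' @param se_min grid-search sensitivity constraint.
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 60, recordings_per_subject = 5,
                            af_prevalence = 0.1, duration = 30, fs = 1000,
                            spike_rate = 2, step_rate = 0.5, burst_rate = 0.5,
                            fractions = c(0.6, 0.2, 0.2),
                            epochs = 30, batch_size = 256,
                            learning_rate = 0.001, patience = 2,
                            min_af_recordings = 3,
                            n_repeats = 3, se_min = 0.99, seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  for (nm in names(x)) cfg[[nm]] <- x[[nm]]
  cfg
}

#' Run the end-to-end screening pipeline
#'
#' Simulate a corpus, build the CNN-training corpus and event dataset, train
#' the event-quality CNN and select its threshold, then evaluate the AF
#' detector on the screening corpus with and without quality control
#' (parameters re-optimized per split under the sensitivity constraint).
#' Deterministic given the configuration seed.
#'
#' @param config a [pipeline_config()].
#' @param verbose log per-stage counts.
#' @return list of class `pipeline_report`: `cnn` (test-split event metrics
#'   and threshold), `without_qc` / `with_qc` ([repeated_eval()] results),
#'   and the `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  noise <- noise_spec(spike_rate = config$spike_rate,
                      step_rate = config$step_rate,
                      burst_rate = config$burst_rate)

  # Dense-noise corpus for event-level CNN training
  say("simulating CNN-training corpus ...")
  train_corpus <- build_corpus(
    n_subjects = config$n_subjects, recordings_per_subject = 2,
    af_prevalence = config$af_prevalence,
    noise = noise_spec(spike_rate = 10, step_rate = 3, burst_rate = 3),
    seed = child_seed(config$seed, 11L), duration = config$duration,
    fs = config$fs)
  ds <- build_event_dataset(train_corpus, fractions = config$fractions,
                            seed = child_seed(config$seed, 12L))
  say("event dataset: %d events (%d true beats, %d false detections)",
      ds$M, ds$M0, ds$M1)

  model <- train_qc(ds, tconfig = train_config(
    epochs = config$epochs, batch_size = config$batch_size,
    learning_rate = config$learning_rate, patience = config$patience,
    seed = child_seed(config$seed, 13L)))
  va <- ds$split == "validation"
  th <- select_threshold(predict(model, ds$segments[va, , drop = FALSE]),
                         ds$label[va])
  te <- ds$split == "test"
  pte <- predict(model, ds$segments[te, , drop = FALSE])
  cnn_m <- metrics(confusion(as.integer(pte > th$theta), ds$label[te],
                             positive = 1L))
  say("CNN threshold %.2f; test-event Se %.1f%% Sp %.1f%% Acc %.1f%% F1 %.1f%%",
      th$theta, 100 * cnn_m$Se, 100 * cnn_m$Sp, 100 * cnn_m$Acc,
      100 * cnn_m$F1)

  # Screening corpus for AF detection
  say("simulating screening corpus ...")
  screen_corpus <- build_corpus(
    n_subjects = config$n_subjects,
    recordings_per_subject = config$recordings_per_subject,
    af_prevalence = config$af_prevalence, noise = noise,
    seed = child_seed(config$seed, 21L), duration = config$duration,
    fs = config$fs, min_af_recordings = config$min_af_recordings)

  inputs_raw <- prepare_detector_inputs(screen_corpus)
  inputs_qc <- prepare_detector_inputs(screen_corpus, model = model,
                                       theta = th$theta)
  say("evaluating AF detector (%d repeats) ...", config$n_repeats)
  ev_raw <- repeated_eval(inputs_raw, n_repeats = config$n_repeats,
                          base_seed = child_seed(config$seed, 31L),
                          se_min = config$se_min)
  ev_qc <- repeated_eval(inputs_qc, n_repeats = config$n_repeats,
                         base_seed = child_seed(config$seed, 31L),
                         se_min = config$se_min)

  structure(list(cnn = list(threshold = th$theta, f1_val = th$f1,
                            test_metrics = cnn_m,
                            history = model$history),
                 model = model,
                 without_qc = ev_raw, with_qc = ev_qc,
                 config = config),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("== event-quality CNN (test events) ==\n")
  cat(sprintf("threshold %.2f  ", x$cnn$threshold))
  print(x$cnn$test_metrics)
  cat("== AF detection without quality control ==\n")
  print(x$without_qc$summary, row.names = FALSE)
  cat("== AF detection with quality control ==\n")
  print(x$with_qc$summary, row.names = FALSE)
  invisible(x)
}
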